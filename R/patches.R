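#' Paired noisy/clean slice
#'
#' One training slice: the clean magnitude image and its simulated noisy
#' counterpart, plus provenance (volume id, slice index, and a record of
#' the simulator call that produced the noisy image).
#'
#' @param clean,noisy [magnitude_image()] objects of identical shape
#' @param volume_id character volume identifier (split granularity)
#' @param slice_index integer slice index within the volume
#' @param simulator list recording how `noisy` was produced
#' @return an object of class `paired_slice`
#' @export
paired_slice <- function(clean, noisy, volume_id, slice_index,
                         simulator = list()) {
  if (!identical(dim(as_pixels(clean)), dim(as_pixels(noisy)))) {
    stop_nn("nativenoise_parameter_error",
            "clean and noisy slices must have the same shape")
  }
  structure(
    list(clean = clean, noisy = noisy, volume_id = as.character(volume_id),
         slice_index = as.integer(slice_index), simulator = simulator),
    class = "paired_slice"
  )
}

#' Split paired slices into train/validation/test sets
#'
#' The partition is performed at volume granularity so that neighboring
#' (nearly identical) slices of one volume can never leak between
#' training and evaluation. Volume counts use largest-remainder
#' apportionment of the requested fractions; every split with a positive
#' fraction must receive at least one volume.
#'
#' @param slices list of [paired_slice()]
#' @param fractions numeric length-3 (train, val, test), positive entries
#'   summing to 1; the 85/5/10 default mirrors common practice for this
#'   kind of denoiser
#' @param seed integer seed for the volume shuffle
#' @return named list of three lists of `paired_slice`: `train`, `val`,
#'   `test`
#' @export
split_dataset <- function(slices, fractions = c(0.85, 0.05, 0.10), seed = 0) {
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop_nn("nativenoise_parameter_error",
            "fractions must be three nonnegative numbers summing to 1")
  }
  vols <- unique(vapply(slices, function(s) s$volume_id, ""))
  nv <- length(vols)
  pos <- fractions > 0
  if (nv < sum(pos)) {
    stop_nn("nativenoise_parameter_error",
            sprintf("%d volumes cannot fill %d splits", nv, sum(pos)))
  }
  counts <- floor(fractions * nv)
  rem <- nv - sum(counts)
  if (rem > 0) {
    order_rem <- order(fractions * nv - counts, decreasing = TRUE)
    counts[order_rem[seq_len(rem)]] <- counts[order_rem[seq_len(rem)]] + 1
  }
  if (any(pos & counts == 0)) {
    stop_nn("nativenoise_parameter_error",
            "a split with positive fraction received no volumes; use more volumes")
  }
  shuffled <- with_seed(seed, sample(vols))
  assign_split <- rep(c("train", "val", "test"), times = counts)
  names(assign_split) <- shuffled
  out <- list(train = list(), val = list(), test = list())
  for (s in slices) {
    out[[assign_split[[s$volume_id]]]] <-
      c(out[[assign_split[[s$volume_id]]]], list(s))
  }
  out
}

#' Extract paired square patches from paired slices
#'
#' Draws `n_per_slice` square patches per slice at uniformly random valid
#' top-left corners (with replacement across locations); noisy and clean
#' patches are cut at identical coordinates. Before patching, each slice
#' pair is normalized to \[0, 1\] by the clean slice's maximum so that MSE
#' and PSNR are comparable across slices.
#'
#' @param slices list of [paired_slice()]
#' @param patch_size patch side in pixels; must fit inside every slice
#' @param n_per_slice patches drawn per slice
#' @param seed integer seed
#' @param split label stored on the returned set (`"train"`, `"val"`,
#'   `"test"`)
#' @return an object of class `paired_patch_set`: arrays `noisy`, `clean`
#'   of dim (patch, patch, n), a data.frame `meta` (slice_id, row, col) and
#'   fields `patch_size`, `split`
#' @export
extract_patches <- function(slices, patch_size = 64, n_per_slice = 5,
                            seed = 0, split = "train") {
  if (length(slices) == 0) {
    return(structure(list(noisy = array(0, c(patch_size, patch_size, 0)),
                          clean = array(0, c(patch_size, patch_size, 0)),
                          meta = data.frame(slice_id = character(),
                                            row = integer(), col = integer()),
                          patch_size = as.integer(patch_size),
                          split = split),
                     class = "paired_patch_set"))
  }
  dims <- vapply(slices, function(s) dim(as_pixels(s$clean)), integer(2))
  if (patch_size > min(dims)) {
    stop_nn("nativenoise_parameter_error",
            sprintf("patch_size %d exceeds the smallest slice dimension %d",
                    patch_size, min(dims)))
  }
  total <- length(slices) * n_per_slice
  noisy <- array(0, c(patch_size, patch_size, total))
  clean <- array(0, c(patch_size, patch_size, total))
  meta <- data.frame(slice_id = character(total), row = integer(total),
                     col = integer(total), stringsAsFactors = FALSE)
  with_seed(seed, {
    k <- 0L
    for (s in slices) {
      cpx <- as_pixels(s$clean)
      npx <- as_pixels(s$noisy)
      mx <- max(cpx)
      if (mx > 0) {
        cpx <- cpx / mx
        npx <- npx / mx
      }
      h <- nrow(cpx)
      w <- ncol(cpx)
      sid <- sprintf("%s:%d", s$volume_id, s$slice_index)
      for (j in seq_len(n_per_slice)) {
        r0 <- sample.int(h - patch_size + 1L, 1L)
        c0 <- sample.int(w - patch_size + 1L, 1L)
        k <- k + 1L
        rows <- r0:(r0 + patch_size - 1L)
        cols <- c0:(c0 + patch_size - 1L)
        noisy[, , k] <- npx[rows, cols]
        clean[, , k] <- cpx[rows, cols]
        meta$slice_id[k] <- sid
        meta$row[k] <- r0
        meta$col[k] <- c0
      }
    }
  })
  structure(list(noisy = noisy, clean = clean, meta = meta,
                 patch_size = as.integer(patch_size), split = split),
            class = "paired_patch_set")
}

#' @export
print.paired_patch_set <- function(x, ...) {
  cat(sprintf("<paired_patch_set> %d patches of %d x %d px, split '%s'\n",
              dim(x$noisy)[3], x$patch_size, x$patch_size, x$split))
  invisible(x)
}

#' Persist / load a paired patch set
#'
#' Single-file container (RDS serialization of the validated fields plus a
#' format tag). `read_patchset(write_patchset(x, p))` reproduces `x`
#' bit-exactly, including provenance.
#'
#' @param set a [extract_patches()] result
#' @param path file path
#' @export
write_patchset <- function(set, path) {
  stopifnot(inherits(set, "paired_patch_set"))
  payload <- list(format = "nativenoise_patchset", version = 1L,
                  noisy = set$noisy, clean = set$clean, meta = set$meta,
                  patch_size = set$patch_size, split = set$split)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_patchset
#' @export
read_patchset <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e) {
    stop_nn("nativenoise_format_error",
            sprintf("cannot read patch set '%s': %s", path,
                    conditionMessage(e)))
  })
  for (f in c("format", "noisy", "clean", "meta", "patch_size", "split")) {
    if (is.null(payload[[f]])) {
      stop_nn("nativenoise_format_error",
              sprintf("patch set file is missing field '%s'", f))
    }
  }
  if (!identical(payload$format, "nativenoise_patchset")) {
    stop_nn("nativenoise_format_error",
            sprintf("field 'format' is '%s', expected 'nativenoise_patchset'",
                    payload$format))
  }
  if (!identical(dim(payload$noisy), dim(payload$clean))) {
    stop_nn("nativenoise_format_error",
            "fields 'noisy' and 'clean' have mismatched patch shapes")
  }
  ps <- payload$patch_size
  if (dim(payload$noisy)[1] != ps || dim(payload$noisy)[2] != ps) {
    stop_nn("nativenoise_format_error",
            "field 'patch_size' disagrees with the stored patch arrays")
  }
  structure(list(noisy = payload$noisy, clean = payload$clean,
                 meta = payload$meta, patch_size = ps, split = payload$split),
            class = "paired_patch_set")
}
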