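#' Magnitude image
#'
#' The basic container of the package: a nonnegative 2D intensity array
#' (arbitrary units, typically normalized to \[0, 1\]) with pixel spacing in
#' mm and an identifier. Magnitude MR images are the modulus of a complex
#' acquisition, so their background noise is Rayleigh/Rician rather than
#' Gaussian — the fact the whole package revolves around.
#'
#' @param pixels numeric matrix, all values finite and >= 0, at least 16 x 16
#' @param spacing numeric length-2, (row, col) pixel spacing in mm
#' @param id character identifier
#' @param validate set to `FALSE` to skip the nonnegativity check (used
#'   internally for Gaussian-corrupted magnitudes, which may dip below zero)
#' @return an object of class `magnitude_image`
#' @export
magnitude_image <- function(pixels, spacing = c(1, 1), id = "",
                            validate = TRUE) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_nn("nativenoise_parameter_error", "pixels must be a numeric matrix")
  }
  if (any(!is.finite(pixels))) {
    stop_nn("nativenoise_parameter_error", "pixels must be finite")
  }
  if (nrow(pixels) < 16 || ncol(pixels) < 16) {
    stop_nn("nativenoise_parameter_error",
            "image must be at least 16 x 16 pixels")
  }
  if (validate && any(pixels < 0)) {
    stop_nn("nativenoise_parameter_error",
            "magnitude image pixels must be nonnegative")
  }
  structure(
    list(pixels = pixels, spacing = as.numeric(spacing), id = as.character(id)),
    class = "magnitude_image"
  )
}

#' @export
print.magnitude_image <- function(x, ...) {
  cat(sprintf("<magnitude_image '%s'> %d x %d px, spacing %.2f x %.2f mm, range [%.4g, %.4g]\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.magnitude_image <- function(x) dim(x$pixels)

as_pixels <- function(image) {
  if (inherits(image, "magnitude_image")) image$pixels else as.matrix(image)
}

#' Side of the corner noise patches
#'
#' Corner patches are the four squares of side `floor(fraction * min(H, W))`
#' at the image corners; their pixels sample pure background noise when the
#' object is centered. The 10% default is the package-wide convention.
#'
#' @param image a `magnitude_image` or matrix
#' @param fraction fraction of the smaller image side, in (0, 0.25]
#' @export
corner_patch_side <- function(image, fraction = 0.1) {
  px <- as_pixels(image)
  if (fraction <= 0 || fraction > 0.25) {
    stop_nn("nativenoise_parameter_error",
            "corner_fraction must be in (0, 0.25]")
  }
  side <- floor(fraction * min(dim(px)))
  if (side < 1) {
    stop_nn("nativenoise_parameter_error",
            "corner patches are empty at this corner_fraction")
  }
  side
}

#' Pixels of the four corner patches, pooled
#' @inheritParams corner_patch_side
#' @export
corner_pixels <- function(image, fraction = 0.1) {
  px <- as_pixels(image)
  side <- corner_patch_side(px, fraction)
  h <- nrow(px)
  w <- ncol(px)
  c(px[1:side, 1:side],
    px[1:side, (w - side + 1):w],
    px[(h - side + 1):h, 1:side],
    px[(h - side + 1):h, (w - side + 1):w])
}

#' Foreground mask of a magnitude image
#'
#' Otsu threshold followed by binary erosion with a 2-pixel square
#' structuring element; if the eroded mask is empty the central 50% x 50%
#' box is used instead. This is the default signal ROI for SNR estimation.
#'
#' @param image a `magnitude_image` or matrix
#' @return logical matrix of the image's shape
#' @export
foreground_mask <- function(image) {
  px <- as_pixels(image)
  m <- cpp_foreground_mask(px)
  storage.mode(m) <- "logical"
  m
}

#' Write a magnitude image as 8-bit grayscale PNG
#'
#' Intensities are mapped linearly from \[0, max\] to the 8-bit range; the
#' scale is recorded in an optional JSON sidecar so images can be read back
#' on their original scale.
#'
#' @param image a `magnitude_image`
#' @param path output path (.png)
#' @param sidecar write `<path>.json` with id, spacing and intensity scale
#' @export
write_image_png <- function(image, path, sidecar = TRUE) {
  px <- pmax(as_pixels(image), 0)
  mx <- max(px)
  scale <- if (mx > 0) mx else 1
  png::writePNG(px / scale, path, dpi = NULL)
  if (sidecar) {
    jsonlite::write_json(
      list(id = image$id, spacing = image$spacing, intensity_scale = scale),
      paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Read a magnitude image written by [write_image_png()]
#' @param path path to the PNG
#' @export
read_image_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  meta <- list(id = basename(path), spacing = c(1, 1), intensity_scale = 1)
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    meta <- utils::modifyList(meta, jsonlite::read_json(sc, simplifyVector = TRUE))
  }
  magnitude_image(px * meta$intensity_scale,
                  spacing = as.numeric(meta$spacing), id = meta$id)
}

#' Write a list of slices as a NIfTI volume
#'
#' @param slices list of `magnitude_image` of identical shape
#' @param path output path (.nii or .nii.gz)
#' @export
write_volume_nifti <- function(slices, path) {
  stopifnot(length(slices) >= 1)
  arr <- vapply(slices, function(s) as_pixels(s),
                matrix(0, nrow(slices[[1]]$pixels), ncol(slices[[1]]$pixels)))
  sp <- slices[[1]]$spacing
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(sp[1], sp[2], 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a list of magnitude images
#' @param path path to a NIfTI file
#' @param id_prefix identifier prefix; slice index is appended
#' @export
read_volume_nifti <- function(path, id_prefix = basename(path)) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  pd <- attr(RNifti::readNifti(path), "pixdim")
  sp <- if (!is.null(pd) && length(pd) >= 2) pd[1:2] else c(1, 1)
  lapply(seq_len(dim(arr)[3]), function(k) {
    magnitude_image(arr[, , k], spacing = sp,
                    id = sprintf("%s_%03d", id_prefix, k))
  })
}
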