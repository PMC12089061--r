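#' Mean squared error between two images
#'
#' Mean of squared pixel differences over all N pixels.
#'
#' @param pred,truth numeric matrices (or [magnitude_image()]) of equal
#'   shape
#' @export
mse <- function(pred, truth) {
  p <- as_pixels(pred)
  t <- as_pixels(truth)
  if (!identical(dim(p), dim(t))) {
    stop_nn("nativenoise_parameter_error", "images must have the same shape")
  }
  mean((p - t)^2)
}

#' Peak signal-to-noise ratio, in dB
#'
#' `10 log10(max(truth)^2 / MSE)`, with the peak taken as the ground-truth
#' image's own maximum (not a fixed dynamic range). Identical images have
#' no finite PSNR and raise a condition of class
#' `nativenoise_infinite_psnr`.
#'
#' @inheritParams mse
#' @export
psnr <- function(pred, truth) {
  m <- mse(pred, truth)
  if (m == 0) {
    stop_nn("nativenoise_infinite_psnr",
            "images are identical; PSNR is infinite")
  }
  10 * log10(max(as_pixels(truth))^2 / m)
}

# Normalized Gaussian window (or uniform when sigma is NULL).
ssim_window <- function(size, sigma) {
  if (is.null(sigma)) {
    matrix(1 / (size * size), size, size)
  } else {
    r <- (size - 1) / 2
    g <- stats::dnorm(seq(-r, r), sd = sigma)
    k <- outer(g, g)
    k / sum(k)
  }
}

#' Structural similarity index
#'
#' Windowed luminance/contrast/structure comparison
#' `((2 mu_x mu_y + C1)(2 sigma_xy + C2)) /
#'  ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))`,
#' averaged over sliding windows (valid positions only). Defaults follow
#' the standard reference implementation: 11 x 11 Gaussian window with
#' sigma 1.5, `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with `L` the dynamic
#' range (1 for \[0, 1\]-normalized images). Window statistics are
#' window-weighted means/variances/covariance.
#'
#' @param x,y images of equal shape
#' @param data_range dynamic range L of the data
#' @param window_size odd window side; must not exceed the image
#' @param window_sigma Gaussian window sigma, or `NULL` for a uniform
#'   window
#' @param C1,C2 stabilizing constants; default derived from `data_range`
#' @return scalar in \[-1, 1\]
#' @export
ssim <- function(x, y, data_range = 1, window_size = 11, window_sigma = 1.5,
                 C1 = (0.01 * data_range)^2, C2 = (0.03 * data_range)^2) {
  xp <- as_pixels(x)
  yp <- as_pixels(y)
  if (!identical(dim(xp), dim(yp))) {
    stop_nn("nativenoise_parameter_error", "images must have the same shape")
  }
  if (window_size > min(dim(xp))) {
    stop_nn("nativenoise_parameter_error", "window larger than image")
  }
  w <- ssim_window(window_size, window_sigma)
  fil <- function(m) local_filter(m, w)
  mu_x <- fil(xp)
  mu_y <- fil(yp)
  sxx <- fil(xp * xp) - mu_x^2
  syy <- fil(yp * yp) - mu_y^2
  sxy <- fil(xp * yp) - mu_x * mu_y
  num <- (2 * mu_x * mu_y + C1) * (2 * sxy + C2)
  den <- (mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2)
  mean(num / den)
}

# Valid-mode 2D correlation of image with window weights, via per-offset
# accumulation (no FFT needed at these sizes).
local_filter <- function(m, w) {
  k <- nrow(w)
  h <- nrow(m) - k + 1
  wd <- ncol(m) - k + 1
  out <- matrix(0, h, wd)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (w[a, b] != 0) {
        out <- out + w[a, b] * m[a:(a + h - 1), b:(b + wd - 1)]
      }
    }
  }
  out
}

#' SNR gain of a denoiser on one image, in dB
#'
#' `snr_db(output) - snr_db(input)`, both measured with [estimate_snr()]
#' under identical corner-patch and ROI conventions.
#'
#' @param input_img,output_img images valid for [estimate_snr()]
#' @param corner_fraction corner-patch convention
#' @export
snr_gain <- function(input_img, output_img, corner_fraction = 0.1) {
  estimate_snr(output_img, corner_fraction)$snr_db -
    estimate_snr(input_img, corner_fraction)$snr_db
}

#' Two-sided paired t-test on per-slice values
#'
#' Thin wrapper over [stats::t.test()] that distinguishes the degenerate
#' cases: identical vectors give `t = 0, p = 1`; a constant nonzero
#' difference (zero variance) raises `nativenoise_degenerate_test`.
#'
#' @param a,b numeric vectors of equal length >= 2
#' @return list with `t`, `p`, `mean_diff`
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop_nn("nativenoise_parameter_error",
            "need two equal-length vectors of length >= 2")
  }
  d <- a - b
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, mean_diff = 0))
    }
    stop_nn("nativenoise_degenerate_test",
            "differences have zero variance but nonzero mean; t is undefined")
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_diff = unname(tt$estimate))
}

#' Absolute difference map between two images
#'
#' @param a,b images of equal shape
#' @return list with `raw` (|a - b|) and `normalized` (scaled to \[0, 1\]
#'   for rendering; all zeros when the images are identical)
#' @export
difference_map <- function(a, b) {
  ap <- as_pixels(a)
  bp <- as_pixels(b)
  if (!identical(dim(ap), dim(bp))) {
    stop_nn("nativenoise_parameter_error", "images must have the same shape")
  }
  raw <- abs(ap - bp)
  mx <- max(raw)
  list(raw = raw, normalized = if (mx > 0) raw / mx else raw)
}

#' Intensity profile along a row or polyline
#'
#' @param image an image
#' @param row integer row index, or `NULL` when `path` is given
#' @param path optional 2-column matrix of (row, col) pixel coordinates
#' @return numeric vector of ordered intensities
#' @export
line_profile <- function(image, row = NULL, path = NULL) {
  px <- as_pixels(image)
  if (!is.null(row)) {
    if (row < 1 || row > nrow(px)) {
      stop_nn("nativenoise_parameter_error", "row outside image")
    }
    return(px[row, ])
  }
  if (is.null(path)) {
    stop_nn("nativenoise_parameter_error", "give either row or path")
  }
  path <- round(path)
  if (any(path[, 1] < 1 | path[, 1] > nrow(px) |
          path[, 2] < 1 | path[, 2] > ncol(px))) {
    stop_nn("nativenoise_parameter_error", "path leaves the image")
  }
  px[cbind(path[, 1], path[, 2])]
}

#' Edge sharpness of a profile
#'
#' Maximum absolute first difference — a scalar summary of how steep the
#' steepest transition along the profile is.
#' @param profile numeric vector
#' @export
profile_edge_sharpness <- function(profile) {
  max(abs(diff(profile)))
}

ci95 <- function(x) {
  n <- length(x)
  m <- mean(x)
  half <- stats::qt(0.975, n - 1) * sd(x) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half)
}

#' Evaluate denoising models on a paired test set
#'
#' Denoises every test slice with every model, measures per-slice input
#' and output SNR (dB), SNR gain, PSNR and SSIM against the clean truth,
#' aggregates each column as mean with 95% Student-t confidence interval,
#' and compares every pair of models by percent improvement of the mean
#' output SNR (`100 (A - B) / B` on dB means) and a paired t-test on the
#' per-slice output SNRs.
#'
#' @param models named list of checkpoints (see [train_denoiser()])
#' @param test_slices list of [paired_slice()] (>= 2); the noisy member is
#'   the model input, the clean member the reference. Slices are
#'   \[0, 1\]-normalized by the clean maximum before evaluation, matching
#'   training.
#' @param corner_fraction corner-patch convention for SNR
#' @return an object of class `metric_report` with `per_slice`,
#'   `aggregate` and `comparisons` data.frames
#' @export
evaluate_methods <- function(models, test_slices, corner_fraction = 0.1) {
  if (length(test_slices) < 2) {
    stop_nn("nativenoise_parameter_error", "need at least 2 test slices")
  }
  stopifnot(length(names(models)) == length(models))
  rows <- list()
  for (mname in names(models)) {
    ck <- models[[mname]]
    for (s in test_slices) {
      cpx <- as_pixels(s$clean)
      npx <- as_pixels(s$noisy)
      mx <- max(cpx)
      if (mx > 0) {
        cpx <- cpx / mx
        npx <- npx / mx
      }
      noisy_img <- magnitude_image(npx, id = "in", validate = FALSE)
      den <- denoise_image(ck, noisy_img)
      snr_in <- estimate_snr(npx, corner_fraction)$snr_db
      snr_out <- estimate_snr(as_pixels(den), corner_fraction)$snr_db
      rows[[length(rows) + 1]] <- data.frame(
        method = mname,
        id = sprintf("%s:%d", s$volume_id, s$slice_index),
        snr_in_db = snr_in, snr_out_db = snr_out,
        gain_db = snr_out - snr_in,
        psnr = psnr(den, cpx), ssim = ssim(as_pixels(den), cpx),
        stringsAsFactors = FALSE)
    }
  }
  per_slice <- do.call(rbind, rows)

  agg <- do.call(rbind, lapply(split(per_slice, per_slice$method), function(d) {
    row <- data.frame(method = d$method[1], n = nrow(d),
                      stringsAsFactors = FALSE)
    for (col in c("snr_in_db", "snr_out_db", "gain_db", "psnr", "ssim")) {
      ci <- ci95(d[[col]])
      row[[paste0(col, "_mean")]] <- ci[["mean"]]
      row[[paste0(col, "_lo")]] <- ci[["lo"]]
      row[[paste0(col, "_hi")]] <- ci[["hi"]]
    }
    row
  }))
  agg <- agg[match(names(models), agg$method), ]
  rownames(agg) <- NULL

  meths <- names(models)
  comp <- list()
  if (length(meths) >= 2) {
    for (i in seq_along(meths)) {
      for (j in seq_along(meths)) {
        if (i >= j) next
        a <- per_slice[per_slice$method == meths[i], ]
        b <- per_slice[per_slice$method == meths[j], ]
        b <- b[match(a$id, b$id), ]
        tt <- tryCatch(paired_ttest(a$snr_out_db, b$snr_out_db),
                       nativenoise_degenerate_test = function(e) {
                         list(t = NA_real_, p = NA_real_,
                              mean_diff = mean(a$snr_out_db - b$snr_out_db))
                       })
        comp[[length(comp) + 1]] <- data.frame(
          method_a = meths[i], method_b = meths[j],
          pct_improvement = 100 * (mean(a$snr_out_db) - mean(b$snr_out_db)) /
            mean(b$snr_out_db),
          t = tt$t, p = tt$p, mean_diff_db = tt$mean_diff,
          stringsAsFactors = FALSE)
      }
    }
  }
  comparisons <- if (length(comp)) do.call(rbind, comp) else
    data.frame(method_a = character(), method_b = character(),
               pct_improvement = numeric(), t = numeric(), p = numeric(),
               mean_diff_db = numeric())

  structure(list(per_slice = per_slice, aggregate = agg,
                 comparisons = comparisons),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  print(x$aggregate[, c("method", "n", "snr_out_db_mean", "gain_db_mean",
                        "psnr_mean", "ssim_mean")], row.names = FALSE)
  if (nrow(x$comparisons)) {
    cat("comparisons:\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}

#' Export a nonnegative map (difference map, ERF) as a grayscale PNG
#'
#' Values are scaled to \[0, 1\] by the map maximum.
#' @param map numeric matrix
#' @param path output path (.png)
#' @export
write_map_png <- function(map, path) {
  mx <- max(map)
  png::writePNG(if (mx > 0) pmax(map, 0) / mx else map * 0, path)
  invisible(path)
}

#' Write a metric report as CSV (per-slice) plus JSON (aggregates)
#'
#' @param report a `metric_report`
#' @param dir output directory (created if needed)
#' @export
write_metric_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_slice, file.path(dir, "per_slice.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(aggregate = report$aggregate, comparisons = report$comparisons),
    file.path(dir, "aggregate.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
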