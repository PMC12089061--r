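#' Noise profile of a target low-field scanner
#'
#' Characterizes the noise of a target acquisition by its corner-patch SNR
#' (linear and dB, with `snr_db = 20 log10(snr_linear)`) and the noise
#' standard deviation on \[0, 1\]-normalized intensities, plus the noise
#' family of the magnitude background (Rician for single-coil magnitude
#' data, Gaussian for directly-added noise).
#'
#' @param target_snr_linear positive linear SNR
#' @param noise_std positive noise standard deviation on normalized
#'   intensities
#' @param family `"rician"` or `"gaussian"`
#' @param name optional label
#' @return an object of class `noise_profile`
#' @export
noise_profile <- function(target_snr_linear, noise_std,
                          family = c("rician", "gaussian"), name = "") {
  family <- match.arg(family)
  if (!is.numeric(target_snr_linear) || target_snr_linear <= 0) {
    stop_nn("nativenoise_parameter_error", "target_snr_linear must be > 0")
  }
  if (!is.numeric(noise_std) || noise_std <= 0) {
    stop_nn("nativenoise_parameter_error", "noise_std must be > 0")
  }
  structure(
    list(target_snr_linear = target_snr_linear,
         target_snr_db = 20 * log10(target_snr_linear),
         noise_std = noise_std, family = family, name = name),
    class = "noise_profile"
  )
}

#' Published low-field noise profiles
#'
#' The three measured scanner profiles the simulator is pointed at:
#' 0.3T M4Raw single-channel (SNR 7.15, noise std 0.024), 0.05T in vivo
#' brain (SNR 4.17, noise std 0.04) and 0.05T phantom (SNR 20.96, noise
#' std 0.018).
#'
#' @return named list of [noise_profile()] objects (`m4raw`, `invivo`,
#'   `phantom`)
#' @export
lf_noise_profiles <- function() {
  list(
    m4raw = noise_profile(7.15, 0.024, "rician", name = "m4raw"),
    invivo = noise_profile(4.17, 0.040, "rician", name = "invivo"),
    phantom = noise_profile(20.96, 0.018, "rician", name = "phantom")
  )
}

#' Configuration of the iterative noise simulator
#'
#' Each iteration adds `rho * n` to the real and imaginary channels, with
#' `n` drawn per pixel from a zero-mean Gaussian of standard deviation
#' `sigma`. `sigma` defaults to 1 so `rho` alone sets the per-step noise
#' increment on the \[0, 1\] intensity scale; the default step
#' `rho * sigma = 0.005` trades accuracy against iteration count (smaller
#' steps land closer to the target SNR but need more iterations).
#'
#' @param rho step scale factor (>= 0; [simulate_native_noise()] itself
#'   requires > 0, while `rho = 0` makes [add_noise_step()] the identity)
#' @param sigma positive per-step noise standard deviation
#' @param tolerance relative SNR error at which to stop (> 0)
#' @param max_iters maximum iterations before signalling non-convergence
#' @param seed integer seed for the noise draws
#' @return an object of class `sim_config`
#' @export
sim_config <- function(rho = 0.005, sigma = 1, tolerance = 0.02,
                       max_iters = 10000, seed = 0) {
  if (!is.numeric(rho) || rho < 0) {
    stop_nn("nativenoise_parameter_error", "rho must be >= 0")
  }
  if (!is.numeric(sigma) || sigma <= 0) {
    stop_nn("nativenoise_parameter_error", "sigma must be > 0")
  }
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stop_nn("nativenoise_parameter_error", "tolerance must be > 0")
  }
  if (!is.numeric(max_iters) || max_iters < 1) {
    stop_nn("nativenoise_parameter_error", "max_iters must be >= 1")
  }
  structure(
    list(rho = rho, sigma = sigma, tolerance = tolerance,
         max_iters = as.integer(max_iters), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Estimate background noise from the corner patches
#'
#' Population standard deviation pooled over the pixels of the four corner
#' squares of side `floor(corner_fraction * min(H, W))`.
#'
#' @param image a [magnitude_image()] or numeric matrix
#' @param corner_fraction fraction of the smaller side, in (0, 0.25]
#' @return positive scalar noise standard deviation
#' @export
estimate_noise_std <- function(image, corner_fraction = 0.1) {
  pop_sd(corner_pixels(image, corner_fraction))
}

#' Corner-patch SNR of a magnitude image
#'
#' SNR is the mean signal in the region of interest divided by the
#' standard deviation of the noise in the corner patches. If `roi` is
#' omitted the foreground is derived with [foreground_mask()] (Otsu
#' threshold eroded by 2 px, central-box fallback).
#'
#' @param image a [magnitude_image()] or numeric matrix
#' @param corner_fraction fraction of the smaller side for the corner
#'   patches
#' @param roi optional logical matrix selecting the signal ROI
#' @return an object of class `snr_result` with fields `snr_linear`,
#'   `snr_db`, `signal_mean`, `noise_std`, `roi_mask_summary`,
#'   `corner_patch_side`
#' @export
estimate_snr <- function(image, corner_fraction = 0.1, roi = NULL) {
  px <- as_pixels(image)
  side <- corner_patch_side(px, corner_fraction)
  if (is.null(roi)) {
    s <- cpp_snr_magnitude(px, corner_fraction)
    noise_std <- s[2]
    signal_mean <- s[3]
    n_roi <- s[4]
  } else {
    if (!identical(dim(roi), dim(px))) {
      stop_nn("nativenoise_parameter_error", "roi shape must match image")
    }
    if (!any(roi)) {
      stop_nn("nativenoise_parameter_error", "roi is empty")
    }
    noise_std <- pop_sd(corner_pixels(px, corner_fraction))
    signal_mean <- mean(px[roi])
    n_roi <- sum(roi)
  }
  if (noise_std <= 0) {
    stop_nn("nativenoise_noise_free_error",
            "corner patches carry no noise; SNR is not finite")
  }
  snr <- signal_mean / noise_std
  structure(
    list(snr_linear = snr, snr_db = 20 * log10(snr),
         signal_mean = signal_mean, noise_std = noise_std,
         roi_mask_summary = list(n_pixels = as.integer(n_roi),
                                 fraction = n_roi / length(px)),
         corner_patch_side = side),
    class = "snr_result"
  )
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("<snr_result> SNR %.3f (%.2f dB); signal %.4g, noise sd %.4g, ROI %d px\n",
              x$snr_linear, x$snr_db, x$signal_mean, x$noise_std,
              x$roi_mask_summary$n_pixels))
  invisible(x)
}

#' Approximate a complex image from a magnitude image
#'
#' When only magnitude data are available, real and imaginary channels are
#' initialized to `magnitude / sqrt(2)` each — the unique equal-channel
#' scaling for which the recombined magnitude `sqrt(re^2 + im^2)` returns
#' the input exactly.
#'
#' @param image a [magnitude_image()] (nonnegative)
#' @return an object of class `complex_image` with fields `real`, `imag`
#' @export
magnitude_to_complex <- function(image) {
  px <- as_pixels(image)
  if (any(px < 0)) {
    stop_nn("nativenoise_parameter_error",
            "magnitude pixels must be nonnegative")
  }
  structure(list(real = px / sqrt(2), imag = px / sqrt(2)),
            class = "complex_image")
}

#' Magnitude of a complex image
#' @param cimg a `complex_image`
#' @return numeric matrix `sqrt(real^2 + imag^2)`
#' @export
complex_magnitude <- function(cimg) {
  sqrt(cimg$real^2 + cimg$imag^2)
}

#' One noise-injection step in the complex domain
#'
#' Adds `rho * n1` and `rho * n2` to the real and imaginary channels, with
#' `n1`, `n2` independent per-pixel draws from zero-mean Gaussians of
#' standard deviation `sigma`. Draws come from R's RNG; seed the session
#' (or use [sim_config()]'s seed via [simulate_native_noise()]) for
#' reproducibility. The input is not mutated.
#'
#' @param cimg a `complex_image`
#' @param config a [sim_config()]
#' @return a new `complex_image`
#' @export
add_noise_step <- function(cimg, config) {
  stopifnot(inherits(config, "sim_config"))
  d <- dim(cimg$real)
  n <- length(cimg$real)
  structure(
    list(real = cimg$real + config$rho *
           matrix(stats::rnorm(n, 0, config$sigma), d[1], d[2]),
         imag = cimg$imag + config$rho *
           matrix(stats::rnorm(n, 0, config$sigma), d[1], d[2])),
    class = "complex_image"
  )
}

#' Simulate a low-field image by iterative native-noise injection
#'
#' The clean magnitude image is lifted to the complex domain
#' ([magnitude_to_complex()]); independent Gaussian noise is then added to
#' the real and imaginary channels in small steps, recombining the
#' magnitude and re-measuring its corner-patch SNR after every step, until
#' the measured SNR falls within the tolerance band of the target
#' (`snr <= target * (1 + tolerance)`). The magnitude background built this
#' way is Rayleigh/Rician — the native noise of single-coil magnitude MRI —
#' unlike Gaussian noise added directly to the magnitude
#' ([simulate_random_noise()]).
#'
#' @param clean a [magnitude_image()] with (near-)noise-free corners
#' @param profile a [noise_profile()] giving the target SNR
#' @param config a [sim_config()]
#' @param corner_fraction corner-patch convention passed to the SNR
#'   estimator
#' @return list with `image` (the simulated [magnitude_image()]), `trace`
#'   (data.frame: iteration, snr_linear, snr_db, noise_std) and
#'   `achieved_snr` (linear)
#' @export
simulate_native_noise <- function(clean, profile, config,
                                  corner_fraction = 0.1) {
  stopifnot(inherits(profile, "noise_profile"), inherits(config, "sim_config"))
  if (config$rho <= 0) {
    stop_nn("nativenoise_parameter_error",
            "iterative simulation needs rho > 0")
  }
  px <- as_pixels(clean)
  target <- profile$target_snr_linear

  # Already at (or noisier than) the target: nothing to inject.
  s0 <- cpp_snr_magnitude(px, corner_fraction)
  if (is.finite(s0[1]) && s0[1] <= target * (1 + config$tolerance)) {
    return(list(image = clean,
                trace = data.frame(iteration = integer(), snr_linear = numeric(),
                                   snr_db = numeric(), noise_std = numeric()),
                achieved_snr = s0[1]))
  }

  res <- with_seed(config$seed, {
    cpp_simulate_native(px, target, config$rho, config$sigma,
                        config$tolerance, config$max_iters, corner_fraction)
  })
  trace <- as.data.frame(res$trace)
  if (!res$converged) {
    stop_nn("nativenoise_convergence_error",
            sprintf("native-noise simulation did not reach SNR %.3f in %d iterations (last SNR %.3f)",
                    target, config$max_iters, trace$snr_linear[nrow(trace)]),
            trace = trace)
  }
  img <- magnitude_image(res$magnitude, spacing = clean$spacing %||% c(1, 1),
                         id = paste0(clean$id %||% "", "_nn"))
  list(image = img, trace = trace,
       achieved_snr = trace$snr_linear[nrow(trace)])
}

#' Simulate a low-field image by direct Gaussian (random) noise addition
#'
#' Adds i.i.d. zero-mean Gaussian noise of standard deviation `noise_std`
#' directly to the magnitude image. No clipping is applied, so pixel values
#' may be negative — the background stays Gaussian, which is precisely how
#' this baseline differs from native-noise simulation.
#'
#' @param clean a [magnitude_image()]
#' @param noise_std nonnegative noise standard deviation
#' @param seed optional seed; if `NULL`, the session RNG stream is used
#' @return a [magnitude_image()] (not validated for nonnegativity)
#' @export
simulate_random_noise <- function(clean, noise_std, seed = NULL) {
  if (!is.numeric(noise_std) || noise_std < 0) {
    stop_nn("nativenoise_parameter_error", "noise_std must be >= 0")
  }
  px <- as_pixels(clean)
  draw <- function() matrix(stats::rnorm(length(px), 0, noise_std),
                            nrow(px), ncol(px))
  noise <- if (is.null(seed)) draw() else with_seed(seed, draw())
  magnitude_image(px + noise, spacing = clean$spacing %||% c(1, 1),
                  id = paste0(clean$id %||% "", "_rn"), validate = FALSE)
}

# Rayleigh distribution helpers (scale parameter sigma).
prayleigh <- function(q, sigma) ifelse(q < 0, 0, 1 - exp(-q^2 / (2 * sigma^2)))

#' Goodness of fit of the background noise distribution
#'
#' Kolmogorov–Smirnov test of the pooled corner-patch pixels against a
#' Rayleigh or Gaussian family with parameters fitted by maximum
#' likelihood (Rayleigh: `sigma^2 = mean(x^2) / 2`; Gaussian: sample mean
#' and population standard deviation). Native-noise backgrounds should fit
#' Rayleigh and reject Gaussian; directly-added Gaussian backgrounds the
#' reverse.
#'
#' @param image a [magnitude_image()] or matrix
#' @param family `"rayleigh"` or `"gaussian"`
#' @param corner_fraction corner-patch convention
#' @return list with `statistic`, `p_value`, `family`, `n`
#' @export
background_distribution_test <- function(image,
                                         family = c("rayleigh", "gaussian"),
                                         corner_fraction = 0.1) {
  family <- match.arg(family)
  x <- corner_pixels(image, corner_fraction)
  if (length(x) < 200) {
    stop_nn("nativenoise_parameter_error",
            sprintf("need >= 200 corner pixels, got %d", length(x)))
  }
  kt <- if (family == "rayleigh") {
    sigma <- sqrt(mean(x^2) / 2)
    suppressWarnings(stats::ks.test(x, prayleigh, sigma = sigma))
  } else {
    suppressWarnings(stats::ks.test(x, "pnorm", mean = mean(x), sd = pop_sd(x)))
  }
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       family = family, n = length(x))
}
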