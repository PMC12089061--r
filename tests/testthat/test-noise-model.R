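test_that("corner noise estimation follows the pooled population-sd convention", {
  z <- matrix(0, 64, 64)
  expect_identical(estimate_noise_std(z), 0)

  # alternating +/-1 checkerboard in the corners: mean 0, population sd 1
  side <- corner_patch_side(z)
  checker <- outer(1:side, 1:side, function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
  m <- z
  m[1:side, 1:side] <- checker
  m[1:side, 65 - side:1] <- checker
  m[65 - side:1, 1:side] <- checker
  m[65 - side:1, 65 - side:1] <- checker
  expect_equal(estimate_noise_std(m), 1.0, tolerance = 1e-12)

  # seeded Gaussian corners recover the generating sigma
  set.seed(31)
  g <- matrix(rnorm(256 * 256, 0, 0.04), 256, 256)  # corners are what counts
  expect_lt(abs(estimate_noise_std(g) - 0.04) / 0.04, 0.05)
  expect_gte(length(corner_pixels(g)), 2500)

  expect_error(corner_patch_side(z, 0.3), class = "nativenoise_parameter_error")
})

test_that("SNR estimation matches closed form and flags noise-free images", {
  m <- matrix(0, 100, 100)
  side <- corner_patch_side(m)
  checker <- outer(1:side, 1:side, function(i, j) ifelse((i + j) %% 2 == 0, 2, -2))
  for (r in list(1:side, 101 - side:1)) {
    for (cc in list(1:side, 101 - side:1)) m[r, cc] <- checker
  }
  m[31:70, 31:70] <- 10
  roi <- matrix(FALSE, 100, 100)
  roi[31:70, 31:70] <- TRUE
  s <- estimate_snr(m, roi = roi)
  expect_equal(s$snr_linear, 5, tolerance = 1e-12)
  expect_equal(s$snr_db, 20 * log10(5), tolerance = 1e-9)
  expect_equal(s$noise_std, 2, tolerance = 1e-12)

  expect_error(estimate_snr(fixture_clean_brain(64, 2)),
               class = "nativenoise_noise_free_error")
  expect_error(estimate_snr(m, roi = matrix(FALSE, 100, 100)),
               class = "nativenoise_parameter_error")
})

test_that("SNR of a noisy disk matches a Monte-Carlo resampling oracle", {
  set.seed(12)
  n <- 256
  g <- coords <- seq(-1, 1, length.out = n)
  r2 <- outer(g^2, g^2, `+`)
  disk <- ifelse(r2 <= 0.6^2, 1, 0)
  sig <- 0.05
  mag <- sqrt((disk / sqrt(2) + matrix(rnorm(n * n, 0, sig), n, n))^2 +
                (disk / sqrt(2) + matrix(rnorm(n * n, 0, sig), n, n))^2)
  est <- estimate_snr(mag)

  # oracle: background magnitudes are Rayleigh; resample their sd
  bg <- sqrt(rnorm(10000, 0, sig)^2 + rnorm(10000, 0, sig)^2)
  oracle_snr <- 1.0 / sqrt(mean((bg - mean(bg))^2))
  expect_lt(abs(est$snr_linear - oracle_snr) / oracle_snr, 0.10)
  # Rayleigh sd ~ 0.655 sigma
  expect_lt(abs(est$noise_std - 0.655 * sig) / (0.655 * sig), 0.10)
})

test_that("magnitude-to-complex lifting is an exact round trip", {
  const <- magnitude_image(matrix(1, 32, 32))
  ci <- magnitude_to_complex(const)
  expect_equal(ci$real[1, 1], 1 / sqrt(2), tolerance = 1e-12)
  expect_identical(ci$real, ci$imag)
  expect_lt(max(abs(complex_magnitude(ci) - 1)), 1e-9)

  zi <- magnitude_to_complex(magnitude_image(matrix(0, 16, 16)))
  expect_true(all(zi$real == 0) && all(zi$imag == 0))

  img <- fixture_clean_brain(64, 3)
  expect_lt(max(abs(complex_magnitude(magnitude_to_complex(img)) -
                      img$pixels)), 1e-9)

  expect_error(magnitude_to_complex(matrix(-1, 16, 16)),
               class = "nativenoise_parameter_error")
})

test_that("noise steps add the configured per-channel variance", {
  ci <- magnitude_to_complex(magnitude_image(matrix(0, 256, 256)))

  expect_identical(add_noise_step(ci, sim_config(rho = 0))$real, ci$real)

  set.seed(5)
  one <- add_noise_step(ci, sim_config(rho = 1, sigma = 1))
  expect_lt(abs(sd(one$real) - 1), 0.03)
  expect_lt(abs(sd(one$imag) - 1), 0.03)
  expect_lt(abs(mean(one$real)), 0.02)

  two <- add_noise_step(one, sim_config(rho = 1, sigma = 1))
  expect_lt(abs(sd(two$real) - sqrt(2)) / sqrt(2), 0.03)
})

test_that("native-noise simulation converges, stops early when possible, and is seeded", {
  prof <- noise_profile(5, 0.1)
  clean <- fixture_clean_brain(128, 4)
  r1 <- simulate_native_noise(clean, prof, sim_config(seed = 9))
  expect_lt(abs(r1$achieved_snr - 5) / 5, 0.10)
  expect_true(all(r1$image$pixels >= 0))

  # bit-identical under the same seed
  r2 <- simulate_native_noise(clean, prof, sim_config(seed = 9))
  expect_identical(r1$image$pixels, r2$image$pixels)
  expect_identical(r1$trace, r2$trace)

  # an input already at the target returns unchanged after 0 iterations
  r0 <- simulate_native_noise(r1$image, prof, sim_config(seed = 1))
  expect_identical(r0$image$pixels, r1$image$pixels)
  expect_identical(nrow(r0$trace), 0L)

  # non-convergence carries the trace
  err <- tryCatch(simulate_native_noise(clean, prof,
                                        sim_config(max_iters = 5, seed = 2)),
                  nativenoise_convergence_error = function(e) e)
  expect_s3_class(err, "nativenoise_convergence_error")
  expect_identical(nrow(err$trace), 5L)

  expect_error(simulate_native_noise(clean, prof, sim_config(rho = 0)),
               class = "nativenoise_parameter_error")
})

test_that("the per-iteration SNR trace decreases", {
  tr <- fixture_native_sim()$trace
  expect_gt(nrow(tr), 100)
  slope <- coef(lm(snr_linear ~ iteration, data = tr))[["iteration"]]
  expect_lt(slope, 0)
})

test_that("random-noise simulation is Gaussian, unclipped, and seeded", {
  clean <- magnitude_image(matrix(0, 256, 256))
  expect_identical(simulate_random_noise(clean, 0, seed = 1)$pixels,
                   clean$pixels)
  noisy <- simulate_random_noise(clean, 1, seed = 3)
  expect_lt(abs(mean(noisy$pixels)), 0.02)
  expect_lt(abs(pop_sd_test(noisy$pixels) - 1), 0.03)
  expect_true(any(noisy$pixels < 0))  # no clipping
  expect_identical(noisy$pixels, simulate_random_noise(clean, 1, seed = 3)$pixels)
})

test_that("background distributions separate native (Rayleigh) from random (Gaussian) noise", {
  nn <- fixture_native_sim()$image
  rn <- fixture_random_sim()
  expect_gte(length(corner_pixels(nn)), 2500)

  expect_gt(background_distribution_test(nn, "rayleigh")$p_value, 0.01)
  expect_lt(background_distribution_test(nn, "gaussian")$p_value, 0.01)
  expect_gt(background_distribution_test(rn, "gaussian")$p_value, 0.01)
  expect_lt(background_distribution_test(rn, "rayleigh")$p_value, 0.01)

  # sampling oracle: synthetic corner draws of known family
  set.seed(21)
  ray <- matrix(sqrt(rnorm(256^2, 0, 1)^2 + rnorm(256^2, 0, 1)^2), 256, 256)
  gau <- matrix(rnorm(256^2), 256, 256)
  expect_gt(background_distribution_test(ray, "rayleigh")$p_value, 0.01)
  expect_lt(background_distribution_test(gau, "rayleigh")$p_value, 0.01)

  expect_error(background_distribution_test(matrix(1, 16, 16), "rayleigh"),
               class = "nativenoise_parameter_error")
})
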