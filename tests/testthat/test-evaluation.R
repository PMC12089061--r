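test_that("MSE and PSNR match their closed forms and brute-force sums", {
  a <- matrix(0, 8, 8)
  b <- matrix(1, 8, 8)
  expect_identical(mse(a, a), 0)
  expect_identical(mse(b, a), 1)
  expect_error(mse(a, matrix(0, 8, 9)), class = "nativenoise_parameter_error")

  set.seed(1)
  x <- matrix(runif(20 * 20), 20, 20)
  y <- matrix(runif(20 * 20), 20, 20)
  expect_lt(abs(mse(x, y) - mse_brute(x, y)), 1e-12)

  # PSNR closed forms: max 1 with MSE 0.01 -> 20 dB; MSE 1 -> 0 dB
  t1 <- matrix(c(1, rep(0, 99)), 10, 10)
  p1 <- t1 + 0.1
  expect_equal(mse(p1, t1), 0.01, tolerance = 1e-12)
  expect_equal(psnr(p1, t1), 20, tolerance = 1e-9)
  expect_equal(psnr(t1 + 1, t1), 0, tolerance = 1e-9)
  expect_equal(psnr(x, y), 10 * log10(max(y)^2 / mse_brute(x, y)),
               tolerance = 1e-9)
  expect_error(psnr(t1, t1), class = "nativenoise_infinite_psnr")
})

test_that("SSIM satisfies its identities and matches a brute-force sliding window", {
  set.seed(2)
  x <- matrix(runif(24 * 24), 24, 24)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)

  # constants with a global uniform window: sigma terms collapse
  a <- matrix(0.5, 16, 16)
  b <- matrix(0.25, 16, 16)
  got <- ssim(a, b, window_size = 16, window_sigma = NULL)
  C1 <- 0.01^2
  expect_equal(got, (2 * 0.5 * 0.25 + C1) / (0.5^2 + 0.25^2 + C1),
               tolerance = 1e-12)

  y <- x + matrix(rnorm(24 * 24, 0, 0.1), 24, 24)
  expect_lt(abs(ssim(x, y) - ssim_brute(x, y)), 1e-9)
})

test_that("SNR gain composes from the two SNR estimates", {
  set.seed(3)
  m <- matrix(0, 64, 64)
  m[24:40, 24:40] <- 1
  noise <- matrix(rnorm(64 * 64, 0, 0.04), 64, 64)
  side <- corner_patch_side(m)
  cmask <- matrix(FALSE, 64, 64)
  cmask[1:side, 1:side] <- TRUE
  cmask[1:side, 65 - side:1] <- TRUE
  cmask[65 - side:1, 1:side] <- TRUE
  cmask[65 - side:1, 65 - side:1] <- TRUE
  img1 <- m + noise * cmask
  img2 <- m + noise * cmask * 0.5  # noise halved, signal untouched

  expect_identical(snr_gain(img1, img1), 0)
  expect_equal(snr_gain(img1, img2), 20 * log10(2), tolerance = 1e-9)
  expect_equal(snr_gain(img1, img2),
               estimate_snr(img2)$snr_db - estimate_snr(img1)$snr_db,
               tolerance = 1e-12)
})

test_that("the paired t-test matches its closed form and flags degenerate input", {
  r <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_identical(r$t, 0)
  expect_identical(r$p, 1)

  # differences {1,2,3}: t = mean/sd * sqrt(n) = 2sqrt(3)
  r2 <- paired_ttest(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r2$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r2$p, 2 * pt(2 * sqrt(3), df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r2$mean_diff, 2, tolerance = 1e-12)

  expect_error(paired_ttest(c(2, 3, 4), c(1, 2, 3)),
               class = "nativenoise_degenerate_test")
  expect_error(paired_ttest(1, 1), class = "nativenoise_parameter_error")
})

test_that("difference maps and line profiles behave as advertised", {
  x <- matrix(runif(64), 8, 8)
  expect_true(all(difference_map(x, x)$raw == 0))
  d <- difference_map(x + 0.3, x)
  expect_equal(max(abs(d$raw - 0.3)), 0, tolerance = 1e-12)
  expect_true(all(d$normalized >= 0 & d$normalized <= 1))

  const <- matrix(2, 16, 16)
  expect_identical(line_profile(const, row = 4), rep(2, 16))

  step <- cbind(matrix(0, 16, 8), matrix(1, 16, 8))
  p <- line_profile(step, row = 8)
  expect_identical(sum(diff(p) != 0), 1L)
  expect_identical(profile_edge_sharpness(p), 1)
  expect_identical(profile_edge_sharpness(p), max(abs(diff(p))))

  expect_error(line_profile(step, row = 99),
               class = "nativenoise_parameter_error")
  path <- cbind(1:20, 1:20)
  expect_error(line_profile(step, path = path),
               class = "nativenoise_parameter_error")
})

test_that("method reports recompute from their per-slice records", {
  ck <- fixture_tiny_ckpt()
  slices <- make_test_slices(3, slices_per_volume = 1, size = 64, seed = 31)
  rep <- evaluate_methods(list(a = ck, b = ck), slices)

  # identical methods: zero improvement, p = 1
  expect_equal(rep$comparisons$pct_improvement, 0, tolerance = 1e-12)
  expect_identical(rep$comparisons$p, 1)
  expect_identical(rep$comparisons$t, 0)

  # every aggregate cell recomputes from the per-slice records
  for (m in c("a", "b")) {
    d <- rep$per_slice[rep$per_slice$method == m, ]
    agg <- rep$aggregate[rep$aggregate$method == m, ]
    for (col in c("snr_in_db", "snr_out_db", "gain_db", "psnr", "ssim")) {
      n <- nrow(d)
      half <- qt(0.975, n - 1) * sd(d[[col]]) / sqrt(n)
      expect_equal(agg[[paste0(col, "_mean")]], mean(d[[col]]),
                   tolerance = 1e-12)
      expect_equal(agg[[paste0(col, "_lo")]], mean(d[[col]]) - half,
                   tolerance = 1e-12)
      expect_equal(agg[[paste0(col, "_hi")]], mean(d[[col]]) + half,
                   tolerance = 1e-12)
      expect_lte(agg[[paste0(col, "_lo")]], agg[[paste0(col, "_mean")]])
    }
    expect_equal(d$gain_db, d$snr_out_db - d$snr_in_db, tolerance = 1e-12)
  }

  dir <- withr::local_tempdir()
  write_metric_report(rep, dir)
  expect_true(file.exists(file.path(dir, "per_slice.csv")))
  expect_true(file.exists(file.path(dir, "aggregate.json")))
})
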