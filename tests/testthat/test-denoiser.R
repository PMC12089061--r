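test_that("channel widths double per level and parameters match the closed-form count", {
  cfg <- unet_config(8, 4, 64)
  expect_identical(unet_channels(cfg), c(8L, 16L, 32L, 64L, 128L))

  # independent count: sum over blocks of k^2*Cin*Cout + Cout
  conv_n <- function(k, cin, cout) k * k * cin * cout + cout
  ch <- c(8, 16, 32, 64)
  expected <- 0
  cin <- 1
  for (c_d in ch) {
    expected <- expected + conv_n(3, cin, c_d) + conv_n(3, c_d, c_d)
    cin <- c_d
  }
  expected <- expected + conv_n(3, 64, 128) + conv_n(3, 128, 128)
  above <- 128
  for (c_d in rev(ch)) {
    expected <- expected + conv_n(2, above, c_d) +
      conv_n(3, 2 * c_d, c_d) + conv_n(3, c_d, c_d)
    above <- c_d
  }
  expected <- expected + conv_n(1, 8, 1)
  expect_equal(unet_n_params(build_unet(cfg, seed = 1)), expected)

  expect_error(unet_config(8, 4, 60), class = "nativenoise_parameter_error")
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- unet_config(2, 1, 8)
  m <- build_unet(cfg, seed = 3)
  set.seed(13)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  target <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  lossfn <- function(pp) {
    mean((nativenoise:::unet_forward(list(config = cfg, params = pp), x) -
            target)^2)
  }
  fwd <- nativenoise:::unet_forward(m, x, keep_cache = TRUE)
  bw <- nativenoise:::unet_backward(m, fwd$cache,
                                    2 * (fwd$y - target) / length(target))
  base <- lossfn(m$params)
  for (nm in names(m$params)) {
    for (k in sample(length(m$params[[nm]]), min(2, length(m$params[[nm]])))) {
      pp <- m$params
      pp[[nm]][k] <- pp[[nm]][k] + 1e-6
      numeric_grad <- (lossfn(pp) - base) / 1e-6
      expect_lt(abs(numeric_grad - bw$grads[[nm]][k]) /
                  max(1e-6, abs(numeric_grad) + abs(bw$grads[[nm]][k])),
                1e-3)
    }
  }
  # input gradient (the quantity the ERF map is built from)
  xb <- x
  xb[3, 4, 1, 1] <- xb[3, 4, 1, 1] + 1e-6
  numeric_dx <- (mean((nativenoise:::unet_forward(m, xb) - target)^2) - base) / 1e-6
  expect_lt(abs(numeric_dx - bw$dx[3, 4, 1, 1]) /
              (abs(numeric_dx) + abs(bw$dx[3, 4, 1, 1])), 1e-3)
})

test_that("training reduces loss, selects the best-validation epoch, and is reproducible", {
  set.seed(77)
  n <- 32
  clean <- array(abs(rnorm(16 * 16 * n, 0.5, 0.1)), c(16, 16, n))
  noisy <- clean + array(rnorm(16 * 16 * n, 0, 0.15), c(16, 16, n))
  ts <- structure(list(noisy = noisy[, , 1:24], clean = clean[, , 1:24],
                       meta = NULL, patch_size = 16L, split = "train"),
                  class = "paired_patch_set")
  vs <- structure(list(noisy = noisy[, , 25:32], clean = clean[, , 25:32],
                       meta = NULL, patch_size = 16L, split = "val"),
                  class = "paired_patch_set")
  tc <- train_config(max_epochs = 30, batch_size = 8, seed = 4)
  ck <- train_denoiser(build_unet(unet_config(4, 2, 16), seed = 4), ts, vs, tc)
  h <- ck$history
  expect_identical(nrow(h), 30L)
  expect_lt(h$train_loss[30], h$train_loss[1])
  expect_identical(ck$best_epoch, which.max(h$val_psnr))
  expect_gte(max(h$val_psnr), h$val_psnr[nrow(h)])

  ck2 <- train_denoiser(build_unet(unet_config(4, 2, 16), seed = 4), ts, vs, tc)
  expect_identical(ck$history, ck2$history)
  expect_identical(ck$weights, ck2$weights)
})

test_that("inference preserves shape for any valid size and matches the patch path", {
  ck <- fixture_tiny_ckpt()

  img64 <- magnitude_image(matrix(abs(rnorm(64 * 64, 0.5, 0.1)), 64, 64))
  expect_identical(dim(denoise_image(ck, img64)$pixels), c(64L, 64L))

  # not divisible by 2^depth: mirror-pad then crop
  img100 <- magnitude_image(matrix(abs(rnorm(100 * 100, 0.5, 0.1)), 100, 100))
  out <- denoise_image(ck, img100)
  expect_identical(dim(out$pixels), c(100L, 100L))
  expect_true(all(is.finite(out$pixels)))

  # full-image inference on an already-divisible input is the plain forward pass
  x <- array(img64$pixels, c(64, 64, 1, 1))
  direct <- nativenoise:::unet_forward(nativenoise:::ckpt_model(ck), x)
  expect_identical(denoise_image(ck, img64)$pixels, direct[, , 1, 1])

  deep <- build_unet(unet_config(2, 5, 32), seed = 1)
  ck5 <- structure(list(weights = deep$params, unet_config = deep$config,
                        train_config = train_config(), history = NULL,
                        best_epoch = 0L), class = "nn_checkpoint")
  expect_error(denoise_image(ck5, magnitude_image(matrix(0.5, 16, 16))),
               class = "nativenoise_parameter_error")
})

test_that("checkpoints reload to bit-identical predictors", {
  ck <- fixture_tiny_ckpt()
  probe <- magnitude_image(matrix(abs(rnorm(32 * 32, 0.5, 0.1)), 32, 32))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  ck2 <- load_checkpoint(path)
  expect_identical(denoise_image(ck, probe)$pixels,
                   denoise_image(ck2, probe)$pixels)
})

test_that("the effective receptive field behaves like the backpropagated gradient it is", {
  # all-zero weights: zero gradient map
  m <- build_unet(unet_config(4, 2, 16), seed = 1)
  m$params <- lapply(m$params, function(p) p * 0)
  ck0 <- structure(list(weights = m$params, unet_config = m$config,
                        train_config = train_config(), history = NULL,
                        best_epoch = 0L), class = "nn_checkpoint")
  img <- magnitude_image(matrix(abs(rnorm(32 * 32, 0.5, 0.1)), 32, 32))
  expect_true(all(compute_erf(ck0, img, c(16, 16)) == 0))

  # a single 3x3 averaging convolution: gradient support is exactly the window
  x <- array(rnorm(64), c(8, 8, 1, 1))
  w <- array(1 / 9, c(3, 3, 1, 1))
  dy <- array(0, c(8, 8, 1, 1))
  dy[4, 5, 1, 1] <- 1
  dx <- nativenoise:::cpp_conv2d_backward(x, w, dy)$dx[, , 1, 1]
  expected <- matrix(0, 8, 8)
  expected[3:5, 4:6] <- 1 / 9
  expect_equal(dx, expected, tolerance = 1e-12)

  # random-weight U-Net: strongest response within the theoretical radius
  ck <- fixture_tiny_ckpt()
  img64 <- magnitude_image(matrix(abs(rnorm(64 * 64, 0.5, 0.1)), 64, 64))
  erf <- compute_erf(ck, img64, c(32, 32))
  expect_identical(max(erf), 1)
  peak <- which(erf == max(erf), arr.ind = TRUE)[1, ]
  r <- receptive_field_radius(ck$unet_config)
  expect_lte(max(abs(peak - c(32, 32))), r)

  expect_error(compute_erf(ck, img64, c(100, 2)),
               class = "nativenoise_parameter_error")
})
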