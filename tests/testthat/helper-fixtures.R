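pop_sd_test <- function(x) sqrt(mean((x - mean(x))^2))

# Shared fixtures, built once per test run and memoized; everything is
# generated in code from seeds.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

fixture_clean_brain <- function(size = 256, seed = 1) {
  memo(sprintf("brain_%d_%d", size, seed),
       make_clean_image(synthetic_spec("brain_like", size, seed = seed)))
}

# In-vivo-like native-noise simulation of a 256^2 brain slice (2500 corner
# pixels), reused by the distribution and trace tests.
fixture_native_sim <- function() {
  memo("native_sim",
       simulate_native_noise(fixture_clean_brain(),
                             lf_noise_profiles()$invivo,
                             sim_config(seed = 11)))
}

fixture_random_sim <- function() {
  memo("random_sim",
       simulate_random_noise(fixture_clean_brain(), noise_std = 0.12,
                             seed = 7))
}

# A genuinely trained (if briefly) small checkpoint for report/shape tests.
fixture_tiny_ckpt <- function() {
  memo("tiny_ckpt", {
    set.seed(42)
    n <- 24
    clean <- array(abs(rnorm(16 * 16 * n, 0.5, 0.1)), c(16, 16, n))
    noisy <- clean + array(rnorm(16 * 16 * n, 0, 0.1), c(16, 16, n))
    ts <- structure(list(noisy = noisy[, , 1:16], clean = clean[, , 1:16],
                         meta = NULL, patch_size = 16L, split = "train"),
                    class = "paired_patch_set")
    vs <- structure(list(noisy = noisy[, , 17:24], clean = clean[, , 17:24],
                         meta = NULL, patch_size = 16L, split = "val"),
                    class = "paired_patch_set")
    train_denoiser(build_unet(unet_config(4, 2, 16), seed = 5), ts, vs,
                   train_config(max_epochs = 3, seed = 5))
  })
}

# Paired slices for dataset tests: clean synthetic slices with cheap
# Gaussian noise (the patch machinery is noise-agnostic).
make_test_slices <- function(n_volumes, slices_per_volume = 1, size = 64,
                             seed = 0) {
  out <- list()
  for (v in seq_len(n_volumes)) {
    vol <- make_volume(synthetic_spec("brain_like", size, seed = seed + v),
                       slices_per_volume)
    for (s in seq_along(vol)) {
      noisy <- simulate_random_noise(vol[[s]], 0.05,
                                     seed = seed + 97 * v + s)
      out[[length(out) + 1]] <-
        paired_slice(vol[[s]], noisy, volume_id = sprintf("vol%02d", v),
                     slice_index = s)
    }
  }
  out
}
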