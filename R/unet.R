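#' U-Net architecture configuration
#'
#' A compact encoder-decoder with skip connections: `depth` pooling levels,
#' `base_channels` in the first convolution block and channel doubling
#' after every pooling. Blocks are two 3x3 same-padding convolutions with
#' ReLU; downsampling is 2x2 max pooling; upsampling is a 2x2 transposed
#' convolution; a final 1x1 convolution maps back to one channel with a
#' linear output. The default (base 8, depth 4) is the original U-Net
#' scaled down by a factor of 8 in channel width, sized for 64 x 64
#' training patches.
#'
#' @param base_channels channels of the first block (>= 1)
#' @param depth number of pooling levels (>= 1)
#' @param in_size training patch side; must be divisible by `2^depth`
#' @return an object of class `unet_config`
#' @export
unet_config <- function(base_channels = 8, depth = 4, in_size = 64) {
  if (base_channels < 1 || depth < 1) {
    stop_nn("nativenoise_parameter_error",
            "base_channels and depth must be >= 1")
  }
  if (in_size %% 2^depth != 0) {
    stop_nn("nativenoise_parameter_error",
            sprintf("in_size %d is not divisible by 2^depth = %d",
                    in_size, 2^depth))
  }
  structure(list(base_channels = as.integer(base_channels),
                 depth = as.integer(depth), in_size = as.integer(in_size)),
            class = "unet_config")
}

#' Encoder channel sequence of a U-Net configuration
#'
#' `base * 2^(level-1)` for the encoder levels, with the bottleneck at
#' `base * 2^depth`.
#' @param config a [unet_config()]
#' @return integer vector of length `depth + 1` (encoder levels then
#'   bottleneck)
#' @export
unet_channels <- function(config) {
  as.integer(config$base_channels * 2^(0:config$depth))
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

#' Build a U-Net denoising autoencoder
#'
#' Initializes all weights (He-normal, zero biases) under `seed`.
#'
#' @param config a [unet_config()]
#' @param seed integer seed for the weight initialization
#' @return an object of class `unet_model`: `config` plus a flat named
#'   list `params`
#' @export
build_unet <- function(config, seed = 0) {
  stopifnot(inherits(config, "unet_config"))
  ch <- unet_channels(config)
  D <- config$depth
  params <- with_seed(seed, {
    p <- list()
    cin <- 1L
    for (d in seq_len(D)) {
      cd <- ch[d]
      p[[sprintf("enc%d_c1_w", d)]] <- he_init(c(3, 3, cin, cd), 9 * cin)
      p[[sprintf("enc%d_c1_b", d)]] <- numeric(cd)
      p[[sprintf("enc%d_c2_w", d)]] <- he_init(c(3, 3, cd, cd), 9 * cd)
      p[[sprintf("enc%d_c2_b", d)]] <- numeric(cd)
      cin <- cd
    }
    cb <- ch[D + 1]
    p[["bot_c1_w"]] <- he_init(c(3, 3, cin, cb), 9 * cin)
    p[["bot_c1_b"]] <- numeric(cb)
    p[["bot_c2_w"]] <- he_init(c(3, 3, cb, cb), 9 * cb)
    p[["bot_c2_b"]] <- numeric(cb)
    above <- cb
    for (d in rev(seq_len(D))) {
      cd <- ch[d]
      p[[sprintf("dec%d_up_w", d)]] <- he_init(c(2, 2, above, cd), 4 * above)
      p[[sprintf("dec%d_up_b", d)]] <- numeric(cd)
      p[[sprintf("dec%d_c1_w", d)]] <- he_init(c(3, 3, 2 * cd, cd), 9 * 2 * cd)
      p[[sprintf("dec%d_c1_b", d)]] <- numeric(cd)
      p[[sprintf("dec%d_c2_w", d)]] <- he_init(c(3, 3, cd, cd), 9 * cd)
      p[[sprintf("dec%d_c2_b", d)]] <- numeric(cd)
      above <- cd
    }
    p[["out_w"]] <- he_init(c(1, 1, ch[1], 1), ch[1])
    p[["out_b"]] <- numeric(1)
    p
  })
  structure(list(config = config, params = params), class = "unet_model")
}

#' Number of trainable parameters
#' @param model a `unet_model` or checkpoint
#' @export
unet_n_params <- function(model) {
  p <- if (!is.null(model$params)) model$params else model$weights
  sum(vapply(p, length, 0L))
}

relu <- function(z) {
  z[z < 0] <- 0
  z
}

concat_channels <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' Forward pass of the U-Net
#'
#' @param model a `unet_model`
#' @param x input array (H, W, 1, N) with H and W divisible by `2^depth`
#' @param keep_cache retain intermediate activations for a backward pass
#' @return output array of the same shape; with `keep_cache = TRUE`, a
#'   list `(y, cache)`
#' @keywords internal
unet_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  D <- model$config$depth
  cc <- list(x = x, skip = vector("list", D), idx = vector("list", D),
             enc_in = vector("list", D), enc_z1 = vector("list", D),
             enc_z2 = vector("list", D), dec_cat = vector("list", D),
             dec_z1 = vector("list", D), dec_z2 = vector("list", D),
             dec_in = vector("list", D))
  h <- x
  for (d in seq_len(D)) {
    cc$enc_in[[d]] <- h
    z1 <- cpp_conv2d_forward(h, p[[sprintf("enc%d_c1_w", d)]],
                             p[[sprintf("enc%d_c1_b", d)]])
    a1 <- relu(z1)
    z2 <- cpp_conv2d_forward(a1, p[[sprintf("enc%d_c2_w", d)]],
                             p[[sprintf("enc%d_c2_b", d)]])
    a2 <- relu(z2)
    cc$enc_z1[[d]] <- z1
    cc$enc_z2[[d]] <- z2
    cc$skip[[d]] <- a2
    mp <- cpp_maxpool2_forward(a2)
    cc$idx[[d]] <- mp$idx
    h <- mp$y
  }
  cc$bot_in <- h
  z1 <- cpp_conv2d_forward(h, p$bot_c1_w, p$bot_c1_b)
  a1 <- relu(z1)
  z2 <- cpp_conv2d_forward(a1, p$bot_c2_w, p$bot_c2_b)
  h <- relu(z2)
  cc$bot_z1 <- z1
  cc$bot_z2 <- z2
  for (d in rev(seq_len(D))) {
    cc$dec_in[[d]] <- h
    up <- cpp_upconv2_forward(h, p[[sprintf("dec%d_up_w", d)]],
                              p[[sprintf("dec%d_up_b", d)]])
    cat_ <- concat_channels(cc$skip[[d]], up)
    cc$dec_cat[[d]] <- cat_
    z1 <- cpp_conv2d_forward(cat_, p[[sprintf("dec%d_c1_w", d)]],
                             p[[sprintf("dec%d_c1_b", d)]])
    a1 <- relu(z1)
    z2 <- cpp_conv2d_forward(a1, p[[sprintf("dec%d_c2_w", d)]],
                             p[[sprintf("dec%d_c2_b", d)]])
    h <- relu(z2)
    cc$dec_z1[[d]] <- z1
    cc$dec_z2[[d]] <- z2
  }
  cc$out_in <- h
  y <- cpp_conv2d_forward(h, p$out_w, p$out_b)
  if (keep_cache) list(y = y, cache = cc) else y
}

# Backward pass: returns list(grads = named list matching params,
# dx = gradient w.r.t. the input array).
unet_backward <- function(model, cache, dy) {
  p <- model$params
  D <- model$config$depth
  g <- list()
  bw <- cpp_conv2d_backward(cache$out_in, p$out_w, dy)
  g$out_w <- bw$dw
  g$out_b <- bw$db
  dh <- bw$dx
  dskip <- vector("list", D)
  for (d in seq_len(D)) {  # decoder ran D..1, so invert 1..D
    dz2 <- dh * (cache$dec_z2[[d]] > 0)
    bw <- cpp_conv2d_backward(relu(cache$dec_z1[[d]]),
                              p[[sprintf("dec%d_c2_w", d)]], dz2)
    g[[sprintf("dec%d_c2_w", d)]] <- bw$dw
    g[[sprintf("dec%d_c2_b", d)]] <- bw$db
    dz1 <- bw$dx * (cache$dec_z1[[d]] > 0)
    bw <- cpp_conv2d_backward(cache$dec_cat[[d]],
                              p[[sprintf("dec%d_c1_w", d)]], dz1)
    g[[sprintf("dec%d_c1_w", d)]] <- bw$dw
    g[[sprintf("dec%d_c1_b", d)]] <- bw$db
    dcat <- bw$dx
    cd <- dim(cache$skip[[d]])[3]
    dskip[[d]] <- dcat[, , seq_len(cd), , drop = FALSE]
    dup <- dcat[, , cd + seq_len(dim(dcat)[3] - cd), , drop = FALSE]
    dim(dup) <- c(dim(dcat)[1], dim(dcat)[2], dim(dcat)[3] - cd, dim(dcat)[4])
    bw <- cpp_upconv2_backward(cache$dec_in[[d]],
                               p[[sprintf("dec%d_up_w", d)]], dup)
    g[[sprintf("dec%d_up_w", d)]] <- bw$dw
    g[[sprintf("dec%d_up_b", d)]] <- bw$db
    dh <- bw$dx
  }
  dz2 <- dh * (cache$bot_z2 > 0)
  bw <- cpp_conv2d_backward(relu(cache$bot_z1), p$bot_c2_w, dz2)
  g$bot_c2_w <- bw$dw
  g$bot_c2_b <- bw$db
  dz1 <- bw$dx * (cache$bot_z1 > 0)
  bw <- cpp_conv2d_backward(cache$bot_in, p$bot_c1_w, dz1)
  g$bot_c1_w <- bw$dw
  g$bot_c1_b <- bw$db
  dh <- bw$dx
  for (d in rev(seq_len(D))) {
    da2 <- cpp_maxpool2_backward(dh, cache$idx[[d]],
                                 dim(cache$skip[[d]])) + dskip[[d]]
    dz2 <- da2 * (cache$enc_z2[[d]] > 0)
    bw <- cpp_conv2d_backward(relu(cache$enc_z1[[d]]),
                              p[[sprintf("enc%d_c2_w", d)]], dz2)
    g[[sprintf("enc%d_c2_w", d)]] <- bw$dw
    g[[sprintf("enc%d_c2_b", d)]] <- bw$db
    dz1 <- bw$dx * (cache$enc_z1[[d]] > 0)
    bw <- cpp_conv2d_backward(cache$enc_in[[d]],
                              p[[sprintf("enc%d_c1_w", d)]], dz1)
    g[[sprintf("enc%d_c1_w", d)]] <- bw$dw
    g[[sprintf("enc%d_c1_b", d)]] <- bw$db
    dh <- bw$dx
  }
  list(grads = g, dx = dh)
}

#' Training configuration
#'
#' Adam with its default learning rate 0.001 and batch size 64; model
#' selection is fixed to the epoch with the highest validation PSNR.
#'
#' @param learning_rate positive Adam step size
#' @param batch_size minibatch size (>= 1)
#' @param max_epochs epochs to train (no early stopping)
#' @param seed integer seed for shuffling (weight init is seeded in
#'   [build_unet()])
#' @return an object of class `train_config`
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64,
                         max_epochs = 30, seed = 0) {
  if (learning_rate <= 0) {
    stop_nn("nativenoise_parameter_error", "learning_rate must be > 0")
  }
  if (batch_size < 1 || max_epochs < 1) {
    stop_nn("nativenoise_parameter_error",
            "batch_size and max_epochs must be >= 1")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed),
                 selection_metric = "val_psnr"),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

as_batch <- function(patches, sel) {
  x <- patches[, , sel, drop = FALSE]
  array(x, c(dim(x)[1], dim(x)[2], 1, dim(x)[3]))
}

# Mean per-patch PSNR of model predictions on a patch set; the peak is
# each clean patch's own maximum. Patches with an all-zero truth (pure
# background, PSNR undefined) or zero error are excluded from the mean.
val_psnr <- function(model, set, batch = 64) {
  n <- dim(set$noisy)[3]
  vals <- rep(NA_real_, n)
  for (start in seq(1, n, by = batch)) {
    sel <- start:min(start + batch - 1, n)
    y <- unet_forward(model, as_batch(set$noisy, sel))
    for (j in seq_along(sel)) {
      truth <- set$clean[, , sel[j]]
      m <- mean((y[, , 1, j] - truth)^2)
      mx <- max(truth)
      if (mx > 0 && m > 0) vals[sel[j]] <- 10 * log10(mx^2 / m)
    }
  }
  vals <- vals[is.finite(vals)]
  if (!length(vals)) {
    stop_nn("nativenoise_training_error",
            "no validation patch has nonempty ground truth")
  }
  mean(vals)
}

#' Train the U-Net denoiser
#'
#' Minimizes the pixel-wise MSE between predictions and clean patches with
#' Adam; records per-epoch training loss and validation PSNR and returns
#' the weights of the epoch with the highest validation PSNR.
#'
#' @param model a [build_unet()] model
#' @param train_set,val_set [extract_patches()] sets (nonempty)
#' @param config a [train_config()]
#' @return an object of class `nn_checkpoint`: `weights`, `unet_config`,
#'   `train_config`, `history` (data.frame: epoch, train_loss, val_psnr)
#'   and `best_epoch`
#' @export
train_denoiser <- function(model, train_set, val_set, config) {
  stopifnot(inherits(model, "unet_model"), inherits(config, "train_config"))
  n <- dim(train_set$noisy)[3]
  if (n < 1 || dim(val_set$noisy)[3] < 1) {
    stop_nn("nativenoise_parameter_error",
            "training and validation sets must be nonempty")
  }
  params <- model$params
  state <- adam_init(params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_psnr = numeric())
  best <- list(psnr = -Inf, params = params, epoch = 0L)
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = config$batch_size)) {
        sel <- ord[start:min(start + config$batch_size - 1, n)]
        xb <- as_batch(train_set$noisy, sel)
        tb <- as_batch(train_set$clean, sel)
        m2 <- list(config = model$config, params = params)
        fwd <- unet_forward(m2, xb, keep_cache = TRUE)
        resid <- fwd$y - tb
        loss <- mean(resid^2)
        if (!is.finite(loss)) {
          stop_nn("nativenoise_training_error",
                  sprintf("non-finite loss at epoch %d", epoch),
                  history = history)
        }
        losses <- c(losses, loss)
        dy <- 2 * resid / length(resid)
        bw <- unet_backward(m2, fwd$cache, dy)
        upd <- adam_step(params, bw$grads, state, config$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      vp <- val_psnr(list(config = model$config, params = params), val_set)
      history[epoch, ] <- list(epoch, mean(losses), vp)
      if (vp > best$psnr) {
        best <- list(psnr = vp, params = params, epoch = epoch)
      }
    }
  })
  structure(list(weights = best$params, unet_config = model$config,
                 train_config = config, history = history,
                 best_epoch = best$epoch),
            class = "nn_checkpoint")
}

#' @export
print.nn_checkpoint <- function(x, ...) {
  cat(sprintf("<nn_checkpoint> base %d, depth %d; best epoch %d/%d (val PSNR %.2f dB)\n",
              x$unet_config$base_channels, x$unet_config$depth, x$best_epoch,
              nrow(x$history), max(x$history$val_psnr)))
  invisible(x)
}

#' Save / load a checkpoint
#'
#' RDS round trip; a reloaded checkpoint yields bit-identical predictions.
#' @param ckpt an `nn_checkpoint`
#' @param path file path
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "nn_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "nn_checkpoint")) {
    stop_nn("nativenoise_format_error", "file does not hold a checkpoint")
  }
  ckpt
}

ckpt_model <- function(ckpt) {
  list(config = ckpt$unet_config, params = ckpt$weights)
}

# Symmetric (mirror) padding on the bottom/right to the next multiple of m.
pad_to_multiple <- function(px, m) {
  h <- nrow(px)
  w <- ncol(px)
  ph <- (m - h %% m) %% m
  pw <- (m - w %% m) %% m
  if (ph > 0) px <- rbind(px, px[h:(h - ph + 1), , drop = FALSE])
  if (pw > 0) px <- cbind(px, px[, w:(w - pw + 1), drop = FALSE])
  px
}

#' Denoise a full image with a trained checkpoint
#'
#' The network is fully convolutional, so the entire image is denoised in
#' one forward pass regardless of the training patch size — no tiling and
#' no stitching artifacts. Sizes not divisible by `2^depth` are handled by
#' mirror-padding on the bottom/right and cropping back.
#'
#' @param ckpt an `nn_checkpoint`
#' @param image a [magnitude_image()] (intensities on the training scale,
#'   typically \[0, 1\]), at least `2^depth` pixels per side
#' @return a [magnitude_image()] of the input's shape
#' @export
denoise_image <- function(ckpt, image) {
  stopifnot(inherits(ckpt, "nn_checkpoint"))
  px <- as_pixels(image)
  m <- 2^ckpt$unet_config$depth
  if (nrow(px) < m || ncol(px) < m) {
    stop_nn("nativenoise_parameter_error",
            sprintf("image must be at least %d px per side", m))
  }
  padded <- pad_to_multiple(px, m)
  x <- array(padded, c(nrow(padded), ncol(padded), 1, 1))
  y <- unet_forward(ckpt_model(ckpt), x)
  out <- y[seq_len(nrow(px)), seq_len(ncol(px)), 1, 1]
  magnitude_image(out, spacing = image$spacing %||% c(1, 1),
                  id = paste0(image$id %||% "", "_dn"), validate = FALSE)
}

#' Effective receptive field at one output location
#'
#' Backpropagates the gradient of the output pixel at `location` through
#' the frozen network: the map `|d y(location) / d x|` shows which input
#' pixels drive that prediction. Normalized to maximum 1 (all-zero maps
#' are returned as zeros).
#'
#' @param ckpt an `nn_checkpoint`
#' @param image input [magnitude_image()]
#' @param location integer (row, col) of the probed output pixel
#' @return nonnegative matrix of the image's shape
#' @export
compute_erf <- function(ckpt, image, location) {
  px <- as_pixels(image)
  if (location[1] < 1 || location[1] > nrow(px) ||
      location[2] < 1 || location[2] > ncol(px)) {
    stop_nn("nativenoise_parameter_error", "location outside image")
  }
  m <- 2^ckpt$unet_config$depth
  padded <- pad_to_multiple(px, m)
  x <- array(padded, c(nrow(padded), ncol(padded), 1, 1))
  model <- ckpt_model(ckpt)
  fwd <- unet_forward(model, x, keep_cache = TRUE)
  dy <- array(0, dim(fwd$y))
  dy[location[1], location[2], 1, 1] <- 1
  bw <- unet_backward(model, fwd$cache, dy)
  erf <- abs(bw$dx[seq_len(nrow(px)), seq_len(ncol(px)), 1, 1])
  mx <- max(erf)
  if (mx > 0) erf / mx else erf
}

#' Theoretical receptive-field radius of the U-Net
#'
#' Architecture arithmetic along the encoder-bottleneck-decoder path:
#' every layer grows the field by `(kernel - 1) * jump`, pooling doubles
#' the jump, transposed convolution halves it.
#'
#' @param config a [unet_config()]
#' @return radius in input pixels (half the receptive-field side)
#' @export
receptive_field_radius <- function(config) {
  rf <- 1
  j <- 1
  for (d in seq_len(config$depth)) {
    rf <- rf + 2 * 2 * j      # two 3x3 convs
    rf <- rf + 1 * j          # 2x2 pool
    j <- j * 2
  }
  rf <- rf + 2 * 2 * j        # bottleneck convs
  for (d in rev(seq_len(config$depth))) {
    rf <- rf + 1 * j          # 2x2 up-convolution
    j <- j / 2
    rf <- rf + 2 * 2 * j
  }
  ceiling((rf - 1) / 2)
}
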