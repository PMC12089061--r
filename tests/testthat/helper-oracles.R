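# Brute-force metric references, written independently of the package
# internals; shared by the evaluation and acceptance tests.
mse_brute <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) s <- s + (a[i, j] - b[i, j])^2
  }
  s / length(a)
}

ssim_brute <- function(x, y, C1 = 0.01^2, C2 = 0.03^2, win = 11, sigma = 1.5) {
  r <- (win - 1) / 2
  w <- if (is.null(sigma)) {
    matrix(1 / win^2, win, win)
  } else {
    k <- dnorm(seq(-r, r), sd = sigma)
    outer(k, k) / sum(outer(k, k))
  }
  vals <- c()
  for (i in seq_len(nrow(x) - win + 1)) {
    for (j in seq_len(ncol(x) - win + 1)) {
      xs <- x[i:(i + win - 1), j:(j + win - 1)]
      ys <- y[i:(i + win - 1), j:(j + win - 1)]
      mx <- sum(w * xs)
      my <- sum(w * ys)
      vx <- sum(w * xs^2) - mx^2
      vy <- sum(w * ys^2) - my^2
      cxy <- sum(w * xs * ys) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                  ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  }
  mean(vals)
}
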