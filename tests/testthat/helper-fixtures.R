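# Shared fixtures and independent oracles.

# harmonic + optional linear trend + single level shift, N observations;
# shift_at is the first observation at the shifted level
make_shift_series <- function(n = 360, shift_at = 180, magnitude = -3000,
                              noise_sd = 0, slope = 0, baseline = 4500,
                              amplitude = 1500, period = 23, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq_len(n)
  y <- baseline + slope * t + amplitude * sin(2 * pi * t / period)
  y[t >= shift_at] <- y[t >= shift_at] + magnitude
  if (noise_sd > 0) y <- y + rnorm(n, 0, noise_sd)
  y
}

# Exhaustive segmentation oracle: enumerate every admissible break placement
# and fit each segment by lm(); independent of the package's prefix-sum DP.
brute_force_seg_rss <- function(y, X, min_seg, n_breaks) {
  n <- length(y)
  seg_rss <- function(i, j) {
    fit <- lm.fit(X[i:j, , drop = FALSE], y[i:j])
    sum(fit$residuals^2)
  }
  if (n_breaks == 0) return(seg_rss(1, n))
  best <- Inf
  if (n_breaks == 1) {
    for (b in min_seg:(n - min_seg))
      best <- min(best, seg_rss(1, b) + seg_rss(b + 1, n))
  } else if (n_breaks == 2) {
    for (b1 in min_seg:(n - 2 * min_seg))
      for (b2 in (b1 + min_seg):(n - min_seg))
        best <- min(best, seg_rss(1, b1) + seg_rss(b1 + 1, b2) +
                      seg_rss(b2 + 1, n))
  } else {
    stop("oracle supports at most 2 breaks")
  }
  best
}

# 1-D grid integration of the 2-class aggregation posterior:
# theta ~ flat on the simplex, q = t(M) theta, counts ~ multinomial(q)
grid_posterior_2class <- function(M, counts, ngrid = 20001) {
  theta1 <- seq(1e-9, 1 - 1e-9, length.out = ngrid)
  q1 <- M[1, 1] * theta1 + M[2, 1] * (1 - theta1)
  q2 <- M[1, 2] * theta1 + M[2, 2] * (1 - theta1)
  loglik <- counts[1] * log(q1) + counts[2] * log(q2)
  w <- exp(loglik - max(loglik))
  w <- w / sum(w)
  mean1 <- sum(w * theta1)
  sd1 <- sqrt(sum(w * (theta1 - mean1)^2))
  list(mean = c(mean1, 1 - mean1), sd = c(sd1, sd1))
}

# separable 4-class feature set: each class has a distinct center in two
# informative covariates, plus optional pure-noise columns
make_separable_features <- function(n_per_class = 50, noise_cols = 0,
                                    seed = 1) {
  set.seed(seed)
  cls <- management_classes()
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  x <- do.call(rbind, lapply(1:4, function(k)
    cbind(rnorm(n_per_class, centers[k, 1], 0.5),
          rnorm(n_per_class, centers[k, 2], 0.5))))
  df <- data.frame(f1 = x[, 1], f2 = x[, 2])
  if (noise_cols > 0)
    for (j in seq_len(noise_cols))
      df[[paste0("noise", j)]] <- rnorm(nrow(df))
  list(features = df, labels = rep(cls, each = n_per_class))
}
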