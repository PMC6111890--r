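#' Decomposition configuration
#'
#' Controls the season/trend/break decomposition.  The minimum segment length
#' of 46 observations (two years of 16-day composites) confines break
#' positions to `[46, N - 46]` — `[46, 314]` for the canonical N = 360
#' record.  Break counts (0 to `max_breaks`) are chosen by BIC over the
#' dynamic-programming segmentations.
#'
#' @param harmonic_order number of sin/cos harmonic pairs in the seasonal
#'   model (default 3).
#' @param max_breaks maximum breaks per component (default 3).
#' @param min_segment minimum observations per segment (default 46).
#' @param period observations per seasonal cycle (default 23).
#' @param criterion break-count selection criterion (only `"bic"`).
#' @param max_iter maximum season/trend alternations (default 3).
#' @return A validated list of class `decomp_config`.
#' @export
decomp_config <- function(harmonic_order = 3, max_breaks = 3,
                          min_segment = 46, period = 23,
                          criterion = "bic", max_iter = 5) {
  criterion <- match.arg(criterion, "bic")
  if (max_breaks < 0) stop("max_breaks must be >= 0")
  if (min_segment < 2 * harmonic_order + 2)
    stop("min_segment must be at least the number of harmonic terms + 2")
  cfg <- list(harmonic_order = harmonic_order, max_breaks = max_breaks,
              min_segment = min_segment, period = period,
              criterion = criterion, max_iter = max_iter)
  class(cfg) <- "decomp_config"
  cfg
}

#' Harmonic design matrix
#'
#' Sin/cos regressors (no intercept) for `order` harmonics of the seasonal
#' period, evaluated at 1-based positions `1..n`.
#'
#' @param n series length.
#' @param order number of harmonic pairs.
#' @param period observations per cycle.
#' @return n x (2*order) matrix.
#' @export
harmonic_design <- function(n, order = 3, period = 23) {
  t <- seq_len(n)
  X <- matrix(0, n, 2 * order)
  for (h in seq_len(order)) {
    X[, 2 * h - 1] <- sin(2 * pi * h * t / period)
    X[, 2 * h] <- cos(2 * pi * h * t / period)
  }
  X
}

# BIC over break counts 0..K. rss may contain NA for infeasible counts.
# The RSS is floored at a scale-relative epsilon so that numerically-zero
# residuals (noiseless inputs) do not reward spurious extra breaks; ties
# resolve to the fewest breaks.
.select_k <- function(rss, n, p, scale) {
  K <- length(rss) - 1
  k <- 0:K
  floor_rss <- n * (1e-6 * max(scale, 1))^2
  df <- (k + 1) * p + k + 1
  bic <- n * log(pmax(rss, floor_rss) / n) + df * log(n)
  bic[is.na(rss)] <- Inf
  which.min(bic) - 1L
}

.segments_from_breaks <- function(breaks, n) {
  data.frame(start = c(1L, breaks + 1L), end = c(breaks, n))
}

# piecewise OLS fit given segment boundaries; returns fitted values and
# per-segment coefficient matrix (p x nseg)
.piecewise_fit <- function(y, X, breaks) {
  n <- length(y)
  seg <- .segments_from_breaks(breaks, n)
  fitted <- numeric(n)
  coefs <- matrix(NA_real_, ncol(X), nrow(seg))
  for (s in seq_len(nrow(seg))) {
    i <- seg$start[s]:seg$end[s]
    fit <- lm.fit(X[i, , drop = FALSE], y[i])
    fitted[i] <- fit$fitted.values
    coefs[, s] <- fit$coefficients
  }
  list(fitted = fitted, coefs = coefs)
}

# Batch engine over a matrix of series (columns).  Alternates between
# piecewise-linear trend segmentation of the deseasonalized series and
# piecewise-harmonic segmentation of the detrended series until the break
# sets stabilise or max_iter is reached.
.decompose_batch <- function(Y, config) {
  n <- nrow(Y); npix <- ncol(Y)
  m <- config$min_segment
  K <- config$max_breaks
  Xt <- cbind(1, seq_len(n))
  Xs <- harmonic_design(n, config$harmonic_order, config$period)
  pt <- ncol(Xt); ps <- ncol(Xs)

  # initial seasonal estimate: single global harmonic fit
  S <- Xs %*% solve(crossprod(Xs), crossprod(Xs, Y))
  Tm <- matrix(0, n, npix)
  tb <- rep(list(integer(0)), npix)
  sb <- rep(list(integer(0)), npix)
  tcoef <- vector("list", npix)
  scoef <- vector("list", npix)

  pick_breaks <- function(scan, px, k) {
    if (k == 0) integer(0) else as.integer(scan$breaks[[k]][px, ])
  }

  # The DP scans (expensive) run only for pixels whose break sets are still
  # moving; the piecewise season/trend refits (cheap) run for every pixel
  # every sweep, so the component estimates keep polishing after the break
  # sets have settled.  Convergence: break sets stable and fitted components
  # stationary to within 1e-6 EVI units.
  active <- seq_len(npix)
  for (iter in seq_len(config$max_iter)) {
    tb_prev <- tb; sb_prev <- sb
    fit_prev <- Tm + S
    D <- Y - S
    if (length(active) > 0) {
      scan_t <- .seg_scan_batch(D[, active, drop = FALSE], Xt, m, K)
      sdD <- apply(D[, active, drop = FALSE], 2, sd)
      for (q in seq_along(active)) {
        k <- .select_k(scan_t$rss[q, ], n, pt, sdD[q])
        tb[[active[q]]] <- pick_breaks(scan_t, q, k)
      }
    }
    for (px in seq_len(npix)) {
      fit <- .piecewise_fit(D[, px], Xt, tb[[px]])
      Tm[, px] <- fit$fitted
      tcoef[[px]] <- fit$coefs
    }
    R <- Y - Tm
    if (length(active) > 0) {
      scan_s <- .seg_scan_batch(R[, active, drop = FALSE], Xs, m, K)
      sdR <- apply(R[, active, drop = FALSE], 2, sd)
      for (q in seq_along(active)) {
        k <- .select_k(scan_s$rss[q, ], n, ps, sdR[q])
        sb[[active[q]]] <- pick_breaks(scan_s, q, k)
      }
    }
    for (px in seq_len(npix)) {
      fit <- .piecewise_fit(R[, px], Xs, sb[[px]])
      S[, px] <- fit$fitted
      scoef[[px]] <- fit$coefs
    }
    active <- active[!vapply(active, function(px)
      identical(tb[[px]], tb_prev[[px]]) && identical(sb[[px]], sb_prev[[px]]),
      TRUE)]
    if (length(active) == 0 && max(abs(Tm + S - fit_prev)) < 1e-6) break
  }
  list(trend = Tm, seasonal = S, remainder = Y - Tm - S,
       trend_breaks = tb, seasonal_breaks = sb,
       trend_coefs = tcoef, seasonal_coefs = scoef)
}

.trend_segment_stats <- function(values, trend, breaks, coefs) {
  seg <- .segments_from_breaks(breaks, length(values))
  seg$mean <- NA_real_; seg$iqr <- NA_real_
  seg$intercept <- coefs[1, ]; seg$slope <- coefs[2, ]
  seg$fit_start <- NA_real_; seg$fit_end <- NA_real_
  for (s in seq_len(nrow(seg))) {
    i <- seg$start[s]:seg$end[s]
    seg$mean[s] <- mean(values[i])
    seg$iqr[s] <- IQR(values[i])
    seg$fit_start[s] <- trend[seg$start[s]]
    seg$fit_end[s] <- trend[seg$end[s]]
  }
  seg
}

.seasonal_segment_stats <- function(seasonal, breaks) {
  seg <- .segments_from_breaks(breaks, length(seasonal))
  seg$range <- NA_real_; seg$entropy <- NA_real_; seg$iqr <- NA_real_
  for (s in seq_len(nrow(seg))) {
    i <- seg$start[s]:seg$end[s]
    seg$range[s] <- diff(range(seasonal[i]))
    seg$entropy[s] <- .spectral_entropy_safe(seasonal[i])
    seg$iqr[s] <- IQR(seasonal[i])
  }
  seg
}

.decomp_from_batch <- function(values, batch, px, config) {
  structure(list(
    values = values,
    trend = batch$trend[, px],
    seasonal = batch$seasonal[, px],
    remainder = batch$remainder[, px],
    trend_breaks = batch$trend_breaks[[px]],
    seasonal_breaks = batch$seasonal_breaks[[px]],
    trend_segments = .trend_segment_stats(values, batch$trend[, px],
                                          batch$trend_breaks[[px]],
                                          batch$trend_coefs[[px]]),
    seasonal_segments = .seasonal_segment_stats(batch$seasonal[, px],
                                                batch$seasonal_breaks[[px]]),
    usable = TRUE, config = config), class = "fm_decomposition")
}

#' Decompose one EVI series
#'
#' Splits a gap-filled series into trend, seasonal and remainder components
#' with up to `max_breaks` structural breaks in each of the trend and the
#' seasonal component.  Trend breaks come from an exact dynamic-programming
#' least-squares segmentation of the deseasonalized series into
#' piecewise-linear segments; seasonal breaks from the analogous segmentation
#' of the detrended series with per-segment harmonic fits.  The two steps are
#' alternated until the break sets converge.  The number of breaks is chosen
#' by BIC; ties (and exact RSS ties inside the segmentation) resolve toward
#' fewer and earlier breaks.  A break index is the 1-based position of the
#' last observation of the segment it terminates.
#'
#' @param series an [evi_series()] (gap-filled) or a numeric vector.
#' @param config a [decomp_config()].
#' @return An `fm_decomposition` with components, break positions and
#'   per-segment statistics (trend: mean and IQR of the observed EVI, fitted
#'   slope/intercept and boundary values; seasonal: range, spectral entropy,
#'   IQR of the seasonal component).  An unusable input series yields an
#'   unusable sentinel.
#' @export
decompose_series <- function(series, config = decomp_config()) {
  if (inherits(series, "evi_series")) {
    if (!series$usable)
      return(structure(list(usable = FALSE, config = config),
                       class = "fm_decomposition"))
    if (any(series$missing))
      stop("series must be gap-filled before decomposition")
    values <- series$values
  } else {
    values <- as.numeric(series)
  }
  n <- length(values)
  if (n < 2 * config$min_segment)
    stop("series too short: need at least 2 * min_segment observations")
  if (any(!is.finite(values))) stop("series contains non-finite values")
  batch <- .decompose_batch(matrix(values, ncol = 1), config)
  .decomp_from_batch(values, batch, 1L, config)
}

#' @export
print.fm_decomposition <- function(x, ...) {
  if (!x$usable) {
    cat("<fm_decomposition> unusable sentinel\n")
    return(invisible(x))
  }
  cat(sprintf("<fm_decomposition> n = %d, trend breaks: %s; seasonal breaks: %s\n",
              length(x$values),
              if (length(x$trend_breaks)) paste(x$trend_breaks, collapse = ", ") else "none",
              if (length(x$seasonal_breaks)) paste(x$seasonal_breaks, collapse = ", ") else "none"))
  invisible(x)
}

#' Decompose every usable pixel of a cube
#'
#' Batch interface over a gap-filled EVI cube; all pixels share the design
#' matrices and segmentation tables, which makes whole-cube processing far
#' cheaper than repeated single-series calls.
#'
#' @param evi nrow x ncol x N gap-filled array.
#' @param usable logical matrix of usable pixels (default all).
#' @param config a [decomp_config()].
#' @return List with `decomps` (list of `fm_decomposition`, NULL where
#'   unusable, in column-major pixel order) and `dims`.
#' @export
decompose_cube <- function(evi, usable = NULL, config = decomp_config()) {
  d <- dim(evi)
  if (is.null(usable)) usable <- matrix(TRUE, d[1], d[2])
  idx <- which(usable)
  Y <- matrix(aperm(evi, c(3, 1, 2)), d[3], d[1] * d[2])[, idx, drop = FALSE]
  batch <- .decompose_batch(Y, config)
  decomps <- vector("list", d[1] * d[2])
  for (q in seq_along(idx))
    decomps[[idx[q]]] <- .decomp_from_batch(Y[, q], batch, q, config)
  list(decomps = decomps, dims = d[1:2])
}

#' Spectral entropy of a series
#'
#' Normalized Shannon entropy of the normalized periodogram (zero frequency
#' excluded), scaled by the log of the number of Fourier frequencies so the
#' maximum attainable value is 1.  A single pure sinusoid concentrates power
#' at one frequency and scores near 0; white noise spreads power and scores
#' near 1.
#'
#' @param x numeric series (gap-filled, non-constant).
#' @return Entropy in (0, 1].
#' @export
spectral_entropy <- function(x) {
  if (any(!is.finite(x))) stop("series contains non-finite values")
  h <- .spectral_entropy_safe(x)
  if (is.na(h)) stop("spectral entropy is undefined for a constant series")
  h
}

.spectral_entropy_safe <- function(x) {
  n <- length(x)
  if (n < 4) return(NA_real_)
  x <- x - mean(x)
  pgram <- Mod(fft(x))^2
  keep <- 2:(floor(n / 2) + 1)  # positive frequencies, zero excluded
  pw <- pgram[keep]
  tot <- sum(pw)
  if (tot <= 0) return(NA_real_)
  p <- pw / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(keep))
}
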