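#' EVI pixel series
#'
#' One pixel's EVI record with its QA usefulness codes and missingness mask.
#' Values are EVI x 10000 (valid range [-2000, 10000]); QA usefulness codes
#' run 0 (best) to 15 (worst); series positions are 1-based.
#'
#' @param values numeric vector of EVI values.
#' @param qa integer usefulness codes in [0, 15], same length as `values`.
#' @param missing logical mask, same length (defaults to `is.na(values)`).
#' @return An `evi_series` object with fields `values`, `qa`, `missing` and
#'   `usable` (set by [fill_gaps()]).
#' @export
evi_series <- function(values, qa = NULL, missing = NULL) {
  n <- length(values)
  if (is.null(qa)) qa <- rep(0L, n)
  if (is.null(missing)) missing <- is.na(values)
  if (length(qa) != n || length(missing) != n)
    stop("values, qa and missing must have equal length")
  if (any(qa < 0 | qa > 15, na.rm = TRUE))
    stop("qa usefulness codes must lie in [0, 15]")
  if (any(!is.finite(values[!missing])))
    stop("non-missing values must be finite")
  structure(list(values = as.numeric(values), qa = as.integer(qa),
                 missing = as.logical(missing), usable = TRUE),
            class = "evi_series")
}

#' @export
print.evi_series <- function(x, ...) {
  cat(sprintf("<evi_series> length %d, %d missing, usable: %s\n",
              length(x$values), sum(x$missing), x$usable))
  invisible(x)
}

#' Mask poor-quality observations
#'
#' Marks as missing every observation whose QA usefulness code exceeds the
#' threshold.  The default threshold of 4 retains the upper half of the
#' usefulness range (codes 0-4, the "good" 0000-0100 block of the MOD13Q1
#' usefulness sub-field, bits 2-5); the comparison is on the integer code and
#' the threshold is configurable.
#'
#' @param series an [evi_series()].
#' @param usefulness_threshold highest code retained (default 4).
#' @return The series with poor observations flagged missing.
#' @export
mask_qa <- function(series, usefulness_threshold = 4) {
  stopifnot(inherits(series, "evi_series"))
  series$missing <- series$missing | (series$qa > usefulness_threshold)
  series
}

#' Gap-fill an EVI series
#'
#' If more than `good_fraction_min` of the observations are good (strictly
#' greater: exactly 75% good fails the default rule), interior gaps are
#' linearly interpolated between the two nearest good observations and edge
#' gaps take the nearest good value; otherwise the whole series is flagged
#' unusable (`usable = FALSE`) and values are left untouched.  Good
#' observations are never altered.
#'
#' @param series an [evi_series()], typically after [mask_qa()].
#' @param good_fraction_min minimum good-data fraction (default 0.75).
#' @return The filled series, or an unusable sentinel series.
#' @export
fill_gaps <- function(series, good_fraction_min = 0.75) {
  stopifnot(inherits(series, "evi_series"))
  good <- !series$missing
  if (mean(good) <= good_fraction_min || !any(good)) {
    series$usable <- FALSE
    return(series)
  }
  if (any(!good)) {
    idx <- seq_along(series$values)
    series$values <- approx(idx[good], series$values[good], xout = idx,
                            method = "linear", rule = 2)$y
    series$missing <- rep(FALSE, length(idx))
  }
  series$usable <- TRUE
  series
}

#' Preprocess an EVI data cube
#'
#' Applies [mask_qa()] and [fill_gaps()] to every pixel of an EVI cube.
#'
#' @param evi nrow x ncol x N array of EVI values.
#' @param qa matching array of usefulness codes (optional).
#' @param usefulness_threshold passed to [mask_qa()].
#' @param good_fraction_min passed to [fill_gaps()].
#' @return List with `evi` (filled cube; unusable pixels all-NA) and `usable`
#'   (logical matrix).
#' @export
preprocess_cube <- function(evi, qa = NULL, usefulness_threshold = 4,
                            good_fraction_min = 0.75) {
  d <- dim(evi)
  if (length(d) != 3) stop("evi must be a 3-d array")
  if (!is.null(qa) && !identical(dim(qa), d))
    stop("qa cube dimensions must match the EVI cube")
  out <- array(NA_real_, d)
  usable <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      s <- evi_series(evi[i, j, ],
                      qa = if (is.null(qa)) NULL else qa[i, j, ])
      s <- fill_gaps(mask_qa(s, usefulness_threshold), good_fraction_min)
      if (s$usable) {
        out[i, j, ] <- s$values
        usable[i, j] <- TRUE
      }
    }
  }
  list(evi = out, usable = usable)
}
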