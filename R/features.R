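#' Break-summary feature names
#'
#' The 29 per-pixel summary variables computed from a decomposition, in the
#' canonical (alphabetical) order used for feature tables and raster stacks.
#' The `bd_*` family describes the trend break with the biggest decrease,
#' `bi_*` the biggest increase, `lb_*`/`lsb_*` the break bounding the longest
#' segment; `*_sb*` variants are the seasonal-component analogues; `entropy`
#' and `entropy_seasonal` are spectral entropies of the input and seasonal
#' component.
#'
#' @return Character vector of length 29.
#' @export
feature_names <- function() {
  c("bd_b", "bd_b_diff", "bd_b_inqtrng", "bd_b_mean_diff",
    "bd_sb", "bd_sb_entropy_diff", "bd_sb_inqtrng", "bd_sb_range_diff",
    "bi_b", "bi_b_diff", "bi_b_inqtrng", "bi_b_mean_diff",
    "bi_sb", "bi_sb_entropy_diff", "bi_sb_inqtrng", "bi_sb_range_diff",
    "detected_breaks", "detected_breaks_seasonal",
    "entropy", "entropy_seasonal",
    "lb_b", "lb_b_diff", "lb_b_inqtrng", "lb_b_mean_diff",
    "lsb_b", "lsb_break_num", "lsb_sb_entropy_diff", "lsb_sb_inqtrng",
    "lsb_sb_range_diff")
}

# earliest index attaining the minimum / maximum
.which_min_first <- function(x) which(x == min(x))[1]
.which_max_first <- function(x) which(x == max(x))[1]

# break terminating the longest segment: segment s* of maximal length
# (earliest on ties); the final segment is bounded by the last break
.longest_segment_break <- function(seg) {
  k <- nrow(seg) - 1
  lens <- seg$end - seg$start + 1
  min(.which_max_first(lens), k)
}

#' Extract the 29 break-summary features
#'
#' Computes the feature vector for one pixel from its decomposition.  Trend
#' break statistics use the fitted-trend jump across the break
#' (`*_diff`), the difference of observed-EVI segment means
#' (`*_mean_diff`) and the observed-EVI interquartile range of the segment
#' preceding the break (`*_inqtrng`); seasonal analogues use the range,
#' spectral entropy and IQR of the seasonal component per segment.  The
#' biggest-decrease break minimises the jump (range change for the seasonal
#' component), the biggest-increase break maximises it, and the longest
#' break bounds the longest segment; ties resolve to the earliest break.
#' When a component has no detected breaks its break-dependent features take
#' the sentinel 0 (locations and counts) or 0.0 (differences), with
#' `detected_breaks`/`detected_breaks_seasonal` carrying the information
#' that no break exists.
#'
#' @param decomp an `fm_decomposition` from [decompose_series()].
#' @param series optional [evi_series()] or numeric vector of the observed
#'   values (defaults to those stored in the decomposition).
#' @return Named numeric vector with the 29 [feature_names()] entries, or
#'   all-NA for an unusable sentinel decomposition.
#' @export
extract_features <- function(decomp, series = NULL) {
  stopifnot(inherits(decomp, "fm_decomposition"))
  out <- stats::setNames(rep(NA_real_, 29), feature_names())
  if (!decomp$usable) return(out)
  values <- if (is.null(series)) decomp$values
            else if (inherits(series, "evi_series")) series$values
            else as.numeric(series)

  tb <- decomp$trend_breaks
  sb <- decomp$seasonal_breaks
  ts <- decomp$trend_segments
  ss <- decomp$seasonal_segments
  out[] <- 0
  out["detected_breaks"] <- length(tb)
  out["detected_breaks_seasonal"] <- length(sb)
  out["entropy"] <- .spectral_entropy_safe(values)
  out["entropy_seasonal"] <- .spectral_entropy_safe(decomp$seasonal)

  if (length(tb) > 0) {
    k <- length(tb)
    jump <- ts$fit_start[1 + seq_len(k)] - ts$fit_end[seq_len(k)]
    mean_diff <- diff(ts$mean)
    iqr_before <- ts$iqr[seq_len(k)]
    fill <- function(prefix, i) {
      out[paste0(prefix, "_b")] <<- tb[i]
      out[paste0(prefix, "_b_diff")] <<- jump[i]
      out[paste0(prefix, "_b_inqtrng")] <<- iqr_before[i]
      out[paste0(prefix, "_b_mean_diff")] <<- mean_diff[i]
    }
    fill("bd", .which_min_first(jump))
    fill("bi", .which_max_first(jump))
    fill("lb", .longest_segment_break(ts))
  }

  if (length(sb) > 0) {
    k <- length(sb)
    range_diff <- diff(ss$range)
    entropy_diff <- diff(ss$entropy)
    entropy_diff[is.na(entropy_diff)] <- 0
    iqr_before <- ss$iqr[seq_len(k)]
    fill_s <- function(prefix, i) {
      out[paste0(prefix, "_sb")] <<- sb[i]
      out[paste0(prefix, "_sb_entropy_diff")] <<- entropy_diff[i]
      out[paste0(prefix, "_sb_inqtrng")] <<- iqr_before[i]
      out[paste0(prefix, "_sb_range_diff")] <<- range_diff[i]
    }
    fill_s("bd", .which_min_first(range_diff))
    fill_s("bi", .which_max_first(range_diff))
    i_long <- .longest_segment_break(ss)
    out["lsb_b"] <- sb[i_long]
    out["lsb_break_num"] <- i_long
    out["lsb_sb_entropy_diff"] <- entropy_diff[i_long]
    out["lsb_sb_inqtrng"] <- iqr_before[i_long]
    out["lsb_sb_range_diff"] <- range_diff[i_long]
  }
  out
}

#' Feature table for a decomposed cube
#'
#' @param cube_decomp result of [decompose_cube()].
#' @return Data frame with one row per pixel in column-major order (all-NA
#'   rows for unusable pixels) and the 29 [feature_names()] columns.
#' @export
features_from_cube <- function(cube_decomp) {
  rows <- lapply(cube_decomp$decomps, function(d) {
    if (is.null(d)) stats::setNames(rep(NA_real_, 29), feature_names())
    else extract_features(d)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- feature_names()
  out
}

#' Assemble per-pixel feature vectors into a raster stack
#'
#' One band per feature plus `trend_break_valid` / `seasonal_break_valid`
#' flag bands marking pixels whose break-dependent features are sentinels;
#' unusable or non-forest pixels are nodata in every band.
#'
#' @param features data frame of per-pixel feature vectors in column-major
#'   pixel order (see [features_from_cube()]).
#' @param dims `c(nrow, ncol)` of the grid.
#' @param mask optional logical matrix; pixels outside it become nodata.
#' @param ... georeferencing arguments passed to [fm_raster()].
#' @return Named list of `fm_raster` bands in [feature_names()] order.
#' @export
assemble_feature_rasters <- function(features, dims, mask = NULL, ...) {
  if (nrow(features) != prod(dims))
    stop("feature table has ", nrow(features),
         " rows but the grid has ", prod(dims), " pixels")
  if (!all(feature_names() %in% names(features)))
    stop("feature table is missing required feature columns")
  drop <- if (is.null(mask)) rep(FALSE, nrow(features)) else !as.vector(mask)
  stack <- lapply(feature_names(), function(nm) {
    v <- features[[nm]]
    v[drop] <- NA
    fm_raster(matrix(v, dims[1], dims[2]), ...)
  })
  names(stack) <- feature_names()
  stack$trend_break_valid <- fm_raster(
    matrix(ifelse(drop | is.na(features$detected_breaks), NA,
                  (features$detected_breaks > 0) + 0), dims[1], dims[2]), ...)
  stack$seasonal_break_valid <- fm_raster(
    matrix(ifelse(drop | is.na(features$detected_breaks_seasonal), NA,
                  (features$detected_breaks_seasonal > 0) + 0),
           dims[1], dims[2]), ...)
  stack
}
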