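#' Random-forest configuration
#'
#' Protocol defaults: 500 trees with 7 candidate covariates tried at each
#' split, permutation importance, and class weights defaulting to inverse
#' class frequency so underrepresented management classes are not swamped.
#'
#' @param n_trees number of trees (default 500).
#' @param mtry candidate covariates per split (default 7); `NULL` asks
#'   [randomForest::tuneRF()] to pick it.
#' @param class_weights optional named positive weights per class; `NULL`
#'   uses inverse class frequency.
#' @param seed RNG seed for tree construction.
#' @param importance importance measure reported for selection:
#'   `"permutation"` (mean decrease in accuracy, can be negative) or
#'   `"impurity"` (mean decrease in node impurity, nonnegative).
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 500, mtry = 7, class_weights = NULL,
                      seed = 1L, importance = c("permutation", "impurity")) {
  importance <- match.arg(importance)
  if (n_trees < 1) stop("n_trees must be >= 1")
  structure(list(n_trees = n_trees, mtry = mtry,
                 class_weights = class_weights, seed = seed,
                 importance = importance), class = "rf_config")
}

.canonicalize_features <- function(features) {
  if (!is.data.frame(features)) features <- as.data.frame(features)
  features[, order(names(features)), drop = FALSE]
}

#' Train the management classifier
#'
#' Fits a random forest on the covariate table with the configured number of
#' trees, mtry and class weights.  Covariate columns are canonicalized to
#' name order before fitting, so the fit (and its OOB error) is invariant to
#' the column order of the input under a fixed seed.
#'
#' @param features data frame of covariates (numeric or factor), no missing
#'   values.
#' @param labels management class labels (coerced to the canonical factor).
#' @param config an [rf_config()].
#' @return List of class `fm_rf` with `model`, `oob_error`, `confusion`
#'   (OOB), `importance` (both measures), `covariates` and `config`.
#' @export
tune_and_train <- function(features, labels, config = rf_config()) {
  features <- .canonicalize_features(features)
  labels <- droplevels(.as_class_factor(labels))
  if (nlevels(labels) < 2)
    stop("training labels contain a single class; at least 2 are required")
  if (anyNA(features)) stop("features contain missing values")
  p <- ncol(features)
  mtry <- config$mtry
  if (!is.null(mtry) && mtry > p)
    stop("mtry (", mtry, ") exceeds the number of covariates (", p, ")")
  cw <- config$class_weights
  if (is.null(cw)) {
    freq <- table(labels)
    cw <- as.numeric(sum(freq) / (nlevels(labels) * freq))
    names(cw) <- names(freq)
  }
  set.seed(config$seed)
  if (is.null(mtry)) {
    tuned <- randomForest::tuneRF(features, labels, ntreeTry = config$n_trees,
                                  trace = FALSE, plot = FALSE, doBest = FALSE)
    mtry <- tuned[which.min(tuned[, "OOBError"]), "mtry"]
    set.seed(config$seed)
  }
  model <- randomForest::randomForest(
    x = features, y = labels, ntree = config$n_trees, mtry = mtry,
    classwt = cw, importance = TRUE)
  oob_pred <- model$predicted
  structure(list(
    model = model,
    oob_error = mean(oob_pred != labels),
    confusion = confusion_and_accuracies(labels, oob_pred),
    importance = randomForest::importance(model),
    covariates = names(features),
    mtry = mtry,
    config = config), class = "fm_rf")
}

#' @export
print.fm_rf <- function(x, ...) {
  cat(sprintf("<fm_rf> %d trees, mtry %d, %d covariates, OOB error %.3f\n",
              x$config$n_trees, x$mtry, length(x$covariates), x$oob_error))
  invisible(x)
}

#' Prune and select covariates
#'
#' Iteratively removes covariates with negative permutation importance
#' (refitting after each round) until none remain, then keeps at most
#' `max_keep` covariates ranked by mean decrease in accuracy.  If fewer than
#' `max_keep` survive, all survivors are returned.  Deterministic under the
#' config seed.
#'
#' @param features covariate data frame.
#' @param labels class labels.
#' @param config an [rf_config()]; `mtry` is capped at the number of
#'   remaining covariates during refits.
#' @param max_keep maximum covariates kept (default 15).
#' @return Character vector of selected covariate names (name order).
#' @export
select_covariates <- function(features, labels, config = rf_config(),
                              max_keep = 15) {
  features <- .canonicalize_features(features)
  keep <- names(features)
  repeat {
    cfg <- config
    cfg$mtry <- min(config$mtry %||% 7, length(keep))
    fit <- tune_and_train(features[, keep, drop = FALSE], labels, cfg)
    mda <- fit$importance[, "MeanDecreaseAccuracy"]
    neg <- names(mda)[mda < 0]
    if (length(neg) == 0 || length(keep) - length(neg) < 2) break
    keep <- setdiff(keep, neg)
  }
  mda <- sort(fit$importance[keep, "MeanDecreaseAccuracy"], decreasing = TRUE)
  sort(names(mda)[seq_len(min(max_keep, length(mda)))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict management class and probability surfaces
#'
#' Applies a fitted classifier to a covariate raster stack.  Per pixel the
#' class is the majority vote (ties broken toward the lowest class code) and
#' the probability surfaces are the per-class vote fractions, which sum to 1.
#' Non-forest or masked pixels are nodata in the class raster and all four
#' probability rasters.
#'
#' @param fit an `fm_rf` from [tune_and_train()].
#' @param stack named list of covariate layers (`fm_raster` or plain
#'   matrices); names must cover the model's covariates.
#' @param forest_mask logical matrix of pixels to predict.
#' @param ... georeferencing passed to [fm_raster()].
#' @return A `management_map`: list with `class` (categorical `fm_raster`
#'   with a Value/Management attribute table), `probability` (named list of
#'   four probability rasters) and `classes`.
#' @export
predict_surfaces <- function(fit, stack, forest_mask = NULL, ...) {
  stopifnot(inherits(fit, "fm_rf"))
  vals <- lapply(stack, function(b) {
    v <- if (inherits(b, "fm_raster")) b$values else b
    if (!is.null(attr(v, "levels")))
      factor(attr(v, "levels")[v], levels = attr(v, "levels"))
    else as.vector(v)
  })
  missing_cov <- setdiff(fit$covariates, names(vals))
  if (length(missing_cov) > 0)
    stop("covariate stack is missing band(s): ",
         paste(missing_cov, collapse = ", "))
  df <- as.data.frame(vals[fit$covariates])
  names(df) <- fit$covariates
  b1 <- stack[[1]]
  dims <- if (inherits(b1, "fm_raster")) dim(b1$values) else dim(b1)
  if (is.null(forest_mask)) forest_mask <- matrix(TRUE, dims[1], dims[2])
  idx <- which(as.vector(forest_mask) & complete.cases(df))
  # align factor levels with training
  xlev <- fit$model$forest$xlevels
  for (nm in names(df))
    if (is.factor(df[[nm]]) && is.character(xlev[[nm]]))
      df[[nm]] <- factor(as.character(df[[nm]]), levels = xlev[[nm]])
  prob <- predict(fit$model, df[idx, , drop = FALSE], type = "vote",
                  norm.votes = TRUE)
  cls <- management_classes()
  pm <- matrix(0, length(idx), length(cls), dimnames = list(NULL, cls))
  pm[, colnames(prob)] <- prob
  prob <- pm
  class_codes <- max.col(prob, ties.method = "first")  # lowest code on ties
  class_m <- matrix(NA_integer_, dims[1], dims[2])
  class_m[idx] <- class_codes
  attr(class_m, "levels") <- cls
  probs <- lapply(seq_along(cls), function(k) {
    m <- matrix(NA_real_, dims[1], dims[2])
    m[idx] <- prob[, cls[k]]
    fm_raster(m, ...)
  })
  names(probs) <- cls
  structure(list(class = fm_raster(class_m, ...), probability = probs,
                 classes = cls,
                 attribute_table = data.frame(Value = seq_along(cls),
                                              Management = cls)),
            class = "management_map")
}

#' @export
print.management_map <- function(x, ...) {
  tab <- table(factor(x$classes[x$class$values], levels = x$classes))
  cat("<management_map>\n")
  print(tab)
  invisible(x)
}
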