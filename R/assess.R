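#' Confusion matrix and accuracy statistics
#'
#' Cross-tabulates predicted against reference labels with rows = predicted
#' (map) class and columns = reference class, and derives the accuracy
#' layout of the published regional validation tables: producers accuracy =
#' diagonal / row total, users accuracy = diagonal / column total, overall =
#' trace / total.  (Accuracy-assessment texts usually attach "producers" to
#' the reference axis; the regional tables this package reproduces print the
#' row-based layout, so the orientation is recorded on the result and
#' [accuracy_from_matrix()] accepts either.)
#'
#' @param reference reference class labels.
#' @param predicted predicted class labels, same length.
#' @return List of class `fm_confusion`: `matrix` (4x4 counts),
#'   `producers`, `users`, `overall`, `n`, `orientation`.
#' @export
confusion_and_accuracies <- function(reference, predicted) {
  reference <- .as_class_factor(reference)
  predicted <- .as_class_factor(predicted)
  if (length(reference) != length(predicted))
    stop("reference and predicted must have equal length")
  m <- table(predicted = predicted, reference = reference)
  accuracy_from_matrix(unclass(m))
}

#' @rdname confusion_and_accuracies
#' @param m square count matrix; `orientation` says what the rows are.
#' @param orientation `"rows_predicted"` (default, the published layout) or
#'   `"rows_reference"` (transposed input).
#' @export
accuracy_from_matrix <- function(m, orientation = c("rows_predicted",
                                                    "rows_reference")) {
  orientation <- match.arg(orientation)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  if (any(m < 0)) stop("confusion matrix counts must be nonnegative")
  if (orientation == "rows_reference") m <- t(m)
  structure(list(
    matrix = m,
    producers = diag(m) / rowSums(m),
    users = diag(m) / colSums(m),
    overall = sum(diag(m)) / sum(m),
    n = sum(m),
    orientation = "rows_predicted"), class = "fm_confusion")
}

#' @export
print.fm_confusion <- function(x, ...) {
  cat(sprintf("<fm_confusion> n = %d, overall accuracy %.3f\n", x$n, x$overall))
  print(x$matrix)
  tab <- rbind(producers = x$producers, users = x$users)
  print(round(tab, 3))
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Splits the data into k disjoint folds, stratified by class (per-class fold
#' sizes differ by at most one); a class with fewer members than folds drops
#' stratification with a warning.  Each fold is held out once against a
#' forest trained on the remainder; the error is averaged over folds.
#'
#' @param features covariate data frame.
#' @param labels class labels.
#' @param k number of folds (default 10).
#' @param seed RNG seed governing fold assignment and tree construction.
#' @param config an [rf_config()].
#' @return List with `folds` (integer assignment), `fold_errors`,
#'   `mean_error` and the pooled held-out `confusion`.
#' @export
kfold_cv <- function(features, labels, k = 10, seed = 1L,
                     config = rf_config()) {
  labels <- .as_class_factor(labels)
  n <- length(labels)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("need at least k observations")
  set.seed(seed)
  folds <- integer(n)
  if (min(table(droplevels(labels))) < k) {
    warning("a class has fewer members than folds; using unstratified folds")
    folds <- sample(rep(seq_len(k), length.out = n))
  } else {
    for (cl in levels(droplevels(labels))) {
      i <- which(labels == cl)
      folds[i] <- sample(rep(seq_len(k), length.out = length(i)))
    }
  }
  features <- .canonicalize_features(features)
  pred <- factor(rep(NA_character_, n), levels = levels(labels))
  fold_errors <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds == f
    cfg <- config
    cfg$seed <- seed + f
    cfg$mtry <- min(config$mtry %||% 7, ncol(features))
    fit <- tune_and_train(features[!test, , drop = FALSE], labels[!test], cfg)
    p <- predict(fit$model, features[test, , drop = FALSE])
    pred[test] <- as.character(p)
    fold_errors[f] <- mean(p != labels[test])
  }
  list(folds = folds, fold_errors = fold_errors,
       mean_error = mean(fold_errors),
       confusion = confusion_and_accuracies(labels, pred))
}

#' Aggregate a class map to coarse-cell proportions
#'
#' Observed class proportions among forest pixels within each factor x factor
#' block of the fine map (default 40, taking 250-m pixels to a 10-km grid).
#' Partial edge blocks use the pixels available; blocks with no forest
#' pixels are returned as nodata.
#'
#' @param class_raster categorical `fm_raster` (or integer matrix of class
#'   codes 1..4).
#' @param forest_mask logical matrix; only these pixels are counted.
#' @param factor aggregation factor (>= 1).
#' @return List with `p_obs` (ncell x 4 matrix, NA rows for forest-free
#'   cells), `n` (forest pixels per cell), `cell_row`, `cell_col`, `dims`.
#' @export
aggregate_proportions <- function(class_raster, forest_mask = NULL,
                                  factor = 40) {
  if (factor < 1) stop("factor must be >= 1")
  v <- if (inherits(class_raster, "fm_raster")) class_raster$values
       else class_raster
  cls <- management_classes()
  nr <- nrow(v); nc <- ncol(v)
  if (is.null(forest_mask)) forest_mask <- matrix(TRUE, nr, nc)
  cr <- ceiling(nr / factor); cc <- ceiling(nc / factor)
  ncell <- cr * cc
  p_obs <- matrix(NA_real_, ncell, 4, dimnames = list(NULL, cls))
  n <- integer(ncell)
  cell_row <- rep(seq_len(cr), cc)
  cell_col <- rep(seq_len(cc), each = cr)
  for (q in seq_len(ncell)) {
    rows <- ((cell_row[q] - 1) * factor + 1):min(cell_row[q] * factor, nr)
    cols <- ((cell_col[q] - 1) * factor + 1):min(cell_col[q] * factor, nc)
    blk <- v[rows, cols]
    keep <- forest_mask[rows, cols] & !is.na(blk)
    n[q] <- sum(keep)
    if (n[q] > 0)
      p_obs[q, ] <- tabulate(blk[keep], nbins = 4) / n[q]
  }
  list(p_obs = p_obs, n = n, cell_row = cell_row, cell_col = cell_col,
       dims = c(cr, cc))
}

# Monte-Carlo posterior of true class proportions for one coarse cell.
# Model: theta ~ Dirichlet(1,..,1); observed mapped-class counts are a
# multinomial draw from q = t(M) theta, with M[i, j] = P(mapped j | true i)
# taken from the classifier's confusion matrix.  Sampled by an
# independence-proposal Metropolis chain whose Dirichlet proposal is centred
# on the linear unmixing of the observed proportions (overdispersed 2x).
.posterior_cell_mcmc <- function(counts, M, n_samples, burn_in) {
  K <- length(counts)
  n <- sum(counts)
  p_obs <- counts / n
  theta_hat <- tryCatch(solve(t(M), p_obs), error = function(e) p_obs)
  theta_hat <- pmax(theta_hat, 1e-6)
  theta_hat <- theta_hat / sum(theta_hat)
  alpha <- 1 + 0.5 * n * theta_hat
  total <- burn_in + n_samples
  # all proposals drawn up front; acceptance is the only sequential part
  g <- matrix(rgamma(total * K, shape = rep(alpha, each = total)), total, K)
  prop <- g / rowSums(g)
  loglik <- function(theta) {
    q <- as.numeric(crossprod(M, theta))
    pos <- counts > 0
    if (any(q[pos] <= 0)) return(-Inf)
    sum(counts[pos] * log(q[pos]))
  }
  logprop <- log(prop) %*% (alpha - 1)  # log proposal density up to a constant
  cur <- prop[1, ]
  cur_ll <- loglik(cur)
  cur_lp <- logprop[1]
  kept <- matrix(NA_real_, n_samples, K)
  for (s in 2:total) {
    cand_ll <- loglik(prop[s, ])
    if (log(runif(1)) < (cand_ll - cur_ll) + (cur_lp - logprop[s])) {
      cur <- prop[s, ]
      cur_ll <- cand_ll
      cur_lp <- logprop[s]
    }
    if (s > burn_in) kept[s - burn_in, ] <- cur
  }
  list(mean = colMeans(kept), sd = apply(kept, 2, sd))
}

#' Bayesian aggregation-uncertainty posterior
#'
#' For each coarse cell, treats the observed forest-pixel class counts as a
#' multinomial draw from the mapped-class distribution implied by the true
#' class proportions and the classifier's confusion matrix, places a flat
#' Dirichlet prior on the true proportions, and samples the posterior by
#' Monte Carlo (independence-Dirichlet Metropolis).  The posterior standard
#' deviation is the cell's uncertainty; it shrinks as the forest-pixel count
#' grows.
#'
#' @param agg result of [aggregate_proportions()].
#' @param confusion an `fm_confusion` (or count matrix, rows = predicted)
#'   from which the mapping channel `P(mapped j | true i)` is estimated; the
#'   external-validation matrix is the conventional choice.
#' @param n_samples posterior draws per cell (default 10000, >= 1000).
#' @param burn_in discarded initial draws (default 1000).
#' @param seed RNG seed.
#' @return List of class `fm_posterior` with `mean` and `sd` (ncell x 4
#'   matrices, NA rows for forest-free cells), plus the fields of `agg`.
#' @export
posterior_uncertainty <- function(agg, confusion, n_samples = 10000,
                                  burn_in = 1000, seed = 1L) {
  if (n_samples < 1000) stop("n_samples must be >= 1000")
  cm <- if (inherits(confusion, "fm_confusion")) confusion$matrix
        else as.matrix(confusion)
  ref_tot <- colSums(cm)
  if (any(ref_tot == 0))
    stop("confusion matrix has a reference class with zero observations; ",
         "the mapping channel is not normalizable")
  # M[i, j] = P(mapped j | true i): transpose the predicted-by-reference
  # counts, then row-normalize
  M <- t(cm) / ref_tot
  set.seed(seed)
  ncell <- nrow(agg$p_obs)
  K <- ncol(agg$p_obs)
  post_mean <- matrix(NA_real_, ncell, K, dimnames = dimnames(agg$p_obs))
  post_sd <- matrix(NA_real_, ncell, K, dimnames = dimnames(agg$p_obs))
  for (q in seq_len(ncell)) {
    if (agg$n[q] == 0 || anyNA(agg$p_obs[q, ])) next
    counts <- round(agg$p_obs[q, ] * agg$n[q])
    res <- .posterior_cell_mcmc(counts, M, n_samples, burn_in)
    post_mean[q, ] <- res$mean
    post_sd[q, ] <- res$sd
  }
  structure(c(list(mean = post_mean, sd = post_sd), agg),
            class = "fm_posterior")
}

#' Uncertainty surfaces from a posterior
#'
#' One coarse-grid raster of posterior standard deviations per class.
#'
#' @param post an `fm_posterior`.
#' @param cellsize coarse cell size in map units.
#' @param ... further arguments for [fm_raster()].
#' @return Named list of four `fm_raster` layers.
#' @export
uncertainty_surfaces <- function(post, cellsize = 10000, ...) {
  cls <- management_classes()
  out <- lapply(seq_along(cls), function(k) {
    m <- matrix(NA_real_, post$dims[1], post$dims[2])
    m[cbind(post$cell_row, post$cell_col)] <- post$sd[, k]
    fm_raster(m, cellsize = cellsize, ...)
  })
  names(out) <- cls
  out
}
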