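#' Pipeline configuration
#'
#' Bundles the stage configurations and thresholds of the end-to-end
#' synthetic-landscape analysis.  Every threshold defaults to the protocol
#' value: QA usefulness threshold 4, good-data fraction 0.75, 80% annotator
#' consensus, 50% forest / 50% single-class training rule, 500-tree forest
#' with mtry 7 and at most 15 covariates kept, and a 20% external hold-out.
#'
#' @param sim a [sim_config()].
#' @param decomp a [decomp_config()].
#' @param rf an [rf_config()].
#' @param nrow,ncol landscape size in pixels.
#' @param patch_size stand size in pixels.
#' @param n_points training points sampled.
#' @param usefulness_threshold QA retention threshold.
#' @param good_fraction_min good-data fraction rule.
#' @param consensus_threshold annotator consensus share.
#' @param holdout_fraction external validation share.
#' @param n_keep maximum covariates kept by selection.
#' @param agg_factor coarse aggregation factor for the uncertainty stage.
#' @param uncertainty_matrix which confusion matrix feeds the uncertainty
#'   channel: `"external"` (default) or `"internal"` (OOB).
#' @param run_uncertainty toggle for the uncertainty stage.
#' @param posterior_samples Monte-Carlo draws per coarse cell.
#' @param seed master seed; stage seeds are derived from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), decomp = decomp_config(),
                            rf = rf_config(), nrow = 60, ncol = 60,
                            patch_size = 5, n_points = 600,
                            usefulness_threshold = 4,
                            good_fraction_min = 0.75,
                            consensus_threshold = 0.8,
                            holdout_fraction = 0.2, n_keep = 15,
                            agg_factor = 20,
                            uncertainty_matrix = c("external", "internal"),
                            run_uncertainty = TRUE,
                            posterior_samples = 4000, seed = 1L) {
  uncertainty_matrix <- match.arg(uncertainty_matrix)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

.stage <- function(name, verbose, expr) {
  if (verbose) message("[", name, "] ...")
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full synthetic-landscape pipeline
#'
#' Executes simulate -> preprocess -> decompose -> features -> covariates ->
#' training-sample development -> covariate selection and training ->
#' prediction -> accuracy assessment -> aggregation uncertainty, entirely on
#' a simulated landscape with known truth.  Deterministic given the config
#' seed.
#'
#' @param config a [pipeline_config()].
#' @param output_dir optional directory; when given, the management map,
#'   probability and uncertainty surfaces, feature stack, training table and
#'   accuracy report are written there (ASCII grids and CSV).
#' @param verbose log stage progress.
#' @return List with the landscape, feature table, training table, fitted
#'   model, `management_map`, internal and external `fm_confusion`,
#'   selected covariates, and (optionally) the aggregation posterior.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL,
                         verbose = TRUE) {
  cfg <- config
  cls <- management_classes()

  scene <- .stage("simulate", verbose,
    simulate_landscape(cfg$sim, nrow = cfg$nrow, ncol = cfg$ncol,
                       patch_size = cfg$patch_size, seed = cfg$seed))

  prep <- .stage("preprocess", verbose,
    preprocess_cube(scene$evi, scene$qa,
                    usefulness_threshold = cfg$usefulness_threshold,
                    good_fraction_min = cfg$good_fraction_min))

  analyse <- scene$forest & prep$usable
  dec <- .stage("decompose", verbose,
    decompose_cube(prep$evi, usable = analyse, config = cfg$decomp))

  feats <- .stage("features", verbose, features_from_cube(dec))

  covs <- .stage("covariates", verbose, {
    road <- line_density(scene$roads,
                         list(nrow = cfg$nrow, ncol = cfg$ncol, xll = 0,
                              yll = 0, cellsize = scene$cellsize),
                         radius = 1000)
    own <- factor(scene$ownership, levels = ownership_levels())
    tbl <- cbind(feats,
                 road_density = as.vector(road$values) * 1e6,  # m per km^2
                 ownership = as.vector(own),
                 prop_conifer = as.vector(scene$prop_conifer),
                 prop_riparian = as.vector(scene$prop_riparian))
    tbl$ownership <- factor(tbl$ownership, levels = ownership_levels())
    tbl
  })

  training <- .stage("training_samples", verbose, {
    # stands are internally pure, so the single-class fraction is 1
    purity <- matrix(1, cfg$nrow, cfg$ncol)
    tmask <- training_mask(scene$forest_frac, purity) & analyse
    candidates <- which(as.vector(tmask))
    set.seed(cfg$seed + 1)
    pts <- sample(candidates, min(cfg$n_points, length(candidates)))
    ann <- simulate_annotations(scene$truth[pts],
                                annotators = cfg$sim$annotators,
                                annotator_error = cfg$sim$annotator_error,
                                seed = cfg$seed + 2)
    cons <- consensus_labels(ann, threshold = cfg$consensus_threshold)
    keep <- !is.na(cons$labels)
    pts <- pts[keep]
    labels <- cons$labels[keep]
    set.seed(cfg$seed + 3)
    holdout <- rep(FALSE, length(pts))
    holdout[sample(length(pts), round(cfg$holdout_fraction * length(pts)))] <- TRUE
    list(pixels = pts, labels = labels, holdout = holdout,
         n_unresolved = sum(!keep),
         table = cbind(covs[pts, ], label = labels, holdout = holdout))
  })
  if (verbose)
    message(sprintf("  %d consensus points (%d unresolved dropped), %d held out",
                    length(training$pixels), training$n_unresolved,
                    sum(training$holdout)))

  fit <- .stage("train", verbose, {
    tr <- !training$holdout
    x <- covs[training$pixels[tr], , drop = FALSE]
    y <- training$labels[tr]
    rf_cfg <- cfg$rf
    rf_cfg$seed <- cfg$seed + 4
    selected <- select_covariates(x, y, rf_cfg, max_keep = cfg$n_keep)
    final_cfg <- rf_cfg
    final_cfg$mtry <- min(rf_cfg$mtry %||% 7, length(selected))
    final <- tune_and_train(x[, selected, drop = FALSE], y, final_cfg)
    list(model = final, selected = selected)
  })
  if (verbose)
    message(sprintf("  %d covariates selected, OOB error %.3f",
                    length(fit$selected), fit$model$oob_error))

  map <- .stage("predict", verbose, {
    stack <- lapply(fit$selected, function(nm) {
      if (is.factor(covs[[nm]])) {
        m <- matrix(as.integer(covs[[nm]]), cfg$nrow, cfg$ncol)
        attr(m, "levels") <- levels(covs[[nm]])
        m
      } else {
        matrix(covs[[nm]], cfg$nrow, cfg$ncol)
      }
    })
    names(stack) <- fit$selected
    predict_surfaces(fit$model, stack, forest_mask = analyse,
                     cellsize = scene$cellsize)
  })

  assessment <- .stage("assess", verbose, {
    ho <- training$holdout
    pred_ho <- cls[map$class$values[training$pixels[ho]]]
    ok <- !is.na(pred_ho)
    list(internal = fit$model$confusion,
         external = confusion_and_accuracies(training$labels[ho][ok],
                                             pred_ho[ok]))
  })
  if (verbose)
    message(sprintf("  OOB accuracy %.3f, external accuracy %.3f",
                    assessment$internal$overall, assessment$external$overall))

  posterior <- NULL
  if (cfg$run_uncertainty) {
    posterior <- .stage("uncertainty", verbose, {
      agg <- aggregate_proportions(map$class, forest_mask = analyse,
                                   factor = cfg$agg_factor)
      cm <- if (cfg$uncertainty_matrix == "external") assessment$external
            else assessment$internal
      # an external hold-out can miss a rare class entirely; the channel
      # then is not estimable from it, so fall back to the OOB matrix
      if (any(colSums(cm$matrix) == 0)) {
        if (verbose) message("  external matrix has an empty reference ",
                             "class; using the internal (OOB) matrix")
        cm <- assessment$internal
      }
      posterior_uncertainty(agg, cm, n_samples = cfg$posterior_samples,
                            burn_in = 1000, seed = cfg$seed + 5)
    })
  }

  result <- list(scene = scene, usable = prep$usable, analyse = analyse,
                 features = feats, covariates = covs, training = training,
                 selected = fit$selected, model = fit$model, map = map,
                 assessment = assessment, posterior = posterior,
                 config = cfg)

  if (!is.null(output_dir)) {
    .stage("write", verbose, .write_artifacts(result, output_dir))
  }
  result
}

.write_artifacts <- function(result, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  cs <- result$scene$cellsize
  write_raster(result$map$class, file.path(output_dir, "management_map.asc"))
  for (cl in management_classes())
    write_raster(result$map$probability[[cl]],
                 file.path(output_dir, paste0("probability_", cl, ".asc")))
  truth_r <- .factor_raster(result$scene$truth, management_classes(),
                            cellsize = cs)
  write_raster(truth_r, file.path(output_dir, "truth.asc"))
  fstack <- assemble_feature_rasters(result$features,
                                     c(cfg$nrow, cfg$ncol),
                                     mask = result$analyse, cellsize = cs)
  write_raster_stack(fstack, file.path(output_dir, "feature_stack"))
  write.csv(result$training$table,
            file.path(output_dir, "training_points.csv"), row.names = FALSE)
  acc <- rbind(
    data.frame(validation = "internal", class = management_classes(),
               producers = result$assessment$internal$producers,
               users = result$assessment$internal$users,
               overall = result$assessment$internal$overall),
    data.frame(validation = "external", class = management_classes(),
               producers = result$assessment$external$producers,
               users = result$assessment$external$users,
               overall = result$assessment$external$overall))
  write.csv(acc, file.path(output_dir, "accuracy_report.csv"),
            row.names = FALSE)
  if (!is.null(result$posterior)) {
    us <- uncertainty_surfaces(result$posterior,
                               cellsize = cs * cfg$agg_factor)
    for (cl in management_classes())
      write_raster(us[[cl]],
                   file.path(output_dir, paste0("uncertainty_", cl, ".asc")))
  }
  invisible(output_dir)
}
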