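#' Simulation configuration
#'
#' Parameters of the synthetic EVI landscape generator.  Defaults emulate the
#' study conditions of the mapped regions: 16-day composites (23 per year)
#' over 16 years, EVI scaled by 10000, a short-rotation production regime
#' (18-20 year harvest rotation, represented by its midpoint of 19), and a
#' class mixture matching the southeastern-region training distribution
#' (3.5% ecological, 28.75% passive, 9.5% preservation, 58.25% production).
#'
#' @param n_years number of simulated years.
#' @param obs_per_year composites per year (series period).
#' @param seasonal_amplitude amplitude of the first-order harmonic seasonal
#'   cycle, EVI x 10000 units.
#' @param baseline undisturbed mean EVI (x 10000).
#' @param noise_sd standard deviation of observation noise (EVI x 10000).
#' @param class_mix named 4-vector of class proportions summing to 1, in
#'   [management_classes()] order.
#' @param rotation_years harvest rotation interval for production stands.
#' @param cut_magnitude EVI drop at a production clearcut.
#' @param ecological_cut_fraction fraction of `cut_magnitude` removed by a
#'   partial (variable-retention style) ecological harvest.
#' @param passive_break_rate expected unplanned disturbances per year in
#'   passively managed stands (Poisson rate).
#' @param passive_cut_fraction fraction of `cut_magnitude` for unplanned
#'   passive-stand disturbances.
#' @param recovery_rate linear EVI recovery per observation step after a cut.
#' @param qa_dropout_prob probability an observation is cloud/QA-degraded.
#' @param annotators number of expert annotators for training labels.
#' @param annotator_error probability an annotator mislabels a point.
#' @param seed default RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_years = 16, obs_per_year = 23,
                       seasonal_amplitude = 1500, baseline = 4500,
                       noise_sd = 150,
                       class_mix = c(ecological = 0.035, passive = 0.2875,
                                     preservation = 0.095, production = 0.5825),
                       rotation_years = 19, cut_magnitude = 3000,
                       ecological_cut_fraction = 0.4,
                       passive_break_rate = 0.02,
                       passive_cut_fraction = 0.6,
                       recovery_rate = 16, qa_dropout_prob = 0.1,
                       annotators = 5, annotator_error = 0.1, seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$class_mix) - 1) > 1e-8)
    stop("class_mix must sum to 1")
  if (length(cfg$class_mix) != 4)
    stop("class_mix must have 4 entries")
  probs <- c(cfg$qa_dropout_prob, cfg$annotator_error,
             cfg$ecological_cut_fraction, cfg$passive_cut_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  n <- cfg$n_years * cfg$obs_per_year
  if (n < 46 || n > 1000)
    stop("n_years * obs_per_year must lie in [46, 1000]")
  class(cfg) <- "sim_config"
  cfg
}

# Disturbance events for one stand: data.frame(index, magnitude).
# Index is the first observation at the reduced level (1-based).
.regime_events <- function(class_label, config, n) {
  opy <- config$obs_per_year
  events <- data.frame(index = integer(0), magnitude = numeric(0))
  if (class_label %in% c("production", "ecological")) {
    u <- runif(1, 0, config$rotation_years)
    yrs <- if (u < config$n_years)
      u + config$rotation_years * (0:floor((config$n_years - u) /
                                             config$rotation_years))
    else numeric(0)
    yrs <- yrs[yrs < config$n_years]
    mag <- config$cut_magnitude *
      if (class_label == "ecological") config$ecological_cut_fraction else 1
    events <- data.frame(index = floor(yrs * opy) + 1L,
                         magnitude = rep(mag, length(yrs)))
  } else if (class_label == "passive") {
    k <- rpois(1, config$passive_break_rate * config$n_years)
    if (k > 0) {
      idx <- sort(sample.int(n, k))
      events <- data.frame(index = idx,
                           magnitude = rep(config$cut_magnitude *
                                             config$passive_cut_fraction, k))
    }
  } else if (class_label != "preservation") {
    stop("unknown management class label: ", class_label)
  }
  events[events$index >= 1 & events$index <= n, , drop = FALSE]
}

# Deterministic disturbance profile: 0 before an event, a drop of the event
# magnitude at its index, then linear recovery toward 0.
.event_profile <- function(events, n, recovery_rate) {
  d <- numeric(n)
  if (nrow(events) == 0) return(d)
  t <- seq_len(n)
  for (i in seq_len(nrow(events))) {
    k <- events$index[i]
    contrib <- pmin(0, -events$magnitude[i] + recovery_rate * (t - k))
    contrib[t < k] <- 0
    d <- pmin(d, contrib)
  }
  d
}

.harmonic_cycle <- function(n, config) {
  config$seasonal_amplitude * sin(2 * pi * (seq_len(n) - 1) / config$obs_per_year)
}

.clip_evi <- function(x) pmin(pmax(x, -2000), 10000)

#' Simulate one pixel's EVI series
#'
#' Generates a seasonal harmonic + disturbance + noise EVI record for a pixel
#' under one management regime, together with its ground-truth record.
#' Production stands are clearcut on the rotation schedule (uniform random
#' phase) with linear recovery; ecological stands follow the same schedule at
#' a fraction of the magnitude; passive stands suffer rare Poisson
#' disturbances; preservation stands have no planned breaks.  QA-degraded
#' observations receive a poor usefulness code (5-15) and a depressed EVI
#' value.  Values are clipped to the valid EVI range [-2000, 10000].
#'
#' @param class_label one of [management_classes()].
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @param n_obs optional series length override (truncates the final partial
#'   year, e.g. 360 for the canonical 16-year record starting in February).
#' @return List with `series` (an [evi_series()]) and `truth` (class, true
#'   break indices, per-event magnitudes).
#' @export
simulate_series <- function(class_label, config = sim_config(),
                            seed = config$seed, n_obs = NULL) {
  class_label <- match.arg(class_label, management_classes())
  n_full <- config$n_years * config$obs_per_year
  n <- if (is.null(n_obs)) n_full else n_obs
  if (n > n_full) stop("n_obs exceeds n_years * obs_per_year")
  set.seed(seed)
  events <- .regime_events(class_label, config, n_full)
  d <- .event_profile(events, n_full, config$recovery_rate)
  base <- config$baseline + .harmonic_cycle(n_full, config)
  noise <- if (config$noise_sd > 0) rnorm(n_full, 0, config$noise_sd) else 0
  values <- base + d + noise
  qa <- .draw_qa(n_full, config$qa_dropout_prob)
  values[qa > 4] <- values[qa > 4] - runif(sum(qa > 4), 500, 2500)
  values <- .clip_evi(values)
  events <- events[events$index <= n, , drop = FALSE]
  list(series = evi_series(values[seq_len(n)], qa = qa[seq_len(n)]),
       truth = list(class = class_label,
                    break_times = events$index,
                    magnitudes = events$magnitude))
}

.draw_qa <- function(n, dropout_prob) {
  bad <- runif(n) < dropout_prob
  qa <- sample(0:4, n, replace = TRUE)
  if (any(bad)) qa[bad] <- sample(5:15, sum(bad), replace = TRUE)
  qa
}

# P(ownership | management class); rows are classes, columns ownership types.
.ownership_class_table <- function() {
  lev <- ownership_levels()
  tab <- matrix(0, 4, length(lev), dimnames = list(management_classes(), lev))
  tab["production", c("corporate", "family", "private")] <- c(0.70, 0.20, 0.10)
  tab["ecological", c("family", "nongovernment organization", "state",
                      "corporate")] <- c(0.40, 0.30, 0.20, 0.10)
  tab["passive", c("family", "private", "local")] <- c(0.60, 0.30, 0.10)
  tab["preservation", c("federal protected", "state protected",
                        "nongovernment organization")] <- c(0.50, 0.30, 0.20)
  tab
}

# P(fine vegetation type | management class)
.veg_class_table <- function() {
  veg <- c("conifer", "hardwood", "riparian", "shrub", "nonforest")
  tab <- rbind(
    ecological   = c(0.50, 0.30, 0.10, 0.05, 0.05),
    passive      = c(0.30, 0.45, 0.10, 0.05, 0.10),
    preservation = c(0.45, 0.30, 0.15, 0.05, 0.05),
    production   = c(0.80, 0.10, 0.03, 0.02, 0.05))
  colnames(tab) <- veg
  tab
}

# mean road segments per stand by management class
.road_rate_table <- function() {
  c(ecological = 0.4, passive = 0.6, preservation = 0.1, production = 1.2)
}

#' Simulate a synthetic landscape
#'
#' Builds a full raster scene with known ground truth: a management-class map
#' made of contiguous square stands allocated to classes by exact quota, a
#' per-stand disturbance history driving the EVI cube, a QA cube with
#' independent dropout, a stand-level ownership map drawn from a fixed
#' conditional table (e.g. corporate ownership is production-heavy), road
#' segments at class-dependent density, and a fine-resolution vegetation
#' raster whose forest/conifer/riparian composition is class-dependent.
#' Non-forest pixels (fine forest fraction < 0.5) carry grass-like dynamics.
#'
#' @param config a [sim_config()].
#' @param nrow,ncol grid size in pixels; must be multiples of `patch_size`.
#' @param patch_size stand (management parcel) edge length in pixels.
#' @param fine_factor fine-to-coarse nesting factor of the vegetation raster.
#' @param cellsize pixel edge length in map units.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return List with arrays `evi` and `qa` (nrow x ncol x N), character
#'   matrices `truth`, `ownership`, `fine_veg`, logical matrix `forest`,
#'   numeric matrices `forest_frac`, `prop_conifer`, `prop_riparian`, roads
#'   data frame (`x0,y0,x1,y1`), per-stand `events`, and bookkeeping fields.
#' @export
simulate_landscape <- function(config = sim_config(), nrow = 60, ncol = 60,
                               patch_size = 5, fine_factor = 8,
                               cellsize = 250, seed = config$seed) {
  if (abs(sum(config$class_mix) - 1) > 1e-8)
    stop("class_mix must sum to 1")
  if (nrow %% patch_size != 0 || ncol %% patch_size != 0)
    stop("grid dimensions must be divisible by patch_size")
  set.seed(seed)
  cls <- management_classes()
  n <- config$n_years * config$obs_per_year
  nbr <- nrow / patch_size; nbc <- ncol / patch_size
  nblocks <- nbr * nbc

  # exact largest-remainder quota keeps realized frequencies at the mix
  quota <- floor(nblocks * config$class_mix)
  rem <- nblocks - sum(quota)
  if (rem > 0) {
    frac <- nblocks * config$class_mix - quota
    quota[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      quota[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  block_class <- sample(rep(cls, quota))
  block_mat <- matrix(block_class, nbr, nbc)

  expand <- function(bm) bm[rep(seq_len(nbr), each = patch_size),
                            rep(seq_len(nbc), each = patch_size)]
  truth <- expand(block_mat)

  own_tab <- .ownership_class_table()
  block_own <- vapply(block_class, function(cl)
    sample(colnames(own_tab), 1, prob = own_tab[cl, ]), "")
  ownership <- expand(matrix(block_own, nbr, nbc))

  # fine vegetation raster, nested fine_factor x fine_factor per pixel
  veg_tab <- .veg_class_table()
  fnr <- nrow * fine_factor; fnc <- ncol * fine_factor
  fine_veg <- matrix("", fnr, fnc)
  for (cl in cls) {
    sel <- truth == cl                      # coarse-pixel selector
    fine_sel <- sel[rep(seq_len(nrow), each = fine_factor),
                    rep(seq_len(ncol), each = fine_factor)]
    fine_veg[fine_sel] <- sample(colnames(veg_tab), sum(fine_sel),
                                 replace = TRUE, prob = veg_tab[cl, ])
  }
  forest_types <- c("conifer", "hardwood", "riparian")
  forest_frac <- upscale_proportion(fine_veg, fine_factor, forest_types)
  prop_conifer <- upscale_proportion(fine_veg, fine_factor, "conifer")
  prop_riparian <- upscale_proportion(fine_veg, fine_factor, "riparian")
  forest <- forest_frac >= 0.5

  # roads: class-dependent Poisson count per stand, short random segments
  rates <- .road_rate_table()
  roads <- list()
  ext_y <- nrow * cellsize
  for (b in seq_len(nblocks)) {
    k <- rpois(1, rates[block_class[b]])
    if (k == 0) next
    br <- (b - 1) %% nbr; bc <- (b - 1) %/% nbr
    x0 <- bc * patch_size * cellsize; y0 <- ext_y - (br + 1) * patch_size * cellsize
    w <- patch_size * cellsize
    xs <- runif(k, x0, x0 + w); ys <- runif(k, y0, y0 + w)
    ang <- runif(k, 0, pi); len <- runif(k, 0.5, 1.5) * w
    roads[[length(roads) + 1]] <-
      data.frame(x0 = xs, y0 = ys,
                 x1 = xs + len * cos(ang), y1 = ys + len * sin(ang))
  }
  roads <- if (length(roads)) do.call(rbind, roads) else
    data.frame(x0 = numeric(0), y0 = numeric(0),
               x1 = numeric(0), y1 = numeric(0))

  # EVI + QA cubes; one disturbance history per stand, iid noise per pixel
  evi <- array(NA_real_, c(nrow, ncol, n))
  qa <- array(0L, c(nrow, ncol, n))
  base <- config$baseline + .harmonic_cycle(n, config)
  grass_base <- 0.6 * config$baseline + 0.5 * .harmonic_cycle(n, config)
  events <- vector("list", nblocks)
  for (b in seq_len(nblocks)) {
    ev <- .regime_events(block_class[b], config, n)
    events[[b]] <- ev
    prof <- .event_profile(ev, n, config$recovery_rate)
    br <- (b - 1) %% nbr; bc <- (b - 1) %/% nbr
    rows <- br * patch_size + seq_len(patch_size)
    cols <- bc * patch_size + seq_len(patch_size)
    npx <- patch_size^2
    blk_forest <- forest[rows, cols]
    sig <- matrix(rep(base + prof, each = npx), npx, n)
    if (any(!blk_forest))
      sig[!blk_forest, ] <- rep(grass_base, each = sum(!blk_forest))
    vals <- sig + matrix(rnorm(npx * n, 0, config$noise_sd), npx, n)
    qa_blk <- matrix(.draw_qa(npx * n, config$qa_dropout_prob), npx, n)
    bad <- qa_blk > 4
    vals[bad] <- vals[bad] - runif(sum(bad), 500, 2500)
    evi[rows, cols, ] <- array(.clip_evi(vals), c(patch_size, patch_size, n))
    qa[rows, cols, ] <- array(qa_blk, c(patch_size, patch_size, n))
  }

  list(evi = evi, qa = qa, truth = truth, ownership = ownership,
       fine_veg = fine_veg, forest = forest, forest_frac = forest_frac,
       prop_conifer = prop_conifer, prop_riparian = prop_riparian,
       roads = roads, events = events, block_class = block_class,
       nrow = nrow, ncol = ncol, patch_size = patch_size,
       fine_factor = fine_factor, cellsize = cellsize,
       config = config, seed = seed)
}

#' Simulate expert annotations
#'
#' Each annotator labels each point with the true class with probability
#' `1 - annotator_error`, otherwise uniformly with one of the other three
#' classes, independently across annotators and points.
#'
#' @param truth_labels character vector of true classes.
#' @param annotators number of annotators (>= 1).
#' @param annotator_error per-label error probability in [0, 1).
#' @param seed RNG seed.
#' @return Data frame with `point_id` and one `annotator_<i>` column each.
#' @export
simulate_annotations <- function(truth_labels, annotators = 5,
                                 annotator_error = 0.1, seed = 1L) {
  if (annotators < 1) stop("annotators must be >= 1")
  if (annotator_error < 0 || annotator_error >= 1)
    stop("annotator_error must lie in [0, 1)")
  truth_labels <- as.character(.as_class_factor(truth_labels))
  set.seed(seed)
  npt <- length(truth_labels)
  cls <- management_classes()
  out <- data.frame(point_id = seq_len(npt))
  for (a in seq_len(annotators)) {
    lab <- truth_labels
    err <- runif(npt) < annotator_error
    if (any(err))
      lab[err] <- vapply(truth_labels[err],
                         function(tr) sample(setdiff(cls, tr), 1), "")
    out[[paste0("annotator_", a)]] <- lab
  }
  out
}
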