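#' Ownership categories
#'
#' The ten landowner types, in precedence order for overlap resolution:
#' protected public land first, then military, other public, and private
#' categories last.
#'
#' @return Character vector of length 10.
#' @export
ownership_levels <- function() {
  c("federal protected", "state protected", "military",
    "federal", "state", "local",
    "nongovernment organization", "family", "corporate", "private")
}

#' Ownership source crosswalk
#'
#' Standardisation of source-specific owner labels to the ten ownership
#' categories.  Sources: the national conservation easement database
#' ("NCED"), the Bureau of Land Management surface management agency layer
#' ("BLM"), the federal lands survey layer ("Federal Lands") and the
#' national public/private forest ownership product ("USDA").  The NCED
#' label "Regional agency" appears under several public owner types in the
#' source documentation; it is standardised here to "state", since regional
#' agencies are sub-federal public bodies, keeping the crosswalk
#' single-valued.
#'
#' @return Data frame with columns `source`, `label`, `category`.
#' @export
ownership_crosswalk <- function() {
  rbind(
    data.frame(source = "NCED",
               label = c("Federal", "State", "Regional agency",
                         "Local Government", "NGO", "Tribal", "Private"),
               category = c("federal", "state", "state", "local",
                            "nongovernment organization",
                            "nongovernment organization", "private")),
    data.frame(source = "BLM",
               label = "Bureau of Land Management", category = "federal"),
    data.frame(source = "Federal Lands",
               label = c("FWS", "NPS", "FS", "Other", "TVA", "DOD"),
               category = c("federal protected", "federal protected",
                            "federal", "federal", "federal", "military")),
    data.frame(source = "USDA",
               label = c("Other private", "Family", "Corporate"),
               category = c("nongovernment organization", "family",
                            "corporate")))
}

#' Rasterize ownership records through the crosswalk
#'
#' Maps each ownership record to one of the ten categories via
#' [ownership_crosswalk()] and rasterizes it.  Overlapping records at a cell
#' are resolved by a fixed precedence (protected > military > other public >
#' private categories, the order of [ownership_levels()]), replacing the
#' manual topology editing a cartographer would otherwise do.
#'
#' @param records data frame with `row`, `col`, `source`, `label`.
#' @param dims `c(nrow, ncol)` of the target grid.
#' @return Character matrix of categories (NA where no record falls).
#' @export
crosswalk_ownership <- function(records, dims) {
  cw <- ownership_crosswalk()
  key <- paste(records$source, records$label, sep = " :: ")
  m <- match(key, paste(cw$source, cw$label, sep = " :: "))
  if (anyNA(m)) {
    bad <- unique(key[is.na(m)])
    stop("unknown ownership source/label pair(s): ", paste(bad, collapse = "; "))
  }
  cat_rank <- match(cw$category[m], ownership_levels())
  out <- matrix(NA_character_, dims[1], dims[2])
  rank <- matrix(Inf, dims[1], dims[2])
  for (i in order(cat_rank, decreasing = TRUE)) {  # low rank written last wins
    r <- records$row[i]; c <- records$col[i]
    if (cat_rank[i] <= rank[r, c]) {
      rank[r, c] <- cat_rank[i]
      out[r, c] <- cw$category[m[i]]
    }
  }
  out
}

#' Road line density
#'
#' Length-per-area density of line segments around each cell center: the
#' total length of road falling inside a disc of the search radius, divided
#' by the disc area.  Segment/disc overlap lengths are exact (closed-form
#' chord clipping), so the estimate is linear in the geometry: duplicating a
#' segment doubles the density.
#'
#' @param segments data frame with `x0, y0, x1, y1` endpoint coordinates.
#' @param grid an `fm_raster` (used for geometry) or a list with `nrow`,
#'   `ncol`, `xll`, `yll`, `cellsize`.
#' @param radius search radius in map units (default 1000, i.e. 1 km).
#' @return `fm_raster` of densities (length/area units).
#' @export
line_density <- function(segments, grid, radius = 1000) {
  if (radius <= 0) stop("radius must be positive")
  if (inherits(grid, "fm_raster")) {
    nr <- nrow(grid$values); nc <- ncol(grid$values)
    geo <- grid
  } else {
    nr <- grid$nrow; nc <- grid$ncol
    geo <- fm_raster(matrix(0, nr, nc), xll = grid$xll, yll = grid$yll,
                     cellsize = grid$cellsize)
  }
  cc <- cell_centers(geo)
  dens <- matrix(0, nr, nc)
  if (nrow(segments) > 0) {
    ax <- segments$x0; ay <- segments$y0
    dx <- segments$x1 - ax; dy <- segments$y1 - ay
    len <- sqrt(dx^2 + dy^2)
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        cx <- cc$x[j]; cy <- cc$y[i]
        # |A + t d - C|^2 = r^2  ->  len^2 t^2 + 2 f.d t + |f|^2 - r^2 = 0
        fx <- ax - cx; fy <- ay - cy
        a <- len^2
        b <- 2 * (fx * dx + fy * dy)
        cterm <- fx^2 + fy^2 - radius^2
        disc <- b^2 - 4 * a * cterm
        ok <- disc > 0 & a > 0
        if (!any(ok)) next
        sq <- sqrt(pmax(disc[ok], 0))
        t1 <- pmax((-b[ok] - sq) / (2 * a[ok]), 0)
        t2 <- pmin((-b[ok] + sq) / (2 * a[ok]), 1)
        inside <- pmax(t2 - t1, 0) * len[ok]
        dens[i, j] <- sum(inside) / (pi * radius^2)
      }
    }
  }
  fm_raster(dens, xll = geo$xll, yll = geo$yll, cellsize = geo$cellsize)
}

#' Upscale fine-class proportions
#'
#' Fraction of fine-resolution cells belonging to a class set within each
#' coarse cell, for integrally nested grids (each coarse cell covers exactly
#' `factor` x `factor` fine cells).  Non-nesting real-world grids must be
#' resampled to a nesting grid first.
#'
#' @param fine categorical matrix (character or factor codes).
#' @param factor integer nesting factor.
#' @param class_set classes counted in the numerator (empty set gives 0).
#' @return Numeric matrix of proportions in [0, 1], dimensions
#'   `dim(fine) / factor`.
#' @export
upscale_proportion <- function(fine, factor, class_set) {
  fd <- dim(fine)
  if (any(fd %% factor != 0))
    stop("fine grid does not nest integrally in the coarse grid ",
         "(dimensions not divisible by factor); resample first")
  ind <- matrix(as.numeric(fine %in% class_set), fd[1], fd[2])
  nr <- fd[1] / factor; nc <- fd[2] / factor
  # block mean via two successive aggregations
  rowagg <- rowsum(ind, rep(seq_len(nr), each = factor))
  colagg <- t(rowsum(t(rowagg), rep(seq_len(nc), each = factor)))
  out <- colagg / factor^2
  dimnames(out) <- NULL
  out
}

#' Training-pixel mask
#'
#' A pixel qualifies as training when it is at least half forest and at
#' least half covered by a single management class (both thresholds
#' inclusive).
#'
#' @param forest_frac numeric matrix of forest fractions in [0, 1].
#' @param class_frac numeric matrix of maximal single-class fractions.
#' @return Logical matrix.
#' @export
training_mask <- function(forest_frac, class_frac) {
  if (!identical(dim(forest_frac), dim(class_frac)))
    stop("forest_frac and class_frac must have identical dimensions")
  forest_frac >= 0.5 & class_frac >= 0.5
}

.transition_vocabulary <- function() {
  types <- c("forest", "grass", "shrub", "urban", "agriculture",
             "water", "barren")
  c("none", as.vector(outer(types, types,
                            function(a, b) paste0(a, "_to_", b))))
}

#' Reconcile the forest mask across land-cover vintages
#'
#' A cell counts as forest if it is forest in any of the three land-cover
#' vintages, or if its from-to transition label indicates a harvest/
#' succession pathway: forest to grass, grass to shrub, or shrub to forest.
#' This recovers clearcuts that a single-date forest layer misses.
#'
#' @param forest_2001,forest_2006,forest_2011 logical matrices.
#' @param transitions character matrix of `<from>_to_<to>` codes or "none".
#' @return Logical matrix.
#' @export
reconcile_forest_mask <- function(forest_2001, forest_2006, forest_2011,
                                  transitions) {
  dims <- dim(forest_2001)
  if (!identical(dims, dim(forest_2006)) || !identical(dims, dim(forest_2011)) ||
      !identical(dims, dim(transitions)))
    stop("all input layers must share dimensions")
  bad <- setdiff(unique(as.vector(transitions)), .transition_vocabulary())
  if (length(bad) > 0)
    stop("unknown transition code(s): ", paste(bad, collapse = ", "))
  forest_2001 | forest_2006 | forest_2011 |
    transitions %in% c("forest_to_grass", "grass_to_shrub", "shrub_to_forest")
}

#' Consensus labels from multi-annotator tables
#'
#' Assigns each point the modal annotator label when its share of the
#' annotations reaches the consensus threshold (default 80%, so 4 of 5
#' annotators suffice); other points are returned unresolved and are dropped
#' from training sets.  The result does not depend on annotator order.
#'
#' @param annotations data frame from [simulate_annotations()] (a `point_id`
#'   column plus one column per annotator), or a character matrix with one
#'   row per point.
#' @param threshold consensus share in (0.5, 1].
#' @return List with `labels` (character, NA where unresolved), `unresolved`
#'   (integer indices) and `point_id`.
#' @export
consensus_labels <- function(annotations, threshold = 0.8) {
  if (threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1]")
  if (is.data.frame(annotations)) {
    point_id <- if ("point_id" %in% names(annotations)) annotations$point_id
                else seq_len(nrow(annotations))
    lab <- as.matrix(annotations[, setdiff(names(annotations), "point_id"),
                                 drop = FALSE])
  } else {
    point_id <- seq_len(nrow(annotations))
    lab <- as.matrix(annotations)
  }
  if (ncol(lab) < 1) stop("at least one annotator is required")
  n_ann <- ncol(lab)
  labels <- rep(NA_character_, nrow(lab))
  for (i in seq_len(nrow(lab))) {
    tab <- table(lab[i, ])
    if (max(tab) / n_ann >= threshold)
      labels[i] <- names(tab)[.which_max_first(tab)]
  }
  list(labels = labels, unresolved = which(is.na(labels)),
       point_id = point_id)
}
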