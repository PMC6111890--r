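#' Published regional validation confusion matrices
#'
#' The validation confusion matrices of the released southeastern (SEUS) and
#' Pacific-northwest (PNW) regional forest-management maps: for each region,
#' the internal 10-fold cross-validation matrix (n = 800 training points)
#' and the external hold-out matrix (n = 178 SEUS, n = 194 PNW).  Rows are
#' the mapped (predicted) class, columns the reference class, both in
#' [management_classes()] order.  Feeding these to
#' [accuracy_from_matrix()] reproduces the published producers/users/overall
#' accuracies; they are also the standard input for the aggregation
#' uncertainty channel of [posterior_uncertainty()].
#'
#' Note the published SEUS external overall accuracy is quoted inconsistently
#' at its source (67% in one place, 0.62 in another) while the matrix trace
#' gives 124/178 = 0.697; this package always reports the matrix-derived
#' value.
#'
#' @return Nested list `list(seus = list(internal, external), pnw = ...)` of
#'   4x4 integer matrices with class dimnames.
#' @export
regional_confusion_matrices <- function() {
  cls <- management_classes()
  mk <- function(...) {
    m <- matrix(c(...), 4, 4, byrow = TRUE,
                dimnames = list(predicted = cls, reference = cls))
    storage.mode(m) <- "integer"
    m
  }
  list(
    seus = list(
      internal = mk(25, 1, 1, 1,
                    0, 188, 4, 38,
                    1, 3, 66, 6,
                    0, 25, 5, 436),
      external = mk(1, 0, 2, 0,
                    0, 24, 3, 22,
                    0, 4, 13, 3,
                    1, 15, 4, 86)),
    pnw = list(
      internal = mk(57, 17, 0, 3,
                    4, 364, 6, 15,
                    0, 8, 195, 0,
                    1, 22, 0, 108),
      external = mk(1, 15, 0, 2,
                    4, 83, 3, 8,
                    0, 5, 43, 0,
                    1, 20, 1, 8)))
}
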