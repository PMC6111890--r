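#' Lightweight single-band raster
#'
#' A minimal in-memory raster: a numeric, integer, logical or factor matrix
#' plus georeferencing metadata (lower-left corner, square cell size, nodata
#' value).  Rows are stored north-up: row 1 is the northernmost row, matching
#' the on-disk order of the ASCII grid interchange format used by
#' [write_raster()].  Synthetic landscapes use an arbitrary Cartesian
#' georeference; real-data projections are passed through untouched in the
#' `crs` field.
#'
#' @param values matrix of cell values (factor matrices are stored as integer
#'   codes with a `levels` attribute).
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize cell edge length (map units).
#' @param nodata value written for missing cells on disk.
#' @param crs free-form projection string carried as metadata.
#' @return An `fm_raster` object.
#' @export
fm_raster <- function(values, xll = 0, yll = 0, cellsize = 250,
                      nodata = -9999, crs = "cartesian") {
  lev <- NULL
  if (is.factor(values)) stop("pass a matrix, not a bare factor")
  if (!is.null(attr(values, "levels"))) lev <- attr(values, "levels")
  if (!is.matrix(values)) stop("values must be a matrix")
  structure(
    list(values = values, xll = xll, yll = yll, cellsize = cellsize,
         nodata = nodata, crs = crs, levels = lev),
    class = "fm_raster")
}

#' @export
print.fm_raster <- function(x, ...) {
  cat(sprintf("<fm_raster> %d x %d, cellsize %g, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  invisible(x)
}

#' @export
dim.fm_raster <- function(x) dim(x$values)

#' Cell-center coordinates of a raster
#'
#' @param r an `fm_raster`.
#' @return List with `x` (length ncol) and `y` (length nrow, north to south).
#' @export
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  list(x = r$xll + (seq_len(nc) - 0.5) * r$cellsize,
       y = r$yll + (nr - seq_len(nr) + 0.5) * r$cellsize)
}

#' Write / read a raster as an ASCII grid
#'
#' Plain-text ESRI ASCII grid (`.asc`) with full double precision, so a
#' write-then-read round trip restores values, the nodata mask and the
#' geotransform exactly.  A categorical raster with class levels additionally
#' writes a `<path>.vat.csv` sidecar attribute table with `Value` and
#' `Management` (or `Category`) columns, which `read_raster` restores.
#'
#' @param r an `fm_raster`.
#' @param path output file path (`.asc` suggested).
#' @param attr_name name of the category column in the sidecar table.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns an
#'   `fm_raster`.
#' @export
write_raster <- function(r, path, attr_name = "Management") {
  stopifnot(inherits(r, "fm_raster"))
  v <- r$values
  if (is.logical(v)) v <- v + 0L
  v[is.na(v)] <- r$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$cellsize),
    sprintf("NODATA_value %.10g", r$nodata)), con)
  write.table(format(v, digits = 17, trim = TRUE, scientific = TRUE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (!is.null(r$levels)) {
    vat <- data.frame(Value = seq_along(r$levels), check.names = FALSE)
    vat[[attr_name]] <- r$levels
    write.csv(vat, paste0(path, ".vat.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  if (!file.exists(path))
    stop("raster file does not exist: ", path)
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys))
    stop("malformed ASCII grid (missing header fields): ", path)
  vals <- stats::setNames(unname(vals), keys)
  m <- matrix(scan(path, skip = 6, quiet = TRUE),
              nrow = vals[["nrows"]], ncol = vals[["ncols"]], byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA
  lev <- NULL
  vat_path <- paste0(path, ".vat.csv")
  if (file.exists(vat_path)) {
    vat <- read.csv(vat_path)
    lev <- as.character(vat[[2]])[order(vat$Value)]
    storage.mode(m) <- "integer"
    attr(m, "levels") <- lev
  }
  fm_raster(m, xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
            cellsize = vals[["cellsize"]], nodata = vals[["nodata_value"]])
}

#' Write / read a multi-band raster stack
#'
#' A stack is a named list of `fm_raster` bands on a shared grid.  On disk it
#' is a directory of one `.asc` per band plus a `bands.txt` index preserving
#' band order.
#'
#' @param stack named list of `fm_raster` objects.
#' @param dir directory to create.
#' @return `write_raster_stack` returns `dir` invisibly; `read_raster_stack`
#'   the named list in index order.
#' @export
write_raster_stack <- function(stack, dir) {
  stopifnot(is.list(stack), length(names(stack)) == length(stack))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack))
    write_raster(stack[[nm]], file.path(dir, paste0(nm, ".asc")))
  writeLines(names(stack), file.path(dir, "bands.txt"))
  invisible(dir)
}

#' @rdname write_raster_stack
#' @export
read_raster_stack <- function(dir) {
  bands <- readLines(file.path(dir, "bands.txt"))
  out <- lapply(bands, function(nm) read_raster(file.path(dir, paste0(nm, ".asc"))))
  names(out) <- bands
  out
}

# matrix -> categorical fm_raster helper
.factor_raster <- function(f_matrix, levels, ...) {
  m <- matrix(match(as.character(f_matrix), levels), nrow = nrow(f_matrix))
  attr(m, "levels") <- levels
  fm_raster(m, ...)
}
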