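#' Gridded climate layer
#'
#' A minimal north-up, cell-center-registered raster container: a numeric
#' matrix whose first row is the northernmost row, plus the lower-left
#' corner, square cell size and a nodata sentinel. Matches the ESRI ASCII
#' grid model used for file IO ([write_asc()], [read_asc()]).
#'
#' @param values numeric matrix (row 1 = north).
#' @param xll,yll x/y coordinate of the lower-left corner of the grid.
#' @param cellsize square cell size (same units as xll/yll; positive).
#' @param varname optional layer name.
#' @param nodata nodata sentinel value used on write.
#' @return Object of class `"climate_grid"`.
#' @export
climate_grid <- function(values, xll, yll, cellsize, varname = "layer",
                         nodata = -9999) {
  stopifnot(is.matrix(values), is.numeric(cellsize), cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, varname = varname, nodata = nodata),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("climate_grid '%s': %d rows x %d cols, cellsize %g, ll (%g, %g)\n",
              x$varname, nrow(x$values), ncol(x$values), x$cellsize,
              x$xll, x$yll))
  cat(sprintf("  values: [%g, %g], NA count %d\n",
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE)),
              sum(is.na(x$values))))
  invisible(x)
}

#' @rdname climate_grid
#' @param g a `climate_grid`.
#' @return `grid_coords()`: list with vectors `x` (cell-center longitudes,
#'   west to east) and `y` (cell-center latitudes, north to south, matching
#'   matrix row order).
#' @export
grid_coords <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  list(x = g$xll + (seq_len(nc) - 0.5) * g$cellsize,
       y = g$yll + (nr - seq_len(nr) + 0.5) * g$cellsize)
}

same_geometry <- function(a, b, tol = 1e-9) {
  nrow(a$values) == nrow(b$values) && ncol(a$values) == ncol(b$values) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster IO for the `climate_grid` container. Values equal to
#' the header's `NODATA_value` are read back as `NA`. Writing uses full
#' double precision (`%.17g`) so a write/read cycle is bit-exact.
#'
#' @param g a [climate_grid()].
#' @param path file path (conventionally `.asc`).
#' @return `read_asc()` returns a `climate_grid`; `write_asc()` returns
#'   `path` invisibly.
#' @export
write_asc <- function(g, path) {
  stopifnot(inherits(g, "climate_grid"))
  v <- g$values
  v[is.na(v)] <- g$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(v)),
               sprintf("nrows %d", nrow(v)),
               sprintf("xllcorner %.17g", g$xll),
               sprintf("yllcorner %.17g", g$yll),
               sprintf("cellsize %.17g", g$cellsize),
               sprintf("NODATA_value %.17g", g$nodata)), con)
  writeLines(apply(v, 1L, function(r) paste(sprintf("%.17g", r),
                                            collapse = " ")), con)
  invisible(path)
}

#' @rdname write_asc
#' @param varname layer name to attach on read.
#' @export
read_asc <- function(path, varname = NULL) {
  if (!file.exists(path)) stop("read_asc: no such file: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("read_asc: malformed header, missing: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  climate_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
               varname = varname %||% sub("\\.asc$", "", basename(path)),
               nodata = nodata)
}
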