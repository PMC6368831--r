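#' Construct a single-band grid
#'
#' A grid is the basic raster carrier used throughout nichecal: a numeric
#' matrix in map orientation (row 1 is the northernmost row), a logical
#' nodata mask of the same shape, and a simple georeference (lower-left
#' corner of the lower-left cell plus a square cell size, as in the ESRI
#' ASCII grid convention).
#'
#' @param values numeric matrix, row 1 = top (north). Non-finite entries are
#'   masked automatically.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize cell edge length (must be nonzero; square cells only).
#' @param mask optional logical matrix, `TRUE` where nodata. Combined with
#'   the non-finite entries of `values`.
#' @param crs free-text coordinate system label (not interpreted).
#' @return an object of class `enm_grid`.
#' @export
enm_grid <- function(values, xll = 0, yll = 0, cellsize = 1, mask = NULL,
                     crs = "") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.finite(cellsize) || cellsize == 0)
    stop("cellsize must be nonzero and finite", call. = FALSE)
  m <- !is.finite(values)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(values)))
      stop("mask and values dimensions differ", call. = FALSE)
    m <- m | mask
  }
  values[m] <- NA_real_
  structure(
    list(values = values, mask = m, xll = as.numeric(xll),
         yll = as.numeric(yll), cellsize = as.numeric(cellsize),
         crs = as.character(crs)),
    class = "enm_grid")
}

#' @export
print.enm_grid <- function(x, ...) {
  cat(sprintf("<enm_grid> %d rows x %d cols, cellsize %g, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  cat(sprintf("  %d masked cells; value range [%g, %g]\n",
              sum(x$mask),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' @export
dim.enm_grid <- function(x) dim(x$values)

grid_compatible <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Six-number affine geotransform of a grid
#'
#' Returns `(x_origin, cellsize, 0, y_origin, 0, -cellsize)` with the origin
#' at the upper-left corner, the common GDAL-style convention.
#' @param grid an `enm_grid`.
#' @export
grid_transform <- function(grid) {
  c(grid$xll, grid$cellsize, 0,
    grid$yll + nrow(grid$values) * grid$cellsize, 0, -grid$cellsize)
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard `.asc` text format (NCOLS/NROWS/XLLCORNER/YLLCORNER/
#' CELLSIZE/NODATA_value header followed by row-major values, first row =
#' north). `XLLCENTER`/`YLLCENTER` headers are accepted and converted to the
#' corner convention.
#'
#' @param path path to the `.asc` file.
#' @return an `enm_grid` with nodata cells masked.
#' @export
read_grid <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read grid: no such file '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2)
    stop(sprintf("'%s': not an ESRI ASCII grid (file too short)", path),
         call. = FALSE)
  hdr <- list()
  i <- 1
  repeat {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) == 2 && grepl("^[A-Za-z_]+$", tok[1]) &&
        !is.na(suppressWarnings(as.numeric(tok[2])))) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      i <- i + 1
      if (i > length(lines)) break
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop(sprintf("'%s': malformed ESRI ASCII header (need NCOLS/NROWS/CELLSIZE)",
                 path), call. = FALSE)
  if (hdr$cellsize == 0)
    stop(sprintf("'%s': CELLSIZE is zero", path), call. = FALSE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (nc < 1 || nr < 1)
    stop(sprintf("'%s': non-positive grid dimensions", path), call. = FALSE)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else if (!is.null(hdr$xllcenter)) hdr$xllcenter - hdr$cellsize / 2
         else stop(sprintf("'%s': missing XLLCORNER/XLLCENTER", path),
                   call. = FALSE)
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else if (!is.null(hdr$yllcenter)) hdr$yllcenter - hdr$cellsize / 2
         else stop(sprintf("'%s': missing YLLCORNER/YLLCENTER", path),
                   call. = FALSE)
  vals <- suppressWarnings(
    as.numeric(unlist(strsplit(trimws(lines[i:length(lines)]), "\\s+"))))
  vals <- vals[!is.na(vals) | TRUE]  # keep NAs: they signal parse failures
  if (length(vals) != nc * nr)
    stop(sprintf("'%s': expected %d values, found %d", path, nc * nr,
                 length(vals)), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  msk <- NULL
  if (!is.null(hdr$nodata_value)) msk <- m == hdr$nodata_value
  enm_grid(m, xll = xll, yll = yll, cellsize = hdr$cellsize, mask = msk)
}

#' Write an ESRI ASCII grid
#'
#' Values are printed with 6 significant digits; masked cells are written as
#' the `nodata` sentinel.
#'
#' @param grid an `enm_grid`.
#' @param path output path.
#' @param nodata numeric sentinel for masked cells.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "enm_grid"))
  v <- grid$values
  v[grid$mask] <- nodata
  hdr <- c(
    sprintf("NCOLS %d", ncol(v)),
    sprintf("NROWS %d", nrow(v)),
    sprintf("XLLCORNER %.10g", grid$xll),
    sprintf("YLLCORNER %.10g", grid$yll),
    sprintf("CELLSIZE %.10g", grid$cellsize),
    sprintf("NODATA_value %g", nodata))
  body <- apply(v, 1, function(r) paste(formatC(signif(r, 6), format = "g",
                                                digits = 6), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Cell indexing: points are assigned to the containing cell with half-open
# cells; a point exactly on a shared vertical edge belongs to the cell to the
# east, on a shared horizontal edge to the cell to the south.
cell_index_from_xy <- function(grid, lon, lat) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cellsize
  col <- floor((lon - grid$xll) / cs) + 1L
  ry <- (lat - grid$yll) / cs
  row_from_bottom <- ceiling(ry)                 # edge point -> south cell
  row_from_bottom[ry == nr] <- nr                # top edge of grid included
  row <- nr - row_from_bottom + 1L
  off <- col < 1L | col > nc | row_from_bottom < 1L | row_from_bottom > nr |
    !is.finite(lon) | !is.finite(lat)
  row[off] <- NA_integer_; col[off] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Coordinates of cell centers
#'
#' @param grid an `enm_grid`.
#' @param rows,cols integer vectors of (matrix) row/column indices.
#' @return two-column matrix of longitude/latitude at cell centers.
#' @export
cell_centers <- function(grid, rows, cols) {
  nr <- nrow(grid$values); cs <- grid$cellsize
  cbind(longitude = grid$xll + (cols - 0.5) * cs,
        latitude  = grid$yll + (nr - rows + 0.5) * cs)
}
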