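#' Build an aligned stack of environmental layers
#'
#' Layers must share dimensions, origin and cell size. The stack carries the
#' union of the layers' nodata masks and the per-layer min/max over unmasked
#' cells (the calibration ranges used to rescale features).
#'
#' @param grids named list of `enm_grid` objects.
#' @param names optional character vector of layer names (defaults to the
#'   list names).
#' @return an object of class `enm_stack`.
#' @export
enm_stack <- function(grids, names = NULL) {
  if (length(grids) < 1) stop("need at least one layer", call. = FALSE)
  if (is.null(names)) names <- base::names(grids)
  if (is.null(names) || any(!nzchar(names)))
    stop("every layer needs a name", call. = FALSE)
  if (anyDuplicated(names))
    stop("layer names must be unique", call. = FALSE)
  ref <- grids[[1]]
  for (g in grids) {
    if (!inherits(g, "enm_grid")) stop("layers must be enm_grid", call. = FALSE)
    if (!grid_compatible(ref, g))
      stop("layers are not aligned (dimensions/origin/cellsize differ)",
           call. = FALSE)
  }
  mask <- Reduce(`|`, lapply(grids, `[[`, "mask"))
  grids <- lapply(grids, function(g) {
    g$mask <- mask; g$values[mask] <- NA_real_; g
  })
  ranges <- t(vapply(grids, function(g)
    range(g$values[!mask]), numeric(2)))
  colnames(ranges) <- c("min", "max")
  rownames(ranges) <- names
  structure(list(layers = grids, names = names, mask = mask, ranges = ranges,
                 xll = ref$xll, yll = ref$yll, cellsize = ref$cellsize),
            class = "enm_stack")
}

#' @export
print.enm_stack <- function(x, ...) {
  cat(sprintf("<enm_stack> %d layers (%s), %d x %d cells, %d masked\n",
              length(x$layers), paste(x$names, collapse = ", "),
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

#' Read all single-band ASCII grids in a directory as a stack
#'
#' Layer names are the file names without extension, in alphabetical order
#' so that calibration (M) and transfer (G) stacks line up by name.
#'
#' @param dir directory containing `.asc` files.
#' @return an `enm_stack`.
#' @export
read_stack <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0)
    stop(sprintf("no .asc layers found in '%s'", dir), call. = FALSE)
  grids <- lapply(files, read_grid)
  names(grids) <- tools::file_path_sans_ext(basename(files))
  enm_stack(grids)
}

#' Write every layer of a stack as ASCII grids
#' @param stack an `enm_stack`.
#' @param dir output directory (created if missing).
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(stack$layers))
    write_grid(stack$layers[[i]], file.path(dir, paste0(stack$names[i], ".asc")))
  invisible(dir)
}

#' Environmental values of all unmasked cells
#'
#' @param stack an `enm_stack`.
#' @return list with `values` (cells x variables matrix, one row per unmasked
#'   cell in column-major matrix order) and `cells` (their linear indices into
#'   the layer matrices).
#' @export
stack_values <- function(stack) {
  keep <- which(!stack$mask)
  vals <- vapply(stack$layers, function(g) g$values[keep],
                 numeric(length(keep)))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = length(keep))
  colnames(vals) <- stack$names
  list(values = vals, cells = keep)
}

#' Extract environmental values at occurrence records
#'
#' Each record is assigned to the cell containing it (no interpolation).
#' Records falling off-grid or on masked cells are dropped with a warning;
#' the counts are attached as the `"report"` attribute.
#'
#' @param stack an `enm_stack` or `enm_grid`.
#' @param occ an `enm_occurrences` object (see [read_occurrences()]).
#' @return numeric matrix records x variables (single column for a grid),
#'   with attributes `cells` (linear cell index of each kept record) and
#'   `report` (named counts: kept, off_grid, masked).
#' @export
extract_values <- function(stack, occ) {
  stopifnot(inherits(occ, "enm_occurrences"))
  single <- inherits(stack, "enm_grid")
  ref <- if (single) stack else stack$layers[[1]]
  idx <- cell_index_from_xy(ref, occ$records$longitude, occ$records$latitude)
  off <- is.na(idx[, 1])
  lin <- rep(NA_integer_, nrow(idx))
  lin[!off] <- idx[!off, 1] + (idx[!off, 2] - 1L) * nrow(ref$values)
  mask <- if (single) stack$mask else stack$mask
  masked <- !off & mask[lin]
  keep <- !off & !masked
  if (!any(keep))
    stop("all occurrence records fall off-grid or on masked cells",
         call. = FALSE)
  if (any(!keep))
    warning(sprintf("dropped %d occurrence record(s): %d off-grid, %d on masked cells",
                    sum(!keep), sum(off), sum(masked)), call. = FALSE)
  lk <- lin[keep]
  if (single) {
    out <- matrix(stack$values[lk], ncol = 1)
    colnames(out) <- "value"
  } else {
    out <- vapply(stack$layers, function(g) g$values[lk], numeric(length(lk)))
    if (!is.matrix(out)) out <- matrix(out, nrow = length(lk),
                                       dimnames = list(NULL, stack$names))
  }
  attr(out, "cells") <- lk
  attr(out, "report") <- c(kept = sum(keep), off_grid = sum(off),
                           masked = sum(masked))
  out
}
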