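#' Feature-class specification for the model engine
#'
#' The engine expands environmental variables (rescaled to [0, 1] by their
#' calibration ranges) into Maxent's feature families: linear (`l`),
#' quadratic (`q`), pairwise product (`p`), threshold step functions (`t`)
#' and hinge ramps (`h`). Threshold and hinge knots are placed at evenly
#' spaced positions on the rescaled range, so the basis is deterministic and
#' independent of the presence sample.
#'
#' @param classes character vector, subset of `c("l","q","p","t","h")`, or a
#'   single compact string such as `"lqp"`.
#' @param threshold_knots knots per variable for threshold features.
#' @param hinge_knots knots per variable and direction for hinge features.
#' @return an object of class `feature_spec`.
#' @export
feature_spec <- function(classes = "lq", threshold_knots = 25,
                         hinge_knots = 25) {
  if (length(classes) == 1 && nchar(classes) > 1)
    classes <- strsplit(classes, "")[[1]]
  classes <- unique(classes)
  bad <- setdiff(classes, c("l", "q", "p", "t", "h"))
  if (length(bad))
    stop(sprintf("unknown feature class(es): %s", paste(bad, collapse = ",")),
         call. = FALSE)
  if (length(classes) == 0) stop("classes must be nonempty", call. = FALSE)
  if (threshold_knots < 1 || hinge_knots < 1)
    stop("knot counts must be >= 1", call. = FALSE)
  structure(list(classes = classes,
                 threshold_knots = as.integer(threshold_knots),
                 hinge_knots = as.integer(hinge_knots)),
            class = "feature_spec")
}

fc_string <- function(spec) {
  paste(intersect(c("l", "q", "p", "t", "h"), spec$classes), collapse = "")
}

#' Feature metadata for a variable set and feature spec
#'
#' @param varnames character vector of variable names.
#' @param spec a [feature_spec()].
#' @return data.frame with one row per feature: `name`, `class`, `var1`,
#'   `var2` (products only), `knot` and `dir` ("fwd"/"rev", hinges only).
#' @export
build_feature_meta <- function(varnames, spec) {
  rows <- list()
  add <- function(name, class, var1, var2 = NA, knot = NA, dir = NA)
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, class = class, var1 = var1, var2 = var2,
      knot = knot, dir = dir, stringsAsFactors = FALSE)
  if ("l" %in% spec$classes)
    for (v in varnames) add(v, "l", v)
  if ("q" %in% spec$classes)
    for (v in varnames) add(paste0(v, "^2"), "q", v)
  if ("p" %in% spec$classes && length(varnames) >= 2) {
    for (i in seq_len(length(varnames) - 1))
      for (j in (i + 1):length(varnames))
        add(paste0(varnames[i], "*", varnames[j]), "p",
            varnames[i], varnames[j])
  }
  if ("t" %in% spec$classes) {
    knots <- seq_len(spec$threshold_knots) / (spec$threshold_knots + 1)
    for (v in varnames)
      for (k in knots) add(sprintf("t(%s>%.4f)", v, k), "t", v, knot = k)
  }
  if ("h" %in% spec$classes) {
    knots <- seq_len(spec$hinge_knots) / (spec$hinge_knots + 1)
    for (v in varnames)
      for (k in knots) {
        add(sprintf("h(%s,%.4f,f)", v, k), "h", v, knot = k, dir = "fwd")
        add(sprintf("h(%s,%.4f,r)", v, k), "h", v, knot = k, dir = "rev")
      }
  }
  do.call(rbind, rows)
}

#' Evaluate features on rescaled variable values
#'
#' @param z matrix cells x variables of values already rescaled to the
#'   calibration [0, 1] range (values outside [0, 1] are legal: that is how
#'   free extrapolation works).
#' @param meta feature metadata from [build_feature_meta()].
#' @return numeric matrix cells x features.
#' @export
expand_features <- function(z, meta) {
  out <- matrix(0, nrow = nrow(z), ncol = nrow(meta),
                dimnames = list(NULL, meta$name))
  for (i in seq_len(nrow(meta))) {
    m <- meta[i, ]
    x <- z[, m$var1]
    out[, i] <- switch(m$class,
      l = x,
      q = x * x,
      p = x * z[, m$var2],
      t = as.numeric(x > m$knot),
      h = if (m$dir == "fwd") pmax(0, (x - m$knot) / (1 - m$knot))
          else pmax(0, (m$knot - x) / m$knot))
  }
  out
}

rescale_env <- function(values, ranges, clamp = FALSE) {
  z <- sweep(values, 2, ranges[colnames(values), "min"], `-`)
  z <- sweep(z, 2, ranges[colnames(values), "max"] -
                     ranges[colnames(values), "min"], `/`)
  if (clamp) z <- pmin(pmax(z, 0), 1)
  z
}

#' Build a design matrix from raw environmental values
#'
#' Rescales each variable to [0, 1] by its calibration range and expands the
#' requested feature classes.
#'
#' @param values matrix cells x variables of raw environmental values.
#' @param spec a [feature_spec()].
#' @param ranges matrix with rownames = variable names and columns
#'   `min`/`max` (calibration ranges).
#' @return list with `design` (cells x features matrix) and `meta`.
#' @export
build_features <- function(values, spec, ranges) {
  if (is.null(colnames(values)))
    stop("values matrix needs variable column names", call. = FALSE)
  rg <- ranges[colnames(values), , drop = FALSE]
  flat <- rg[, "max"] - rg[, "min"] <= 0
  if (any(flat))
    stop(sprintf("constant variable(s): %s",
                 paste(rownames(rg)[flat], collapse = ", ")), call. = FALSE)
  meta <- build_feature_meta(colnames(values), spec)
  if (is.null(meta) || nrow(meta) == 0)
    stop(sprintf("feature classes {%s} yield no features for %d variable(s)",
                 fc_string(spec), ncol(values)), call. = FALSE)
  list(design = expand_features(rescale_env(values, rg), meta), meta = meta)
}
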