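# Maxent-style penalized Gibbs model engine.
#
# The model is the Gibbs density raw_i = exp(lambda . f_i) / Z over the
# calibration cells, fitted by minimizing the negative presence
# log-likelihood plus an L1 penalty sum_j beta_j |lambda_j|, where
# beta_j = rm * base(class, n_presences) * sd_j(presences). The convex
# problem is solved through the equivalence with a weighted lasso logistic
# regression of presences against background (background weight 100), using
# glmnet as the coordinate-descent solver; the path's final lambda is scaled
# so that the effective penalty per feature equals beta_j relative to the
# per-presence log-likelihood.

# Base regularization by feature class, linearly interpolated on the number
# of presences and held constant outside the tabulated range (Maxent's
# published defaults).
base_regularization <- function(class, n) {
  tab <- switch(class,
    l = ,
    q = list(x = c(10, 30, 100), y = c(1.0, 0.2, 0.05)),
    p = list(x = c(0, 10, 17),   y = c(2.6, 1.6, 1.4)),
    t = list(x = c(0, 100),      y = c(2.0, 1.0)),
    h = list(x = c(0, 1),        y = c(0.5, 0.5)))
  stats::approx(tab$x, tab$y, xout = n, rule = 2)$y
}

#' Fit a penalized Gibbs (Maxent-style) model from design matrices
#'
#' Low-level fitting routine operating on pre-built feature rows. Most users
#' should call [enm_maxent()] instead, which handles extraction, rescaling
#' and background assembly.
#'
#' @param pres design matrix of presence rows (one per unique presence cell).
#' @param bg design matrix of background rows (the calibration cells; the
#'   Gibbs density is normalized over these rows).
#' @param rm positive regularization multiplier.
#' @param meta feature metadata (from [build_features()]).
#' @param ranges calibration ranges carried into the model for prediction.
#' @param spec the [feature_spec()] used to build the rows.
#' @param tol coordinate-descent convergence tolerance.
#' @param maxit maximum solver iterations.
#' @return an object of class `enm_model`.
#' @export
fit_gibbs <- function(pres, bg, rm, meta, ranges, spec,
                      tol = 1e-7, maxit = 1e4) {
  np <- nrow(pres)
  if (is.null(np) || np < 2)
    stop("need at least 2 unique presence cells", call. = FALSE)
  if (rm <= 0) stop("regularization multiplier must be positive", call. = FALSE)
  s <- apply(pres, 2, stats::sd)
  s_all <- apply(rbind(pres, bg), 2, stats::sd)
  s[!is.finite(s) | s == 0] <- s_all[!is.finite(s) | s == 0]
  s[!is.finite(s) | s == 0] <- 1  # constant feature: penalty scale irrelevant
  reg <- rm * vapply(meta$class, base_regularization, numeric(1), n = np) * s
  x <- rbind(pres, bg)
  # glmnet requires at least two predictor columns; pad degenerate
  # single-feature designs with an inert zero column
  padded <- ncol(x) == 1
  if (padded) {
    x <- cbind(x, `(pad)` = 0)
    reg <- c(reg, mean(reg))
  }
  y <- c(rep(1, np), rep(0, nrow(bg)))
  w <- ifelse(y == 1, 1, 100)
  lambdas <- 10^(seq(4, 0, length.out = 200)) *
    sum(reg) / length(reg) * sum(y) / sum(w)
  fit <- glmnet::glmnet(x, y, family = "binomial", weights = w,
                        penalty.factor = reg, lambda = lambdas,
                        standardize = FALSE, thresh = tol, maxit = maxit)
  if (!is.null(fit$jerr) && fit$jerr != 0)
    stop(sprintf("glmnet solver failed (jerr = %d, npasses = %d)",
                 fit$jerr, fit$npasses), call. = FALSE)
  beta <- fit$beta[, ncol(fit$beta)]
  if (padded) beta <- beta[-length(beta)]
  if (any(!is.finite(beta)))
    stop("solver returned non-finite coefficients", call. = FALSE)
  eta_bg <- drop(bg %*% beta)
  logZ <- log_sum_exp(eta_bg)
  raw <- exp(eta_bg - logZ)
  H <- -sum(raw * log(pmax(raw, .Machine$double.xmin)))
  structure(list(meta = meta, beta = beta, ranges = ranges, spec = spec,
                 rm = rm, n_presences = np, logZ = logZ, entropy = H),
            class = "enm_model")
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' @export
print.enm_model <- function(x, ...) {
  cat(sprintf("<enm_model> fc=%s rm=%g: %d/%d nonzero features, n=%d, H=%.3f\n",
              fc_string(x$spec), x$rm, count_parameters(x), length(x$beta),
              x$n_presences, x$entropy))
  invisible(x)
}

#' Number of model parameters
#'
#' Counts the features with nonzero coefficients; the L1 solver produces
#' exact zeros, so this is the parameter count used in AICc.
#' @param model an `enm_model`.
#' @export
count_parameters <- function(model) sum(model$beta != 0)

#' Fit a Maxent-style model from occurrences and an environmental stack
#'
#' Extracts occurrence cells (deduplicating to one presence per cell),
#' assembles the background from all unmasked calibration cells (or a seeded
#' uniform sample when there are more than `bg_max`), builds the feature
#' design, and fits the penalized Gibbs model.
#'
#' @param occ an `enm_occurrences` or an integer vector of presence cell
#'   indices into `stack`'s layer matrices.
#' @param stack calibration `enm_stack`.
#' @param spec a [feature_spec()] (or compact class string like `"lqp"`).
#' @param rm regularization multiplier.
#' @param bg_max background cap (cells beyond this are subsampled).
#' @param seed integer seed controlling background subsampling.
#' @param ... passed to [fit_gibbs()].
#' @return an `enm_model`.
#' @export
enm_maxent <- function(occ, stack, spec = "lq", rm = 1, bg_max = 10000,
                       seed = 1, ...) {
  if (!inherits(spec, "feature_spec")) spec <- feature_spec(spec)
  sv <- stack_values(stack)
  if (inherits(occ, "enm_occurrences")) {
    ev <- extract_values(stack, occ)
    cells <- attr(ev, "cells")
  } else cells <- as.integer(occ)
  cells <- unique(cells)
  pres_vals <- vapply(stack$layers, function(g) g$values[cells],
                      numeric(length(cells)))
  if (!is.matrix(pres_vals))
    pres_vals <- matrix(pres_vals, nrow = length(cells),
                        dimnames = list(NULL, stack$names))
  colnames(pres_vals) <- stack$names
  bg_vals <- sv$values
  if (nrow(bg_vals) > bg_max) {
    keep <- with_seed(seed, sample.int(nrow(bg_vals), bg_max))
    bg_vals <- bg_vals[keep, , drop = FALSE]
  }
  fb <- build_features(rbind(pres_vals, bg_vals), spec, stack$ranges)
  pres <- fb$design[seq_len(nrow(pres_vals)), , drop = FALSE]
  bg <- fb$design[-seq_len(nrow(pres_vals)), , drop = FALSE]
  fit_gibbs(pres, bg, rm, fb$meta, stack$ranges[stack$names, , drop = FALSE],
            spec, ...)
}

#' Predict a fitted model onto an environmental stack
#'
#' @param model an `enm_model`.
#' @param stack an `enm_stack` holding (at least) the model's variables.
#' @param output `"raw"` (Gibbs probability, sums to 1 over the calibration
#'   cells), `"logistic"` or `"cloglog"` (bounded monotone transforms using
#'   the model entropy).
#' @param mode extrapolation regime: `"free"` (features computed from
#'   unbounded rescaled values), `"clamp"` (each variable clipped to its
#'   calibration range first) or `"none"` (as clamp, but cells with any
#'   variable outside its calibration range are set to exactly 0).
#' @return an `enm_grid` aligned with `stack`.
#' @export
predict_enm <- function(model, stack,
                        output = c("logistic", "cloglog", "raw"),
                        mode = c("free", "clamp", "none")) {
  output <- match.arg(output)
  mode <- match.arg(mode)
  vars <- rownames(model$ranges)
  missing <- setdiff(vars, stack$names)
  if (length(missing))
    stop(sprintf("stack lacks model variable(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  sv <- stack_values(stack)
  vals <- sv$values[, vars, drop = FALSE]
  z <- rescale_env(vals, model$ranges)
  oob <- rowSums(z < 0 | z > 1) > 0
  if (mode != "free") z <- pmin(pmax(z, 0), 1)
  eta <- drop(expand_features(z, model$meta) %*% model$beta)
  raw <- exp(eta - model$logZ)
  out <- switch(output,
    raw = raw,
    logistic = {
      er <- exp(model$entropy) * raw
      er / (1 + er)
    },
    cloglog = 1 - exp(-exp(model$entropy) * raw))
  if (mode == "none") out[oob] <- 0
  vm <- matrix(NA_real_, nrow = nrow(stack$mask), ncol = ncol(stack$mask))
  vm[sv$cells] <- out
  enm_grid(vm, xll = stack$xll, yll = stack$yll, cellsize = stack$cellsize)
}

#' Bootstrap replicate fits
#'
#' Refits the model on with-replacement resamples (of the original size) of
#' the occurrence records; each resample is deduplicated to one presence per
#' cell before fitting, mirroring the per-cell presence convention.
#'
#' @param occ an `enm_occurrences`.
#' @param stack calibration `enm_stack`.
#' @param spec,rm model settings, as in [enm_maxent()].
#' @param n_reps number of replicates.
#' @param seed integer seed; replicate `i` uses a deterministic offset.
#' @param ... passed to [enm_maxent()].
#' @return list of `enm_model`, length `n_reps`.
#' @export
fit_replicates <- function(occ, stack, spec = "lq", rm = 1, n_reps = 10,
                           seed = 1, ...) {
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  ev <- extract_values(stack, occ)
  cells <- attr(ev, "cells")
  lapply(seq_len(n_reps), function(i) {
    res <- with_seed(derive_seed(seed, paste0("replicate_", i)),
                     sample(cells, length(cells), replace = TRUE))
    tryCatch(enm_maxent(res, stack, spec = spec, rm = rm, seed = seed, ...),
             error = function(e)
               stop(sprintf("replicate %d: %s", i, conditionMessage(e)),
                    call. = FALSE))
  })
}

#' Serialize a fitted model to JSON
#' @param model an `enm_model`.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  obj <- list(meta = model$meta,
              beta = as.numeric(model$beta),
              beta_names = names(model$beta),
              ranges = list(vars = rownames(model$ranges),
                            min = model$ranges[, "min"],
                            max = model$ranges[, "max"]),
              spec = list(classes = model$spec$classes,
                          threshold_knots = model$spec$threshold_knots,
                          hinge_knots = model$spec$hinge_knots),
              rm = model$rm, n_presences = model$n_presences,
              logZ = model$logZ, entropy = model$entropy)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model serialized by [write_model()]
#' @param path JSON path.
#' @export
read_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- as.numeric(o$beta)
  names(beta) <- o$beta_names
  ranges <- cbind(min = as.numeric(o$ranges$min),
                  max = as.numeric(o$ranges$max))
  rownames(ranges) <- o$ranges$vars
  meta <- as.data.frame(o$meta, stringsAsFactors = FALSE)
  # row-wise JSON omits all-NA fields; restore the full metadata schema
  if (is.null(meta$var2)) meta$var2 <- NA_character_
  if (is.null(meta$dir)) meta$dir <- NA_character_
  if (is.null(meta$knot)) meta$knot <- NA_real_
  meta$knot <- as.numeric(meta$knot)
  structure(list(meta = meta, beta = beta, ranges = ranges,
                 spec = feature_spec(o$spec$classes, o$spec$threshold_knots,
                                     o$spec$hinge_knots),
                 rm = o$rm, n_presences = o$n_presences,
                 logZ = o$logZ, entropy = o$entropy),
            class = "enm_model")
}
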