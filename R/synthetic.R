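# Virtual-species simulator: spatially autocorrelated environmental layers,
# a known true suitability surface, suitability-proportional presence
# sampling, and a complete on-disk project layout, so every pipeline stage
# is testable without external data.

#' Virtual-species configuration
#'
#' Defaults define the package's reference study conditions: a 64 x 64 grid,
#' 3 environmental layers smoothed with a Gaussian radius of 5 cells and
#' rescaled to [0, 1], a unimodal true niche (optimum at 0.5 on each
#' variable, logit `-27 + sum(40 x - 40 x^2)`, giving a landscape prevalence
#' of roughly 0.2-0.3 as is typical of virtual-species studies), 200
#' presences split 50/50 into train/test, 20 independent records, and
#' transfer scenarios `current` (identical to M) and `future` (all layers
#' shifted by +0.25, inducing strict extrapolation).
#'
#' @param nrow,ncol grid dimensions.
#' @param n_layers number of environmental layers.
#' @param smoothness Gaussian blur radius in cells (0 = white noise).
#' @param intercept,coef_linear,coef_quad true-niche coefficients on the
#'   logit scale (`coef_*` recycled to `n_layers`).
#' @param n_presence number of presence cells (>= 10).
#' @param train_fraction fraction of presences used for training.
#' @param n_independent size of the independent evaluation sample.
#' @param g_offsets named numeric vector: additive layer shift per transfer
#'   scenario.
#' @param detection_noise fraction of presences relocated to uniformly
#'   random cells (observer error; 0 = none).
#' @param seed integer seed (mandatory for reproducibility).
#' @return an object of class `vs_config`.
#' @export
vs_config <- function(nrow = 64, ncol = 64, n_layers = 3, smoothness = 5,
                      intercept = -27, coef_linear = 40, coef_quad = -40,
                      n_presence = 200, train_fraction = 0.5,
                      n_independent = 20,
                      g_offsets = c(current = 0, future = 0.25),
                      detection_noise = 0, seed = 42) {
  if (n_presence < 10) stop("n_presence must be >= 10", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  if (is.null(seed)) stop("seed is mandatory", call. = FALSE)
  structure(list(nrow = nrow, ncol = ncol, n_layers = n_layers,
                 smoothness = smoothness, intercept = intercept,
                 coef_linear = rep_len(coef_linear, n_layers),
                 coef_quad = rep_len(coef_quad, n_layers),
                 n_presence = as.integer(n_presence),
                 train_fraction = train_fraction,
                 n_independent = as.integer(n_independent),
                 g_offsets = g_offsets,
                 detection_noise = detection_noise,
                 seed = as.integer(seed)),
            class = "vs_config")
}

gaussian_blur <- function(m, radius) {
  if (radius <= 0) return(m)
  half <- max(1L, ceiling(3 * radius))
  k <- exp(-0.5 * ((-half:half) / radius)^2)
  k <- k / sum(k)
  reflect_idx <- function(i, n) {
    j <- (i - 1) %% (2 * n)
    ifelse(j < n, j + 1, 2 * n - j)
  }
  conv1 <- function(x) {
    n <- length(x)
    p <- x[reflect_idx((1 - half):(n + half), n)]
    as.numeric(stats::filter(p, k, sides = 2)[(half + 1):(half + n)])
  }
  m <- apply(m, 2, conv1)
  t(apply(t(m), 2, conv1))
}

#' Generate spatially autocorrelated environmental layers
#'
#' Each layer is seeded white noise smoothed by a Gaussian kernel of the
#' configured radius (reflective padding) and rescaled to [0, 1].
#'
#' @param config a [vs_config()].
#' @return an `enm_stack` with layers `env_1 ... env_k`, cell size 1,
#'   origin (0, 0).
#' @export
generate_env <- function(config) {
  grids <- lapply(seq_len(config$n_layers), function(i) {
    m <- with_seed(derive_seed(config$seed, paste0("layer_", i)),
                   matrix(stats::rnorm(config$nrow * config$ncol),
                          nrow = config$nrow))
    m <- gaussian_blur(m, config$smoothness)
    m <- (m - min(m)) / (max(m) - min(m))
    enm_grid(m)
  })
  names(grids) <- paste0("env_", seq_len(config$n_layers))
  enm_stack(grids)
}

#' True suitability surface of the virtual species
#'
#' Logistic of a linear-plus-quadratic function of the environmental
#' layers: `plogis(b0 + sum_i (a_i x_i + c_i x_i^2))`, strictly inside
#' (0, 1).
#'
#' @param stack an `enm_stack` from [generate_env()].
#' @param config the matching [vs_config()].
#' @return an `enm_grid` of true suitabilities.
#' @export
true_suitability <- function(stack, config) {
  if (length(config$coef_linear) != length(stack$layers))
    stop("coefficient vector length does not match layer count", call. = FALSE)
  eta <- config$intercept
  for (i in seq_along(stack$layers)) {
    x <- stack$layers[[i]]$values
    eta <- eta + config$coef_linear[i] * x + config$coef_quad[i] * x^2
  }
  enm_grid(stats::plogis(eta), xll = stack$xll, yll = stack$yll,
           cellsize = stack$cellsize)
}

#' Sample occurrence sets from a suitability surface
#'
#' Presence cells are drawn without replacement with probability
#' proportional to suitability; record coordinates are the cell centers.
#' The joint sample is split into train/test at `train_fraction`; the
#' independent sample is drawn separately from the cells not already used.
#'
#' @param suitability an `enm_grid` (e.g. [true_suitability()]).
#' @param config a [vs_config()].
#' @return list of `enm_occurrences`: `joint`, `train`, `test`,
#'   `independent`.
#' @export
sample_occurrences <- function(suitability, config) {
  s <- suitability$values
  cells <- which(!suitability$mask & s > 0)
  if (config$n_presence + config$n_independent > length(cells))
    stop("requested more presences than available cells", call. = FALSE)
  if (sum(s[cells]) <= 0) stop("suitability sums to zero", call. = FALSE)
  draw <- with_seed(derive_seed(config$seed, "presences"), {
    joint <- sample(cells, config$n_presence, prob = s[cells])
    if (config$detection_noise > 0) {
      nflip <- round(config$detection_noise * length(joint))
      if (nflip > 0)
        joint[seq_len(nflip)] <- sample(cells, nflip)
    }
    rest <- setdiff(cells, joint)
    ind <- sample(rest, config$n_independent, prob = s[rest])
    ntr <- round(config$train_fraction * length(joint))
    tr_idx <- sample(seq_along(joint), ntr)
    list(joint = joint, train = joint[tr_idx], test = joint[-tr_idx],
         independent = ind)
  })
  nr <- nrow(s)
  mk <- function(cells, role) {
    rows <- ((cells - 1L) %% nr) + 1L
    cols <- ((cells - 1L) %/% nr) + 1L
    xy <- cell_centers(suitability, rows, cols)
    enm_occurrences("virtual_species", xy[, 1], xy[, 2], role)
  }
  list(joint = mk(draw$joint, "joint"), train = mk(draw$train, "train"),
       test = mk(draw$test, "test"),
       independent = mk(draw$independent, "independent"))
}

#' Write a complete simulated project to disk
#'
#' Generates the environmental stack, true suitability, occurrence samples
#' and the full project layout (occurrence CSVs, `M_variables/Set_1/`,
#' `G_variables/Set_1/<scenario>/` as additively shifted copies of the M
#' layers, and `true_suitability.asc` for reference).
#'
#' @param root project directory to create.
#' @param config a [vs_config()].
#' @return the validated `enm_layout` of the new project.
#' @export
enm_simulate <- function(root, config = vs_config()) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  stack <- generate_env(config)
  suit <- true_suitability(stack, config)
  occ <- sample_occurrences(suit, config)
  write_occurrences(occ$joint, file.path(root, "sp_joint.csv"))
  write_occurrences(occ$train, file.path(root, "sp_train.csv"))
  write_occurrences(occ$test, file.path(root, "sp_test.csv"))
  write_occurrences(occ$independent, file.path(root, "sp_ind.csv"))
  write_grid(suit, file.path(root, "true_suitability.asc"))
  write_stack(stack, file.path(root, "M_variables", "Set_1"))
  for (sc in names(config$g_offsets)) {
    shifted <- lapply(stack$layers, function(g) {
      g$values <- g$values + config$g_offsets[[sc]]
      g$values[g$mask] <- NA_real_
      g
    })
    names(shifted) <- stack$names
    write_stack(enm_stack(shifted),
                file.path(root, "G_variables", "Set_1", sc))
  }
  validate_layout(project_layout(root), need_independent = TRUE)
}
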