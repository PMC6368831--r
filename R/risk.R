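#' Mobility-oriented parity (MOP) extrapolation surface
#'
#' For every unmasked cell of the transfer stack (G), computes the mean
#' Euclidean environmental distance (raw variable units by default) to its
#' nearest `percent`% of calibration (M) conditions, and converts distances
#' to a similarity in [0, 1] by dividing by the maximum distance over
#' non-strict G cells. Cells with any variable outside the full M range are
#' strict extrapolation and receive similarity exactly 0.
#'
#' @param m_values matrix cells x variables of calibration conditions.
#' @param g_stack transfer `enm_stack` with the same variables.
#' @param percent reference percentage of nearest M conditions (default 5).
#' @param m_subsample cap on M rows used for distances (seeded uniform
#'   sample); the strict-extrapolation ranges always use the full M set.
#' @param seed integer seed for the subsample.
#' @param standardize z-score variables by M mean/sd before distances.
#' @return object of class `mop_result`: `similarity` (`enm_grid` in
#'   [0, 1]), `strict_mask` (0/1 `enm_grid`), `percent`, `distance`
#'   (`enm_grid` of raw mean distances).
#' @export
mop <- function(m_values, g_stack, percent = 5, m_subsample = 10000,
                seed = 1, standardize = FALSE) {
  if (!inherits(g_stack, "enm_stack")) stop("g_stack must be an enm_stack",
                                            call. = FALSE)
  m_values <- as.matrix(m_values)
  if (nrow(m_values) == 0) stop("empty calibration condition set",
                                call. = FALSE)
  if (is.null(colnames(m_values)) ||
      !setequal(colnames(m_values), g_stack$names))
    stop("M and G variable names differ", call. = FALSE)
  if (percent <= 0 || percent > 100)
    stop("percent must be in (0, 100]", call. = FALSE)
  m_values <- m_values[, g_stack$names, drop = FALSE]
  rng <- apply(m_values, 2, range)
  sv <- stack_values(g_stack)
  g <- sv$values
  strict <- rowSums(sweep(g, 2, rng[1, ], `<`) |
                    sweep(g, 2, rng[2, ], `>`)) > 0
  mm <- m_values
  if (nrow(mm) > m_subsample)
    mm <- mm[with_seed(seed, sample.int(nrow(mm), m_subsample)), ,
             drop = FALSE]
  if (standardize) {
    mu <- colMeans(mm); sdv <- apply(mm, 2, stats::sd)
    sdv[sdv == 0] <- 1
    mm <- sweep(sweep(mm, 2, mu), 2, sdv, `/`)
    g <- sweep(sweep(g, 2, mu), 2, sdv, `/`)
  }
  kn <- ceiling(percent / 100 * nrow(mm))
  d <- numeric(nrow(g))
  m2 <- rowSums(mm^2)
  block <- max(1L, as.integer(floor(2e6 / max(1, nrow(mm)))))
  for (start in seq(1, nrow(g), by = block)) {
    idx <- start:min(start + block - 1, nrow(g))
    gb <- g[idx, , drop = FALSE]
    # squared distances via the expansion |g - m|^2 = |g|^2 - 2 g.m + |m|^2
    d2 <- outer(rowSums(gb^2), m2, `+`) - 2 * gb %*% t(mm)
    d2[d2 < 0] <- 0
    d[idx] <- apply(d2, 1, function(r)
      mean(sqrt(sort.int(r, partial = kn)[seq_len(kn)])))
  }
  dmax <- if (all(strict)) NA_real_ else max(d[!strict])
  if (is.na(dmax)) {
    warning("all transfer cells are strict extrapolation; similarity is all zero",
            call. = FALSE)
    sim <- rep(0, length(d))
  } else if (dmax == 0) {
    sim <- rep(1, length(d))
  } else {
    sim <- 1 - d / dmax
  }
  sim[strict] <- 0
  to_grid <- function(x) {
    v <- matrix(NA_real_, nrow = nrow(g_stack$mask), ncol = ncol(g_stack$mask))
    v[sv$cells] <- x
    enm_grid(v, xll = g_stack$xll, yll = g_stack$yll,
             cellsize = g_stack$cellsize)
  }
  structure(list(similarity = to_grid(sim),
                 strict_mask = to_grid(as.numeric(strict)),
                 percent = percent, distance = to_grid(d)),
            class = "mop_result")
}

#' @export
print.mop_result <- function(x, ...) {
  s <- x$strict_mask$values[!x$strict_mask$mask]
  cat(sprintf("<mop_result> percent = %g, strict-extrapolation cells: %d/%d\n",
              x$percent, sum(s > 0), length(s)))
  invisible(x)
}

#' Batched MOP over all transfer scenarios
#'
#' Runs [mop()] for every (predictor set, scenario, percent) combination in
#' the project layout and writes the surfaces under
#' `MOP_results/<set>/<scenario>/` (`mop_<percent>.asc` and
#' `strict_<percent>.asc`). Per-scenario failures are logged and do not
#' abort the batch.
#'
#' @param layout an `enm_layout`.
#' @param percents numeric vector of reference percentages.
#' @param m_subsample,seed,standardize passed to [mop()].
#' @return data.frame batch log (set, scenario, percent, status, message).
#' @export
enm_mop_batch <- function(layout, percents = 5, m_subsample = 10000,
                          seed = 1, standardize = FALSE) {
  rows <- list()
  for (set in layout$sets) {
    scs <- layout$scenarios[[set]]
    if (length(scs) == 0) next
    mstack <- read_stack(file.path(layout$root, "M_variables", set))
    m_values <- stack_values(mstack)$values
    for (sc in scs) for (p in percents) {
      res <- tryCatch({
        gstack <- read_stack(file.path(layout$root, "G_variables", set, sc))
        r <- mop(m_values, gstack, percent = p, m_subsample = m_subsample,
                 seed = derive_seed(seed, paste(set, sc, p)),
                 standardize = standardize)
        dir <- file.path(layout$root, "MOP_results", set, sc)
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        write_grid(r$similarity, file.path(dir, sprintf("mop_%g.asc", p)))
        write_grid(r$strict_mask, file.path(dir, sprintf("strict_%g.asc", p)))
        "ok"
      }, error = function(e) conditionMessage(e))
      rows[[length(rows) + 1]] <- data.frame(
        set = set, scenario = sc, percent = p,
        status = if (identical(res, "ok")) "ok" else "failed",
        message = if (identical(res, "ok")) "" else res,
        stringsAsFactors = FALSE)
    }
  }
  log <- if (length(rows)) do.call(rbind, rows)
         else data.frame(set = character(), scenario = character(),
                         percent = numeric(), status = character(),
                         message = character())
  utils::write.csv(log, file.path(layout$root, "MOP_results_log.csv"),
                   row.names = FALSE)
  log
}

#' Multivariate environmental similarity surface (MESS)
#'
#' Classic percentile-based novelty surface: for each variable the
#' similarity is derived from the fraction f of M conditions below the G
#' value (negative where the value lies outside the M range); the MESS value
#' of a cell is the minimum over variables, and the most dissimilar variable
#' is the argmin (lowest index on ties).
#'
#' @param m_values matrix cells x variables of calibration conditions.
#' @param g_stack transfer `enm_stack` with the same variables.
#' @return object of class `mess_result`: `mess` (`enm_grid`),
#'   `most_dissimilar` (`enm_grid` of 1-based variable indices).
#' @export
mess <- function(m_values, g_stack) {
  m_values <- as.matrix(m_values)
  if (is.null(colnames(m_values)) ||
      !setequal(colnames(m_values), g_stack$names))
    stop("M and G variable names differ", call. = FALSE)
  m_values <- m_values[, g_stack$names, drop = FALSE]
  sv <- stack_values(g_stack)
  g <- sv$values
  nM <- nrow(m_values)
  S <- matrix(NA_real_, nrow = nrow(g), ncol = ncol(g))
  for (j in seq_len(ncol(g))) {
    mv <- sort(m_values[, j])
    minv <- mv[1]; maxv <- mv[nM]
    span <- maxv - minv
    f <- 100 * findInterval(g[, j], mv, left.open = TRUE) / nM
    s <- numeric(nrow(g))
    below <- f == 0
    above <- f == 100
    mid_lo <- f > 0 & f <= 50
    mid_hi <- f > 50 & f < 100
    if (span > 0) {
      s[below] <- 100 * (g[below, j] - minv) / span
      s[above] <- 100 * (maxv - g[above, j]) / span
    } else {
      # constant variable in M: any deviation is infinitely novel
      s[below] <- ifelse(g[below, j] == minv, 100, -1e9)
      s[above] <- ifelse(g[above, j] == maxv, 100, -1e9)
    }
    s[mid_lo] <- 2 * f[mid_lo]
    s[mid_hi] <- 2 * (100 - f[mid_hi])
    S[, j] <- s
  }
  mins <- apply(S, 1, min)
  am <- apply(S, 1, which.min)
  to_grid <- function(x) {
    v <- matrix(NA_real_, nrow = nrow(g_stack$mask), ncol = ncol(g_stack$mask))
    v[sv$cells] <- x
    enm_grid(v, xll = g_stack$xll, yll = g_stack$yll,
             cellsize = g_stack$cellsize)
  }
  structure(list(mess = to_grid(mins), most_dissimilar = to_grid(am)),
            class = "mess_result")
}

#' @export
print.mess_result <- function(x, ...) {
  v <- x$mess$values[!x$mess$mask]
  cat(sprintf("<mess_result> %d cells, %d novel (MESS < 0), min = %.2f\n",
              length(v), sum(v < 0), min(v)))
  invisible(x)
}
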