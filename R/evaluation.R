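#' Partial ROC significance test
#'
#' ROC analysis restricted to high sensitivity (>= 1 - E/100). Thresholds
#' are up to 1,000 evenly spaced quantiles of the prediction surface; for
#' each threshold the sensitivity is the fraction of (bootstrap-resampled)
#' test suitabilities at or above it and the proportional area is the
#' fraction of unmasked cells at or above it. The AUC ratio is the
#' trapezoidal area of sensitivity-vs-area divided by the area of the
#' identity line over the same area range; significance is the direct count
#' of bootstrap AUC ratios <= 1.
#'
#' @param prediction an `enm_grid` (or numeric vector of prediction values).
#' @param test_suitabilities prediction values at the test occurrences.
#' @param E omission threshold percentage (sensitivity floor 1 - E/100).
#' @param iterations bootstrap iterations.
#' @param boot_fraction fraction of test points resampled (with replacement)
#'   per iteration.
#' @param seed integer seed.
#' @param n_thresholds cap on the threshold count.
#' @return object of class `proc_result`: `mean_auc_ratio`, `p_value`,
#'   `iterations`, `boot_fraction`, `E`, `n_undefined`, `auc_ratios`.
#' @export
partial_roc <- function(prediction, test_suitabilities, E = 5,
                        iterations = 500, boot_fraction = 0.5, seed = 1,
                        n_thresholds = 1000) {
  v <- if (inherits(prediction, "enm_grid"))
    prediction$values[!prediction$mask] else as.numeric(prediction)
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2)
    stop("prediction needs at least 2 distinct unmasked values", call. = FALSE)
  ts <- as.numeric(test_suitabilities)
  if (length(ts) < 2) stop("need at least 2 test values", call. = FALSE)
  thr <- unique(stats::quantile(v, probs = seq(0, 1,
                  length.out = min(n_thresholds, length(v))), names = FALSE,
                  type = 7))
  sv <- sort(v)
  area <- (length(sv) - findInterval(thr, sv, left.open = TRUE)) / length(sv)
  smin <- 1 - E / 100
  m <- max(1L, as.integer(round(boot_fraction * length(ts))))
  ratios <- with_seed(derive_seed(seed, "partial_roc"), {
    vapply(seq_len(iterations), function(i) {
      bs <- sort(ts[sample.int(length(ts), m, replace = TRUE)])
      sens <- (m - findInterval(thr, bs, left.open = TRUE)) / m
      keep <- sens >= smin
      if (sum(keep) < 2) return(NA_real_)
      a <- area[keep]; s <- sens[keep]
      o <- order(a)
      a <- a[o]; s <- s[o]
      model_area <- sum(diff(a) * (s[-1] + s[-length(s)]) / 2)
      null_area <- (max(a)^2 - min(a)^2) / 2
      if (null_area <= 0) return(NA_real_)
      model_area / null_area
    }, numeric(1))
  })
  n_undef <- sum(is.na(ratios))
  # an undefined ratio cannot support significance: count it as <= 1
  p <- (sum(ratios <= 1, na.rm = TRUE) + n_undef) / iterations
  structure(list(mean_auc_ratio = mean(ratios, na.rm = TRUE),
                 p_value = p, iterations = iterations,
                 boot_fraction = boot_fraction, E = E,
                 n_undefined = n_undef, auc_ratios = ratios),
            class = "proc_result")
}

#' @export
print.proc_result <- function(x, ...) {
  cat(sprintf("<proc_result> mean AUC ratio %.3f, p = %.4f (%d iters, %g%% bootstrap, E = %g%%)\n",
              x$mean_auc_ratio, x$p_value, x$iterations,
              100 * x$boot_fraction, x$E))
  invisible(x)
}

#' Omission rate at threshold E
#'
#' The suitability threshold is the nearest-rank E-th percentile of the
#' training suitabilities (rank `ceil(E/100 * n)`, rank 0 mapped to the
#' minimum); the omission rate is the fraction of test suitabilities
#' strictly below it (ties at the threshold count as predicted).
#'
#' @param train_suitabilities suitabilities of the training occurrences.
#' @param test_suitabilities suitabilities of the test occurrences.
#' @param E allowed omission percentage, `0 <= E < 100`.
#' @return object of class `omission_result`: `E`, `threshold`,
#'   `omission_rate`.
#' @export
omission_rate <- function(train_suitabilities, test_suitabilities, E = 5) {
  tr <- as.numeric(train_suitabilities)
  te <- as.numeric(test_suitabilities)
  if (length(tr) == 0 || length(te) == 0)
    stop("suitability vectors must be nonempty", call. = FALSE)
  if (E < 0 || E >= 100) stop("E must be in [0, 100)", call. = FALSE)
  r <- ceiling(E / 100 * length(tr))
  thr <- if (r == 0) min(tr) else sort(tr)[r]
  structure(list(E = E, threshold = thr,
                 omission_rate = mean(te < thr)),
            class = "omission_result")
}

#' AICc of a single candidate model
#'
#' Uses the raw (Gibbs) prediction of the full-occurrence model: the
#' log-likelihood is the sum of log raw probabilities at the (deduplicated)
#' occurrence cells, after defensively renormalizing the raw surface over
#' its unmasked cells. AICc is undefined (NA) when `n - k - 1 <= 0`.
#'
#' @param raw_prediction an `enm_grid` of raw output.
#' @param occurrence_cells integer linear cell indices of the occurrences.
#' @param k parameter count (nonzero coefficients).
#' @return list: `k`, `n`, `log_likelihood`, `aicc` (NA when undefined).
#' @export
aicc <- function(raw_prediction, occurrence_cells, k) {
  stopifnot(inherits(raw_prediction, "enm_grid"))
  cells <- unique(as.integer(occurrence_cells))
  if (any(raw_prediction$mask[cells]))
    stop("occurrence on a masked cell", call. = FALSE)
  vals <- raw_prediction$values
  total <- sum(vals[!raw_prediction$mask])
  p <- vals[cells] / total
  n <- length(cells)
  ll <- sum(log(pmax(p, .Machine$double.xmin)))
  a <- if (n - k - 1 > 0) 2 * k - 2 * ll + 2 * k * (k + 1) / (n - k - 1)
       else NA_real_
  list(k = as.integer(k), n = n, log_likelihood = ll, aicc = a)
}

#' Delta AICc and Akaike weights
#'
#' @param aiccs numeric vector of AICc values (NAs allowed; they get NA
#'   delta/weight and are excluded from the weight normalization).
#' @return list with `delta` and `weight`, aligned with the input.
#' @export
delta_and_weights <- function(aiccs) {
  a <- as.numeric(aiccs)
  if (all(is.na(a))) stop("no defined AICc values", call. = FALSE)
  delta <- a - min(a, na.rm = TRUE)
  rel <- exp(-delta / 2)
  weight <- rel / sum(rel, na.rm = TRUE)
  list(delta = delta, weight = weight)
}

#' Hierarchical three-stage model selection
#'
#' Filters candidates by (1) partial-ROC significance (`p_value < alpha`),
#' (2) omission rate at E (`omission_rate <= E/100`) and (3) complexity:
#' delta AICc recomputed relative to the minimum AICc *within the
#' significant, low-omission set* (never the global minimum), keeping
#' `delta <= delta_max`. If no significant model meets the omission
#' criterion, the significant models with minimal omission rate are carried
#' forward and flagged as a fallback.
#'
#' @param records data.frame with columns `candidate_id`, `p_value`,
#'   `omission_rate`, `aicc` (NA = undefined).
#' @param alpha significance level.
#' @param E omission percentage.
#' @param delta_max delta-AICc ceiling.
#' @return object of class `selection_result`: `selected` (candidate ids),
#'   `flags` (per-candidate logicals per stage plus the recomputed
#'   `delta_selected`), `tallies`, `fallback`, `status`.
#' @export
select_best <- function(records, alpha = 0.05, E = 5, delta_max = 2) {
  need <- c("candidate_id", "p_value", "omission_rate", "aicc")
  if (!all(need %in% names(records)))
    stop(sprintf("records must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  if (nrow(records) == 0) stop("records is empty", call. = FALSE)
  s1 <- !is.na(records$p_value) & records$p_value < alpha
  s2 <- s1 & !is.na(records$omission_rate) & records$omission_rate <= E / 100
  fallback <- FALSE
  if (!any(s2) && any(s1)) {
    fallback <- TRUE
    om <- records$omission_rate
    om[!s1] <- NA
    s2 <- s1 & !is.na(om) & om == min(om, na.rm = TRUE)
  }
  delta_sel <- rep(NA_real_, nrow(records))
  s3 <- rep(FALSE, nrow(records))
  pool <- s2 & !is.na(records$aicc)
  if (any(pool)) {
    ref <- min(records$aicc[pool])
    delta_sel[pool] <- records$aicc[pool] - ref
    s3 <- pool & delta_sel <= delta_max
    s3[is.na(s3)] <- FALSE
  }
  status <- if (!any(s1)) "none_significant"
            else if (!any(s3)) "none_selected" else "ok"
  structure(list(
    selected = records$candidate_id[s3],
    flags = data.frame(candidate_id = records$candidate_id,
                       significant = s1, low_omission = s2, selected = s3,
                       delta_selected = delta_sel,
                       stringsAsFactors = FALSE),
    tallies = c(candidates = nrow(records), significant = sum(s1),
                low_omission = sum(s2), selected = sum(s3)),
    fallback = fallback, status = status),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  t <- x$tallies
  cat(sprintf("<selection_result> %d candidates -> %d significant -> %d low-omission%s -> %d selected (%s)\n",
              t["candidates"], t["significant"], t["low_omission"],
              if (x$fallback) " [fallback]" else "", t["selected"], x$status))
  invisible(x)
}

#' Evaluate all candidate models and select the best
#'
#' Completes calibration: for every candidate written by [enm_calibrate()],
#' computes partial-ROC significance and omission rate at E from the
#' training model (logistic output, test occurrences) and AICc from the
#' full model's raw output at the deduplicated joint occurrence cells, then
#' applies the three-stage selection. Writes `calibration_results.csv`
#' (delta/weights over the whole candidate table, relative to the global
#' minimum), `selected_models.csv`, `selection_summary.txt` and the
#' omission-vs-AICc diagnostic figure to the project root.
#'
#' @param layout an `enm_layout` with a populated `Candidate_models/` tree.
#' @param E,alpha,delta_max selection parameters.
#' @param iterations,boot_fraction partial-ROC parameters.
#' @param seed integer seed (partial-ROC bootstrap).
#' @return list with `results` (the full evaluation table) and `selection`
#'   (a `selection_result`), invisibly.
#' @export
enm_evaluate <- function(layout, E = 5, alpha = 0.05, delta_max = 2,
                         iterations = 500, boot_fraction = 0.5, seed = 1) {
  cm <- file.path(layout$root, "Candidate_models")
  logf <- file.path(cm, "candidate_log.csv")
  if (!file.exists(logf))
    stop("no candidate models found; run enm_calibrate() first", call. = FALSE)
  batch <- utils::read.csv(logf, stringsAsFactors = FALSE)
  ids <- batch$candidate_id[batch$status == "ok"]
  occ_train <- read_occurrences(layout$occ_files["train"], "train")
  occ_test <- read_occurrences(layout$occ_files["test"], "test")
  occ_joint <- read_occurrences(layout$occ_files["joint"], "joint")
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    dir <- file.path(cm, id)
    train_pred <- read_grid(file.path(dir, "train_logistic.asc"))
    tr_suit <- extract_values(train_pred,
                              enm_occurrences(occ_train$species,
                                              occ_train$records$longitude,
                                              occ_train$records$latitude,
                                              "train"))
    te_suit <- extract_values(train_pred,
                              enm_occurrences(occ_test$species,
                                              occ_test$records$longitude,
                                              occ_test$records$latitude,
                                              "test"))
    pr <- partial_roc(train_pred, te_suit[, 1], E = E,
                      iterations = iterations, boot_fraction = boot_fraction,
                      seed = derive_seed(seed, id))
    om <- omission_rate(tr_suit[, 1], te_suit[, 1], E = E)
    full_raw <- read_grid(file.path(dir, "full_raw.asc"))
    jm <- extract_values(full_raw,
                         enm_occurrences(occ_joint$species,
                                         occ_joint$records$longitude,
                                         occ_joint$records$latitude, "joint"))
    model_full <- read_model(file.path(dir, "model_full.json"))
    ai <- aicc(full_raw, attr(jm, "cells"), count_parameters(model_full))
    rows[[i]] <- data.frame(
      candidate_id = id, mean_auc_ratio = pr$mean_auc_ratio,
      p_value = pr$p_value, omission_rate = om$omission_rate,
      aicc = ai$aicc, k = ai$k, n = ai$n, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  if (any(!is.na(results$aicc))) {
    dw <- delta_and_weights(results$aicc)
    results$delta_aicc <- dw$delta
    results$weight_aicc <- dw$weight
  } else {
    results$delta_aicc <- NA_real_
    results$weight_aicc <- NA_real_
  }
  sel <- select_best(results, alpha = alpha, E = E, delta_max = delta_max)
  utils::write.csv(results, file.path(layout$root, "calibration_results.csv"),
                   row.names = FALSE)
  utils::write.csv(results[results$candidate_id %in% sel$selected, ],
                   file.path(layout$root, "selected_models.csv"),
                   row.names = FALSE)
  writeLines(c(
    sprintf("Candidate models evaluated: %d", sel$tallies["candidates"]),
    sprintf("Statistically significant (p < %g): %d", alpha,
            sel$tallies["significant"]),
    sprintf("Meeting omission-rate criterion (<= %g%%): %d%s", E,
            sel$tallies["low_omission"],
            if (sel$fallback) " [fallback: minimum-omission significant models]"
            else ""),
    sprintf("Selected (delta AICc <= %g within that set): %d", delta_max,
            sel$tallies["selected"]),
    sprintf("Status: %s", sel$status),
    if (length(sel$selected)) c("Selected models:",
                                paste(" ", sel$selected)) else character()),
    file.path(layout$root, "selection_summary.txt"))
  try(plot_calibration(results, sel,
                       file.path(layout$root, "calibration_figure.png")),
      silent = TRUE)
  invisible(list(results = results, selection = sel))
}

#' Omission-vs-AICc diagnostic figure
#'
#' Scatter of omission rate against AICc for all candidates, highlighting
#' non-significant and selected models.
#'
#' @param results evaluation table from [enm_evaluate()].
#' @param selection matching `selection_result`.
#' @param path output PNG path (NULL plots to the active device).
#' @export
plot_calibration <- function(results, selection, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 700, res = 110)
    on.exit(grDevices::dev.off())
  }
  ok <- !is.na(results$aicc)
  nonsig <- !selection$flags$significant
  selfl <- selection$flags$selected
  graphics::plot(results$aicc[ok], results$omission_rate[ok],
                 pch = 16, col = "grey60",
                 xlab = "AICc", ylab = sprintf("Omission rate at E"),
                 main = "Candidate model performance")
  if (any(nonsig & ok))
    graphics::points(results$aicc[nonsig & ok],
                     results$omission_rate[nonsig & ok],
                     pch = 16, col = "orange2")
  if (any(selfl & ok))
    graphics::points(results$aicc[selfl & ok],
                     results$omission_rate[selfl & ok],
                     pch = 17, col = "red", cex = 1.3)
  graphics::legend("topright", pch = c(16, 16, 17),
                   col = c("grey60", "orange2", "red"),
                   legend = c("all candidates", "non-significant", "selected"),
                   bty = "n")
  invisible(path)
}
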