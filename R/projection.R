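#' Cell-wise median consolidation of replicate grids
#'
#' @param grids list of aligned `enm_grid` objects.
#' @return an `enm_grid`; each cell is the median over replicates (mean of
#'   the two middle values for even counts), with the union of the masks.
#' @export
consolidate <- function(grids) {
  if (length(grids) == 0) stop("need at least one grid", call. = FALSE)
  ref <- grids[[1]]
  for (g in grids)
    if (!grid_compatible(ref, g))
      stop("replicate grids are not aligned", call. = FALSE)
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  arr <- array(unlist(lapply(grids, function(g) {
    v <- g$values; v[g$mask] <- NA_real_; v
  })), dim = c(nr, nc, length(grids)))
  med <- apply(arr, c(1, 2), function(x)
    if (anyNA(x)) NA_real_ else stats::median(x))
  enm_grid(med, xll = ref$xll, yll = ref$yll, cellsize = ref$cellsize)
}

#' Build final models and transfer them to every scenario
#'
#' Refits each selected parameterization on the complete occurrence set with
#' bootstrap replicates, consolidates replicates by cell-wise median, and
#' predicts the calibration area plus every transfer scenario under every
#' requested extrapolation mode and output type. Results are written under
#' `Final_Models/<candidate_id>/` as
#' `<scenario>_<mode>_<output>.asc` (scenario `calibration` for the M area),
#' with per-replicate models serialized alongside.
#'
#' @param layout an `enm_layout`.
#' @param specs data.frame with columns `candidate_id`, `set_id`, `rm`, `fc`
#'   (e.g. selected rows of [enumerate_candidates()]).
#' @param n_reps bootstrap replicates per model.
#' @param outputs subset of `c("logistic", "cloglog", "raw")`.
#' @param modes subset of `c("free", "clamp", "none")`.
#' @param threshold_knots,hinge_knots,bg_max engine settings (must match
#'   calibration for comparability).
#' @param seed integer seed.
#' @param consensus also write the cell-wise median across all selected
#'   parameterizations (`Final_Models/consensus/`), when more than one.
#' @return invisible list of per-model output directories.
#' @export
enm_final <- function(layout, specs, n_reps = 10, outputs = "logistic",
                      modes = c("free", "clamp", "none"),
                      threshold_knots = 25, hinge_knots = 25, bg_max = 10000,
                      seed = 1, consensus = TRUE) {
  validate_layout(layout)
  outputs <- match.arg(outputs, c("logistic", "cloglog", "raw"),
                       several.ok = TRUE)
  modes <- match.arg(modes, c("free", "clamp", "none"), several.ok = TRUE)
  occ <- read_occurrences(layout$occ_files["joint"], "joint")
  out_root <- file.path(layout$root, "Final_Models")
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  done <- list()
  consensus_stacks <- list()  # scenario_mode_output -> list of grids
  for (i in seq_len(nrow(specs))) {
    id <- specs$candidate_id[i]
    set <- specs$set_id[i]
    mstack <- read_stack(file.path(layout$root, "M_variables", set))
    spec <- feature_spec(specs$fc[i], threshold_knots, hinge_knots)
    reps <- fit_replicates(occ, mstack, spec = spec, rm = specs$rm[i],
                           n_reps = n_reps,
                           seed = derive_seed(seed, paste0("final_", id)),
                           bg_max = bg_max)
    dir <- file.path(out_root, id)
    dir.create(dir, showWarnings = FALSE)
    for (r in seq_along(reps))
      write_model(reps[[r]], file.path(dir, sprintf("replicate_%02d.json", r)))
    scen_stacks <- c(list(calibration = mstack),
                     stats::setNames(lapply(layout$scenarios[[set]],
                       function(sc) read_stack(
                         file.path(layout$root, "G_variables", set, sc))),
                       layout$scenarios[[set]]))
    for (sc in names(scen_stacks)) {
      gstack <- scen_stacks[[sc]]
      missing <- setdiff(mstack$names, gstack$names)
      if (length(missing))
        stop(sprintf("scenario '%s' lacks layer(s): %s", sc,
                     paste(missing, collapse = ", ")), call. = FALSE)
      for (mode in modes) for (out in outputs) {
        grids <- lapply(reps, predict_enm, stack = gstack,
                        output = out, mode = mode)
        cons <- consolidate(grids)
        write_grid(cons, file.path(dir,
                   sprintf("%s_%s_%s.asc", sc, mode, out)))
        key <- sprintf("%s_%s_%s", sc, mode, out)
        consensus_stacks[[key]] <- c(consensus_stacks[[key]], list(cons))
      }
    }
    done[[id]] <- dir
    run_log(layout$root, sprintf("final model %s done (%d replicates)", id,
                                 n_reps))
  }
  if (consensus && nrow(specs) > 1) {
    cdir <- file.path(out_root, "consensus")
    dir.create(cdir, showWarnings = FALSE)
    for (key in names(consensus_stacks))
      write_grid(consolidate(consensus_stacks[[key]]),
                 file.path(cdir, paste0(key, ".asc")))
    done[["consensus"]] <- cdir
  }
  invisible(done)
}

#' Evaluate final models with independent occurrence data
#'
#' For each final model (and the consensus, when present), computes
#' partial-ROC significance and the omission rate at E on the consolidated
#' calibration-area prediction, using the independent occurrences as test
#' points and the complete (joint) occurrence set for the omission
#' threshold. Writes `final_evaluation.csv` to the project root.
#'
#' @param layout an `enm_layout` with `sp_ind.csv` present.
#' @param E omission percentage.
#' @param iterations,boot_fraction partial-ROC parameters.
#' @param seed integer seed.
#' @param mode,output which consolidated grid to evaluate.
#' @return data.frame: candidate_id, mean_auc_ratio, p_value, omission_rate,
#'   significant, low_omission. Returns a zero-row frame with a message when
#'   the independent set is absent.
#' @export
enm_feval <- function(layout, E = 5, iterations = 500, boot_fraction = 0.5,
                      seed = 1, mode = "free", output = "logistic") {
  empty <- data.frame(candidate_id = character(), mean_auc_ratio = numeric(),
                      p_value = numeric(), omission_rate = numeric(),
                      significant = logical(), low_omission = logical(),
                      stringsAsFactors = FALSE)
  if (!file.exists(layout$occ_files["independent"])) {
    message("no independent occurrence data (sp_ind.csv); skipping final evaluation")
    return(invisible(empty))
  }
  occ_ind <- read_occurrences(layout$occ_files["independent"], "independent")
  occ_joint <- read_occurrences(layout$occ_files["joint"], "joint")
  fm <- file.path(layout$root, "Final_Models")
  dirs <- list.dirs(fm, recursive = FALSE)
  if (length(dirs) == 0)
    stop("no final models found; run enm_final() first", call. = FALSE)
  rows <- list()
  for (d in dirs) {
    id <- basename(d)
    gridfile <- file.path(d, sprintf("calibration_%s_%s.asc", mode, output))
    if (!file.exists(gridfile)) next
    pred <- read_grid(gridfile)
    ind_suit <- extract_values(pred, occ_ind)
    joint_suit <- extract_values(pred, occ_joint)
    pr <- partial_roc(pred, ind_suit[, 1], E = E, iterations = iterations,
                      boot_fraction = boot_fraction,
                      seed = derive_seed(seed, paste0("feval_", id)))
    om <- omission_rate(joint_suit[, 1], ind_suit[, 1], E = E)
    rows[[id]] <- data.frame(
      candidate_id = id, mean_auc_ratio = pr$mean_auc_ratio,
      p_value = pr$p_value, omission_rate = om$omission_rate,
      significant = pr$p_value < 0.05,
      low_omission = om$omission_rate <= E / 100,
      stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(res) <- NULL
  utils::write.csv(res, file.path(layout$root, "final_evaluation.csv"),
                   row.names = FALSE)
  res
}
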