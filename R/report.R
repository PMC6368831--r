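# Run configuration (YAML) and the run report.

#' Default run configuration
#'
#' Aggregates every tunable of the pipeline with its default: the
#' 17-value regularization grid, the 29-combination feature catalog, E = 5,
#' alpha = 0.05, delta AICc ceiling 2, 500 partial-ROC iterations at 50%
#' bootstrap, 10 final-model replicates with logistic output under the three
#' extrapolation modes, MOP at 5%, and the run seed. The `fc` field, when
#' set, lists explicit feature-class combinations and overrides the named
#' catalog.
#'
#' @param root project root directory.
#' @return a named list of class `run_config`.
#' @export
default_run_config <- function(root = ".") {
  structure(list(
    root = root, rm_grid = default_rm_grid(), fc_catalog = "paper29",
    fc = NULL,
    E = 5, alpha = 0.05, delta_max = 2,
    proc_iterations = 500, proc_boot_fraction = 0.5,
    n_reps = 10, outputs = "logistic",
    modes = c("free", "clamp", "none"),
    mop_percents = 5, threshold_knots = 25, hinge_knots = 25,
    bg_max = 10000, seed = 1), class = "run_config")
}

#' Write a run configuration as YAML
#' @param config a `run_config` list.
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' Unknown keys are rejected; missing keys take their defaults; every value
#' is type- and range-checked before any computation starts.
#'
#' @param path YAML path.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  def <- unclass(default_run_config())
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  cfg <- utils::modifyList(def, raw)
  check <- function(ok, msg) if (!ok) stop(paste("config:", msg), call. = FALSE)
  cfg$rm_grid <- as.numeric(unlist(cfg$rm_grid))
  check(all(cfg$rm_grid > 0) && !is.unsorted(cfg$rm_grid, strictly = TRUE),
        "rm_grid must be strictly increasing positives")
  check(cfg$fc_catalog %in% c("paper29", "all31"),
        "fc_catalog must be 'paper29' or 'all31'")
  # [["fc"]] avoids partial matching against fc_catalog when fc is absent
  if (!is.null(cfg[["fc"]])) {
    cfg[["fc"]] <- as.character(unlist(cfg[["fc"]]))
    check(all(grepl("^[lqpth]+$", cfg[["fc"]])) &&
            !anyDuplicated(cfg[["fc"]]),
          "fc must be distinct combinations of l, q, p, t, h")
  }
  check(cfg$E >= 0 && cfg$E < 100, "E must be in [0, 100)")
  check(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)")
  check(cfg$delta_max >= 0, "delta_max must be >= 0")
  check(cfg$proc_iterations >= 1, "proc_iterations must be >= 1")
  check(cfg$proc_boot_fraction > 0 && cfg$proc_boot_fraction <= 1,
        "proc_boot_fraction must be in (0, 1]")
  check(cfg$n_reps >= 1, "n_reps must be >= 1")
  check(all(cfg$outputs %in% c("raw", "logistic", "cloglog")),
        "outputs must be raw/logistic/cloglog")
  check(all(cfg$modes %in% c("free", "clamp", "none")),
        "modes must be free/clamp/none")
  check(all(cfg$mop_percents > 0 & cfg$mop_percents <= 100),
        "mop_percents must be in (0, 100]")
  check(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be one integer")
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline from a configuration
#'
#' Calibrate, evaluate/select, build final models with transfers, evaluate
#' with independent data when present, and compute MOP surfaces — all from
#' one validated configuration, with a serialized copy of the configuration
#' and a run report written into the project root.
#'
#' @param config a `run_config` (see [read_run_config()]).
#' @return invisible list with the evaluation results, the selection, the
#'   final-evaluation table and the MOP batch log.
#' @export
enm_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  layout <- project_layout(config$root)
  write_run_config(config, file.path(config$root, "config_used.yml"))
  fc <- if (!is.null(config[["fc"]])) config[["fc"]]
        else fc_catalog(config$fc_catalog)
  enm_calibrate(layout, rm_grid = config$rm_grid, fc = fc,
                threshold_knots = config$threshold_knots,
                hinge_knots = config$hinge_knots, bg_max = config$bg_max,
                seed = config$seed)
  ev <- enm_evaluate(layout, E = config$E, alpha = config$alpha,
                     delta_max = config$delta_max,
                     iterations = config$proc_iterations,
                     boot_fraction = config$proc_boot_fraction,
                     seed = config$seed)
  cand <- enumerate_candidates(config$rm_grid, fc, layout$sets)
  specs <- cand[cand$candidate_id %in% ev$selection$selected, ]
  fe <- NULL
  if (nrow(specs) > 0) {
    enm_final(layout, specs, n_reps = config$n_reps,
              outputs = config$outputs, modes = config$modes,
              threshold_knots = config$threshold_knots,
              hinge_knots = config$hinge_knots, bg_max = config$bg_max,
              seed = config$seed)
    fe <- enm_feval(layout, E = config$E,
                    iterations = config$proc_iterations,
                    boot_fraction = config$proc_boot_fraction,
                    seed = config$seed)
  }
  mop_log <- enm_mop_batch(layout, percents = config$mop_percents,
                           seed = config$seed)
  enm_report(layout$root)
  invisible(list(evaluation = ev$results, selection = ev$selection,
                 final_evaluation = fe, mop_log = mop_log))
}

#' Render the run report
#'
#' Collects the outputs present in a project directory (selection tallies,
#' selected-model table, final evaluation, MOP log, the configuration used,
#' the diagnostic figure) into `report.md` and a minimal self-contained
#' `report.html`. Regeneration without recomputation is deterministic.
#'
#' @param root project root.
#' @return path of the markdown report, invisibly.
#' @export
enm_report <- function(root) {
  lines <- c("# Niche-model calibration run report", "")
  cfgf <- file.path(root, "config_used.yml")
  sumf <- file.path(root, "selection_summary.txt")
  self <- file.path(root, "selected_models.csv")
  fevf <- file.path(root, "final_evaluation.csv")
  mopf <- file.path(root, "MOP_results_log.csv")
  figf <- file.path(root, "calibration_figure.png")
  if (file.exists(sumf)) {
    lines <- c(lines, "## Model selection", "", "```",
               readLines(sumf), "```", "")
  } else lines <- c(lines, "## Model selection", "",
                    "_missing: selection has not been run_", "")
  md_table <- function(df) {
    if (nrow(df) == 0) return("_empty table_")
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    c(paste("|", paste(names(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|")))
  }
  if (file.exists(self)) {
    sel <- utils::read.csv(self, stringsAsFactors = FALSE)
    lines <- c(lines, "## Selected models", "", md_table(sel), "")
  }
  if (file.exists(figf))
    lines <- c(lines, "## Diagnostic figure", "",
               sprintf("![omission vs AICc](%s)", basename(figf)), "")
  if (file.exists(fevf)) {
    fe <- utils::read.csv(fevf, stringsAsFactors = FALSE)
    lines <- c(lines, "## Final-model evaluation (independent data)", "",
               md_table(fe), "")
  }
  if (file.exists(mopf)) {
    ml <- utils::read.csv(mopf, stringsAsFactors = FALSE)
    lines <- c(lines, "## MOP analyses", "", md_table(ml), "")
  }
  if (file.exists(cfgf))
    lines <- c(lines, "## Configuration", "", "```yaml",
               readLines(cfgf), "```", "")
  mdpath <- file.path(root, "report.md")
  writeLines(lines, mdpath)
  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
            "<title>nichecal run report</title>",
            "<style>body{font-family:sans-serif;max-width:60em;margin:2em auto}pre{background:#f6f6f6;padding:1em}</style>",
            "</head><body><pre>", gsub("<", "&lt;", lines),
            "</pre></body></html>")
  writeLines(html, file.path(root, "report.html"))
  invisible(mdpath)
}
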