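#' Default regularization-multiplier grid
#'
#' The 17-value grid used for exhaustive calibration: 0.1 to 1.0 in steps of
#' 0.1, 2 to 6 in steps of 1, then 8 and 10.
#' @return strictly increasing numeric vector of length 17.
#' @export
default_rm_grid <- function() c(seq(0.1, 1, by = 0.1), 2:6, 8, 10)

#' Feature-class catalogs
#'
#' `"paper29"` is the default 29-combination catalog: all nonempty subsets of
#' {l, q, p, t, h} except the two degenerate single-class sets {p} and {t}
#' (products and thresholds alone give pathological response shapes).
#' `"all31"` is every nonempty subset.
#'
#' @param name `"paper29"` or `"all31"`.
#' @return character vector of compact feature-class strings (e.g. `"lqp"`),
#'   ordered by subset size then by canonical class order l, q, p, t, h.
#' @export
fc_catalog <- function(name = c("paper29", "all31")) {
  name <- match.arg(name)
  letters5 <- c("l", "q", "p", "t", "h")
  subsets <- character()
  for (k in 1:5) {
    idx <- utils::combn(5, k)
    subsets <- c(subsets,
                 apply(idx, 2, function(i) paste(letters5[i], collapse = "")))
  }
  if (name == "paper29") subsets <- setdiff(subsets, c("p", "t"))
  subsets
}

#' Enumerate the candidate-model grid
#'
#' Builds the Cartesian product of predictor sets, regularization multipliers
#' and feature-class combinations, in (set, rm, fc) lexicographic order, with
#' the canonical candidate id `M_<rm>_F_<fc>_<set>`.
#'
#' @param rm_grid numeric vector of positive regularization multipliers.
#' @param fc character vector of feature-class strings (see [fc_catalog()]).
#' @param sets character vector of predictor-set names.
#' @return data.frame with columns `candidate_id`, `set_id`, `rm`, `fc`.
#' @export
enumerate_candidates <- function(rm_grid = default_rm_grid(),
                                 fc = fc_catalog("paper29"),
                                 sets = "Set_1") {
  if (length(rm_grid) == 0 || length(fc) == 0 || length(sets) == 0)
    stop("rm_grid, fc and sets must all be nonempty", call. = FALSE)
  if (any(rm_grid <= 0)) stop("regularization multipliers must be > 0",
                              call. = FALSE)
  if (is.unsorted(rm_grid, strictly = TRUE))
    stop("rm_grid must be strictly increasing", call. = FALSE)
  if (anyDuplicated(fc)) stop("duplicate feature-class combinations",
                              call. = FALSE)
  if (anyDuplicated(sets)) stop("duplicate set ids", call. = FALSE)
  grid <- expand.grid(fc = fc, rm = rm_grid, set_id = sets,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$set_id, sets), grid$rm,
                     match(grid$fc, fc)), c("set_id", "rm", "fc")]
  rownames(grid) <- NULL
  grid$candidate_id <- sprintf("M_%s_F_%s_%s", format(grid$rm, trim = TRUE,
                                                      drop0trailing = TRUE),
                               grid$fc, grid$set_id)
  grid[, c("candidate_id", "set_id", "rm", "fc")]
}

#' Create all candidate models (full + training pairs)
#'
#' For every candidate on the grid, fits one model on the complete
#' occurrence set and one on the training occurrences only, and writes both
#' (model JSON plus calibration-area logistic and raw predictions) under
#' `Candidate_models/<candidate_id>/` in the project root. Per-candidate
#' failures are logged and do not abort the batch; results live on disk, not
#' in memory.
#'
#' @param layout an `enm_layout` (validated before any fitting).
#' @param rm_grid,fc,sets calibration grid components; `sets` defaults to
#'   every set found under `M_variables/`.
#' @param threshold_knots,hinge_knots knot counts for the feature basis.
#' @param bg_max background cell cap per fit.
#' @param seed integer run seed.
#' @return data.frame batch log (candidate_id, status, message), invisibly;
#'   also written as `Candidate_models/candidate_log.csv`.
#' @export
enm_calibrate <- function(layout, rm_grid = default_rm_grid(),
                          fc = fc_catalog("paper29"), sets = NULL,
                          threshold_knots = 25, hinge_knots = 25,
                          bg_max = 10000, seed = 1) {
  validate_layout(layout)
  if (is.null(sets)) sets <- layout$sets
  if (!all(sets %in% layout$sets))
    stop(sprintf("unknown predictor set(s): %s",
                 paste(setdiff(sets, layout$sets), collapse = ", ")),
         call. = FALSE)
  cand <- enumerate_candidates(rm_grid, fc, sets)
  occ_joint <- read_occurrences(layout$occ_files["joint"], "joint")
  occ_train <- read_occurrences(layout$occ_files["train"], "train")
  out_root <- file.path(layout$root, "Candidate_models")
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  stacks <- list()
  log <- data.frame(candidate_id = cand$candidate_id, status = "ok",
                    message = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cand))) {
    id <- cand$candidate_id[i]
    res <- tryCatch({
      set <- cand$set_id[i]
      if (is.null(stacks[[set]]))
        stacks[[set]] <- read_stack(file.path(layout$root, "M_variables", set))
      stack <- stacks[[set]]
      spec <- feature_spec(cand$fc[i], threshold_knots, hinge_knots)
      dir <- file.path(out_root, id)
      dir.create(dir, showWarnings = FALSE)
      for (which in c("full", "train")) {
        occ <- if (which == "full") occ_joint else occ_train
        m <- enm_maxent(occ, stack, spec = spec, rm = cand$rm[i],
                        bg_max = bg_max,
                        seed = derive_seed(seed, paste0("bg_", set)))
        write_model(m, file.path(dir, paste0("model_", which, ".json")))
        write_grid(predict_enm(m, stack, "logistic", "free"),
                   file.path(dir, paste0(which, "_logistic.asc")))
        write_grid(predict_enm(m, stack, "raw", "free"),
                   file.path(dir, paste0(which, "_raw.asc")))
      }
      "ok"
    }, error = function(e) conditionMessage(e))
    if (!identical(res, "ok")) {
      log$status[i] <- "failed"
      log$message[i] <- res
      run_log(layout$root, sprintf("candidate %s FAILED: %s", id, res))
    } else {
      run_log(layout$root, sprintf("candidate %s done", id))
    }
  }
  utils::write.csv(log, file.path(out_root, "candidate_log.csv"),
                   row.names = FALSE)
  invisible(log)
}
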