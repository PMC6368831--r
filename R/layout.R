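#' Describe a modelling project directory
#'
#' nichecal uses a one-directory-per-species layout: occurrence CSVs at the
#' root (`sp_joint.csv`, `sp_train.csv`, `sp_test.csv`, optional
#' `sp_ind.csv`), calibration-region predictor sets under
#' `M_variables/Set_<i>/`, and per-set transfer scenarios under
#' `G_variables/Set_<i>/<scenario>/`. All pipeline stages read from and write
#' to this tree so no large object is held wholesale in memory.
#'
#' @param root project root directory.
#' @return an object of class `enm_layout` listing the occurrence files,
#'   predictor sets and transfer scenarios found.
#' @export
project_layout <- function(root) {
  if (!dir.exists(root))
    stop(sprintf("project root '%s' does not exist", root), call. = FALSE)
  mdir <- file.path(root, "M_variables")
  sets <- if (dir.exists(mdir))
    sort(basename(list.dirs(mdir, recursive = FALSE))) else character()
  gdir <- file.path(root, "G_variables")
  scenarios <- list()
  for (s in sets) {
    gs <- file.path(gdir, s)
    scenarios[[s]] <- if (dir.exists(gs))
      sort(basename(list.dirs(gs, recursive = FALSE))) else character()
  }
  structure(list(
    root = root,
    occ_files = c(joint = file.path(root, "sp_joint.csv"),
                  train = file.path(root, "sp_train.csv"),
                  test = file.path(root, "sp_test.csv"),
                  independent = file.path(root, "sp_ind.csv")),
    sets = sets, scenarios = scenarios),
    class = "enm_layout")
}

#' @export
print.enm_layout <- function(x, ...) {
  cat(sprintf("<enm_layout> %s\n  sets: %s\n", x$root,
              paste(x$sets, collapse = ", ")))
  for (s in names(x$scenarios))
    if (length(x$scenarios[[s]]))
      cat(sprintf("  G/%s: %s\n", s, paste(x$scenarios[[s]], collapse = ", ")))
  invisible(x)
}

#' Validate a project layout before a run
#'
#' Checks that the occurrence files needed for calibration exist, that every
#' predictor set directory holds at least one layer, and that each transfer
#' scenario contains exactly the layer names of its calibration set.
#'
#' @param layout an `enm_layout`.
#' @param need_independent require `sp_ind.csv` too.
#' @return `layout`, invisibly; stops with an informative message otherwise.
#' @export
validate_layout <- function(layout, need_independent = FALSE) {
  stopifnot(inherits(layout, "enm_layout"))
  need <- c("joint", "train", "test")
  if (need_independent) need <- c(need, "independent")
  missing <- need[!file.exists(layout$occ_files[need])]
  if (length(missing))
    stop(sprintf("missing occurrence file(s): %s",
                 paste(basename(layout$occ_files[missing]), collapse = ", ")),
         call. = FALSE)
  if (length(layout$sets) == 0)
    stop("no predictor sets under M_variables/", call. = FALSE)
  for (s in layout$sets) {
    mfiles <- layer_names_in(file.path(layout$root, "M_variables", s))
    if (length(mfiles) == 0)
      stop(sprintf("predictor set '%s' has no .asc layers", s), call. = FALSE)
    for (sc in layout$scenarios[[s]]) {
      gfiles <- layer_names_in(file.path(layout$root, "G_variables", s, sc))
      if (!setequal(mfiles, gfiles))
        stop(sprintf("scenario '%s' of set '%s' does not match M layer names (%s vs %s)",
                     sc, s, paste(gfiles, collapse = ","),
                     paste(mfiles, collapse = ",")), call. = FALSE)
    }
  }
  invisible(layout)
}

layer_names_in <- function(dir) {
  sort(tools::file_path_sans_ext(
    list.files(dir, pattern = "\\.asc$", ignore.case = TRUE)))
}

#' Scaffold an empty project tree
#'
#' Creates the starting directory structure (occurrence placeholders are not
#' written) plus a commented run-configuration YAML that documents every
#' tunable of the pipeline.
#'
#' @param root directory to create.
#' @param n_sets number of (empty) predictor-set directories.
#' @param scenarios character vector of transfer-scenario names to scaffold
#'   per set (empty for none).
#' @return the root path, invisibly.
#' @export
enm_init <- function(root, n_sets = 1, scenarios = character()) {
  for (i in seq_len(n_sets)) {
    dir.create(file.path(root, "M_variables", paste0("Set_", i)),
               recursive = TRUE, showWarnings = FALSE)
    for (sc in scenarios)
      dir.create(file.path(root, "G_variables", paste0("Set_", i), sc),
                 recursive = TRUE, showWarnings = FALSE)
  }
  write_run_config(default_run_config(root), file.path(root, "config.yml"))
  invisible(root)
}
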