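# Seed discipline: every random step consumes a seed derived from the run
# seed plus a stage label, so whole pipelines are reproducible and stages can
# be rerun in isolation.

#' Derive a stage-specific seed from a base seed
#'
#' Deterministic mixing of an integer base seed with a stage label; keeps
#' results independent across stages while fully reproducible from one seed.
#' @param seed integer base seed.
#' @param stage character label of the pipeline stage.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, stage) {
  h <- as.double(seed) %% 2147483647
  for (c in utf8ToInt(as.character(stage)))
    h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

run_log <- function(root, msg) {
  path <- file.path(root, "run.log")
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg),
      file = path, append = TRUE)
  invisible(path)
}
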