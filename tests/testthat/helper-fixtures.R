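# Shared fixtures, built in code. The simulated reference project is created
# once per test session and reused across files.

fixture_grid <- function(values = matrix(1:9, 3, 3, byrow = TRUE), ...) {
  enm_grid(values, ...)
}

# small two-layer aligned stack with a deterministic gradient
fixture_stack <- function(n = 8, masked_cell = NULL) {
  a <- matrix(seq(0, 1, length.out = n * n), n, n)
  b <- matrix(rep(seq(10, 20, length.out = n), each = n), n, n)
  if (!is.null(masked_cell)) a[masked_cell] <- NA
  enm_stack(list(env_a = enm_grid(a), env_b = enm_grid(b)))
}

# reference simulated project (default study conditions, seed 42)
default_project <- function() {
  root <- file.path(tempdir(), "nichecal_default_project")
  if (!file.exists(file.path(root, "sp_joint.csv")))
    enm_simulate(root, vs_config())
  project_layout(root)
}

# small, fast project for pipeline tests: coarser grid, fewer presences
small_project <- function(name = "nichecal_small_project", ...) {
  root <- file.path(tempdir(), name)
  cfg <- vs_config(nrow = 32, ncol = 32, n_presence = 80, n_independent = 15,
                   smoothness = 3, seed = 7, ...)
  if (!file.exists(file.path(root, "sp_joint.csv")))
    enm_simulate(root, cfg)
  project_layout(root)
}

# independent brute-force re-implementation of the three-stage selection rule
oracle_select <- function(records, alpha = 0.05, E = 5, delta_max = 2) {
  sig <- c()
  for (i in seq_len(nrow(records)))
    if (!is.na(records$p_value[i]) && records$p_value[i] < alpha)
      sig <- c(sig, i)
  low <- c()
  for (i in sig)
    if (!is.na(records$omission_rate[i]) &&
        records$omission_rate[i] <= E / 100)
      low <- c(low, i)
  if (length(low) == 0 && length(sig) > 0) {
    oms <- records$omission_rate[sig]
    if (any(!is.na(oms)))
      low <- sig[which(!is.na(oms) & oms == min(oms, na.rm = TRUE))]
  }
  pool <- low[!is.na(records$aicc[low])]
  if (length(pool) == 0) return(character())
  ref <- min(records$aicc[pool])
  sel <- c()
  for (i in pool)
    if (records$aicc[i] - ref <= delta_max) sel <- c(sel, i)
  records$candidate_id[sel]
}

random_record_table <- function(n = 12) {
  data.frame(
    candidate_id = sprintf("cand_%02d", seq_len(n)),
    p_value = round(stats::runif(n, 0, 0.2), 3),
    omission_rate = round(stats::runif(n, 0, 0.15), 3),
    aicc = ifelse(stats::runif(n) < 0.1, NA_real_,
                  round(stats::rnorm(n, 1000, 5), 2)),
    stringsAsFactors = FALSE)
}

# exhaustive pairwise-distance oracle for MOP
oracle_mop_distance <- function(m, g_row, percent) {
  d <- sqrt(colSums((t(m) - g_row)^2))
  k <- ceiling(percent / 100 * nrow(m))
  mean(sort(d)[seq_len(k)])
}

# direct per-variable MESS formula oracle
oracle_mess_cell <- function(m, g_row) {
  s <- sapply(seq_along(g_row), function(j) {
    mv <- m[, j]
    f <- 100 * sum(mv < g_row[j]) / length(mv)
    minv <- min(mv); maxv <- max(mv)
    if (f == 0) 100 * (g_row[j] - minv) / (maxv - minv)
    else if (f <= 50) 2 * f
    else if (f < 100) 2 * (100 - f)
    else 100 * (maxv - g_row[j]) / (maxv - minv)
  })
  list(mess = min(s), which = unname(which.min(s)))
}

lag1_autocor <- function(m) {
  stats::cor(as.vector(m[, -ncol(m)]), as.vector(m[, -1]))
}
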