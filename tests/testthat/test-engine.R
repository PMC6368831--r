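# Engine behavior is checked on the simulated landscape: normalization,
# penalty structure, output transforms, extrapolation regimes, replicates.

test_that("null data is shrunk to a near-uniform model", {
  layout <- default_project()
  stack <- read_stack(file.path(layout$root, "M_variables", "Set_1"))
  sv <- stack_values(stack)
  # presences drawn uniformly from background cells: no environmental
  # signal; a large sample keeps the score noise below the L1 threshold
  cells <- withr::with_seed(11, sample(sv$cells, 1200))
  m <- enm_maxent(cells, stack, spec = "lq", rm = 1)
  expect_true(all(abs(m$beta) <= 1e-3))
  raw <- predict_enm(m, stack, "raw", "free")
  rv <- raw$values[!raw$mask]
  expect_lt(max(abs(rv - 1 / length(rv))) / (1 / length(rv)), 0.05)
})

test_that("an overwhelming penalty zeroes every coefficient", {
  layout <- default_project()
  stack <- read_stack(file.path(layout$root, "M_variables", "Set_1"))
  occ <- read_occurrences(layout$occ_files["joint"], "joint")
  m <- enm_maxent(occ, stack, spec = "lqp", rm = 1e6)
  expect_identical(count_parameters(m), 0L)
  raw <- predict_enm(m, stack, "raw", "free")
  rv <- raw$values[!raw$mask]
  expect_equal(max(rv), min(rv), tolerance = 1e-12)
  # penalty monotonicity at the extremes
  m_small <- enm_maxent(occ, stack, spec = "lqp", rm = 0.1)
  expect_lte(count_parameters(m), count_parameters(m_small))
})

test_that("a monotone presence sample recovers a positive linear effect", {
  layout <- default_project()
  stack <- read_stack(file.path(layout$root, "M_variables", "Set_1"))
  sv <- stack_values(stack)
  # presences = cells with the highest env_1 values
  cells <- sv$cells[order(sv$values[, "env_1"], decreasing = TRUE)[1:100]]
  m <- enm_maxent(cells, stack, spec = "l", rm = 1)
  expect_gt(m$beta[["env_1"]], 0)
})

test_that("raw output is a normalized density and transforms preserve ranks", {
  layout <- default_project()
  stack <- read_stack(file.path(layout$root, "M_variables", "Set_1"))
  occ <- read_occurrences(layout$occ_files["joint"], "joint")
  m <- enm_maxent(occ, stack, spec = "lq", rm = 0.5)
  raw <- predict_enm(m, stack, "raw", "free")
  expect_equal(sum(raw$values[!raw$mask]), 1, tolerance = 1e-8)
  expect_gte(m$entropy, 0)
  logi <- predict_enm(m, stack, "logistic", "free")
  clog <- predict_enm(m, stack, "cloglog", "free")
  keep <- !raw$mask
  expect_true(all(logi$values[keep] >= 0 & logi$values[keep] <= 1))
  expect_true(all(clog$values[keep] >= 0 & clog$values[keep] <= 1))
  expect_equal(cor(raw$values[keep], logi$values[keep], method = "spearman"),
               1)
  expect_equal(cor(logi$values[keep], clog$values[keep], method = "spearman"),
               1)
})

test_that("count_parameters counts exact nonzeros", {
  layout <- default_project()
  stack <- read_stack(file.path(layout$root, "M_variables", "Set_1"))
  occ <- read_occurrences(layout$occ_files["joint"], "joint")
  m <- enm_maxent(occ, stack, spec = "lq", rm = 1)
  expect_lte(count_parameters(m), length(m$beta))
  m$beta[] <- c(0.5, 0, -0.2, 0, 0, 0)
  expect_identical(count_parameters(m), 2L)
  m$beta[] <- 0
  expect_identical(count_parameters(m), 0L)
})

test_that("extrapolation regimes agree on calibration data and differ off it", {
  layout <- default_project()
  stack <- read_stack(file.path(layout$root, "M_variables", "Set_1"))
  occ <- read_occurrences(layout$occ_files["joint"], "joint")
  m <- enm_maxent(occ, stack, spec = "lq", rm = 1)
  # G identical to M: the three modes coincide
  for (mode in c("clamp", "none")) {
    p0 <- predict_enm(m, stack, "logistic", "free")
    p1 <- predict_enm(m, stack, "logistic", mode)
    expect_equal(p0$values, p1$values)
  }
  # shift one layer beyond its calibration maximum in a corner of the grid
  shifted <- stack
  bump <- max(stack$ranges["env_1", "max"]) + 0.3
  shifted$layers$env_1$values[1, 1] <- bump
  pn <- predict_enm(m, shifted, "logistic", "none")
  expect_identical(pn$values[1, 1], 0)
  pc <- predict_enm(m, shifted, "logistic", "clamp")
  at_max <- stack
  at_max$layers$env_1$values[1, 1] <- stack$ranges["env_1", "max"]
  pb <- predict_enm(m, at_max, "logistic", "clamp")
  expect_equal(pc$values[1, 1], pb$values[1, 1])
  expect_error(predict_enm(m, enm_stack(list(zz = stack$layers$env_1))),
               "env_")
})

test_that("bootstrap replicates are seeded and reproducible", {
  layout <- small_project()
  stack <- read_stack(file.path(layout$root, "M_variables", "Set_1"))
  occ <- read_occurrences(layout$occ_files["joint"], "joint")
  r1 <- fit_replicates(occ, stack, spec = "lq", rm = 1, n_reps = 3, seed = 5)
  r2 <- fit_replicates(occ, stack, spec = "lq", rm = 1, n_reps = 3, seed = 5)
  expect_length(r1, 3)
  expect_equal(r1[[1]]$beta, r2[[1]]$beta)
  expect_equal(r1[[3]]$beta, r2[[3]]$beta)
  r3 <- fit_replicates(occ, stack, spec = "lq", rm = 1, n_reps = 2, seed = 6)
  expect_false(isTRUE(all.equal(r1[[1]]$beta, r3[[1]]$beta)))
})

test_that("model JSON serialization round-trips predictions", {
  layout <- small_project()
  stack <- read_stack(file.path(layout$root, "M_variables", "Set_1"))
  occ <- read_occurrences(layout$occ_files["joint"], "joint")
  m <- enm_maxent(occ, stack, spec = "lqt", rm = 1)
  p <- withr::local_tempfile(fileext = ".json")
  write_model(m, p)
  m2 <- read_model(p)
  g1 <- predict_enm(m, stack, "logistic", "free")
  g2 <- predict_enm(m2, stack, "logistic", "free")
  expect_equal(g1$values, g2$values)
  expect_equal(m2$entropy, m$entropy)
})

test_that("the engine recovers the virtual species' suitability ranking", {
  layout <- default_project()
  stack <- read_stack(file.path(layout$root, "M_variables", "Set_1"))
  occ <- read_occurrences(layout$occ_files["joint"], "joint")
  m <- enm_maxent(occ, stack, spec = "lq", rm = 1, bg_max = 2000, seed = 42)
  pred <- predict_enm(m, stack, "logistic", "free")
  truth <- read_grid(file.path(layout$root, "true_suitability.asc"))
  keep <- !pred$mask
  rho <- cor(pred$values[keep], truth$values[keep], method = "spearman")
  expect_gte(rho, 0.7)
})

test_that("degenerate fits raise errors", {
  layout <- small_project()
  stack <- read_stack(file.path(layout$root, "M_variables", "Set_1"))
  sv <- stack_values(stack)
  expect_error(enm_maxent(sv$cells[1], stack, spec = "l", rm = 1),
               "at least 2")
  occ <- read_occurrences(layout$occ_files["joint"], "joint")
  expect_error(enm_maxent(occ, stack, spec = "l", rm = -1), "positive")
})
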