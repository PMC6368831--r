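test_that("perfect discrimination yields p = 0 and ratios above 1", {
  set.seed(8)
  v <- runif(1500)
  ts <- rep(max(v), 10)
  pr <- partial_roc(v, ts, E = 5, iterations = 300, boot_fraction = 0.5,
                    seed = 2)
  expect_equal(pr$p_value, 0)
  expect_true(all(pr$auc_ratios > 1, na.rm = TRUE))
  expect_equal(pr$iterations, 300)
  expect_equal(pr$boot_fraction, 0.5)
  expect_equal(pr$E, 5)
})

test_that("partial ROC p-value is the exact direct count", {
  set.seed(9)
  v <- runif(2000)
  ts <- sample(v, 30)
  pr <- partial_roc(v, ts, E = 5, iterations = 400, seed = 4)
  expect_equal(pr$p_value,
               (sum(pr$auc_ratios <= 1, na.rm = TRUE) +
                  sum(is.na(pr$auc_ratios))) / 400)
  # determinism under the seed
  pr2 <- partial_roc(v, ts, E = 5, iterations = 400, seed = 4)
  expect_identical(pr$auc_ratios, pr2$auc_ratios)
  expect_error(partial_roc(rep(1, 50), ts), "distinct")
  expect_error(partial_roc(v, 0.5), "test values")
})

test_that("the null false-positive rate of the pROC test is controlled", {
  # uniform prediction, test points random cells; adequate test sample so
  # that the restricted region holds enough points for the direct count
  hits <- 0
  n_models <- 40
  for (s in seq_len(n_models)) {
    set.seed(s)
    v <- runif(3000)
    ts <- sample(v, 300)
    pr <- partial_roc(v, ts, E = 5, iterations = 200, seed = s + 1000)
    if (pr$p_value < 0.05) hits <- hits + 1
  }
  expect_lte(hits / n_models, 0.10)
})

test_that("omission thresholds use the nearest-rank percentile", {
  om <- omission_rate(c(0.3, 0.1, 0.2), c(0.3, 0.1, 0.2), E = 0)
  expect_equal(om$threshold, 0.1)
  expect_equal(om$omission_rate, 0)

  om2 <- omission_rate(seq(0.1, 1, by = 0.1), c(0.05, 0.5), E = 5)
  expect_equal(om2$threshold, 0.1)  # rank ceil(0.05 * 10) = 1
  expect_equal(om2$omission_rate, 0.5)

  # ties at the threshold are NOT omitted
  om3 <- omission_rate(c(0.2, 0.4, 0.6, 0.8), c(0.2, 0.1), E = 25)
  expect_equal(om3$threshold, 0.2)
  expect_equal(om3$omission_rate, 0.5)

  # monotone in E for fixed data
  set.seed(10)
  tr <- runif(40); te <- runif(25)
  rates <- sapply(0:20, function(E) omission_rate(tr, te, E)$omission_rate)
  expect_true(all(diff(rates) >= 0))
  expect_error(omission_rate(numeric(), te), "nonempty")
  expect_error(omission_rate(tr, te, E = 100), "E must")
})

test_that("AICc follows the closed form and its degeneracy guard", {
  # uniform raw over C cells, k = 0: AICc = 2 n ln C
  C <- 25; n <- 6
  g <- enm_grid(matrix(1 / C, 5, 5))
  a <- aicc(g, seq_len(n), k = 0)
  expect_equal(a$log_likelihood, -n * log(C))
  expect_equal(a$aicc, 2 * n * log(C))

  # hand-computed guard case: n - k - 1 = 0 -> undefined
  g4 <- enm_grid(matrix(c(0.4, 0.3, 0.2, 0.1), 2, 2))
  a4 <- aicc(g4, c(1, 2), k = 1)
  expect_equal(a4$log_likelihood, log(0.4) + log(0.3))
  expect_true(is.na(a4$aicc))
  expect_true(is.na(aicc(g4, c(1, 2), k = 2)$aicc))  # k = n

  # duplicated occurrence cells are collapsed
  a_dup <- aicc(g, c(1, 1, 2), k = 0)
  expect_equal(a_dup$n, 2)

  # masked occurrence cell is a hard error
  gm <- enm_grid(matrix(c(NA, 1, 1, 1), 2, 2))
  expect_error(aicc(gm, 1, k = 0), "masked")
})

test_that("delta AICc and Akaike weights have the standard arithmetic", {
  dw <- delta_and_weights(c(3346.46, 3385.65, 3358.27, 3348.13))
  expect_equal(round(dw$delta, 2), c(0, 39.19, 11.81, 1.67))
  expect_equal(sum(dw$weight), 1, tolerance = 1e-12)
  expect_equal(min(dw$delta), 0)

  dw1 <- delta_and_weights(100)
  expect_equal(dw1$delta, 0)
  expect_equal(dw1$weight, 1)

  dw2 <- delta_and_weights(c(10, 10))
  expect_equal(dw2$weight, c(0.5, 0.5))

  dwna <- delta_and_weights(c(100, NA, 102))
  expect_true(is.na(dwna$weight[2]))
  expect_equal(sum(dwna$weight, na.rm = TRUE), 1)
  expect_error(delta_and_weights(c(NA_real_, NA_real_)), "no defined")
})

test_that("three-stage selection matches a brute-force oracle", {
  set.seed(12)
  for (i in 1:60) {
    rec <- random_record_table(sample(4:16, 1))
    sel <- select_best(rec)
    expect_setequal(sel$selected, oracle_select(rec))
    # nesting: selected <= low-omission <= significant
    f <- sel$flags
    expect_true(all(!f$selected | f$low_omission))
    expect_true(all(!f$low_omission | f$significant))
  }
})

test_that("the delta reference is never a non-significant global minimum", {
  rec <- data.frame(
    candidate_id = c("good_a", "good_b", "bad_min"),
    p_value = c(0.01, 0.01, 0.50),       # bad_min not significant
    omission_rate = c(0.02, 0.03, 0.00),
    aicc = c(1000, 1001.5, 900),          # bad_min is the global minimum
    stringsAsFactors = FALSE)
  sel <- select_best(rec, alpha = 0.05, E = 5, delta_max = 2)
  # reference must be 1000 (min over significant & low omission), so both
  # good models are within delta 2 even though both are 100+ from the
  # global minimum
  expect_setequal(sel$selected, c("good_a", "good_b"))
  expect_equal(sel$flags$delta_selected[1], 0)
  expect_equal(sel$flags$delta_selected[2], 1.5)
  expect_true(is.na(sel$flags$delta_selected[3]))
})

test_that("selection handles fallback and empty outcomes explicitly", {
  rec <- data.frame(
    candidate_id = c("a", "b", "c"),
    p_value = c(0.01, 0.02, 0.03),
    omission_rate = c(0.30, 0.10, 0.10),  # none meets E = 5%
    aicc = c(500, 510, 505), stringsAsFactors = FALSE)
  sel <- select_best(rec)
  expect_true(sel$fallback)
  # fallback keeps the minimum-omission significant models, then delta <= 2
  expect_setequal(sel$selected, "c")
  expect_setequal(rec$candidate_id[sel$flags$low_omission], c("b", "c"))

  rec$p_value <- c(0.5, 0.6, 0.7)
  sel2 <- select_best(rec)
  expect_equal(sel2$status, "none_significant")
  expect_length(sel2$selected, 0)
  expect_false(sel2$fallback)
  expect_error(select_best(rec[0, ]), "empty")
})

test_that("candidate evaluation produces the full results table and files", {
  layout <- small_project()
  if (!file.exists(file.path(layout$root, "Candidate_models",
                             "candidate_log.csv")))
    enm_calibrate(layout, rm_grid = c(0.5, 1), fc = c("lq", "lqp"), seed = 2)
  ev <- enm_evaluate(layout, iterations = 100, seed = 2)
  expect_equal(nrow(ev$results), 4)
  expect_true(all(c("mean_auc_ratio", "p_value", "omission_rate", "aicc",
                    "delta_aicc", "weight_aicc", "k") %in% names(ev$results)))
  ok <- !is.na(ev$results$aicc)
  expect_equal(min(ev$results$delta_aicc[ok]), 0)
  expect_equal(sum(ev$results$weight_aicc[ok]), 1, tolerance = 1e-12)
  expect_true(file.exists(file.path(layout$root, "calibration_results.csv")))
  expect_true(file.exists(file.path(layout$root, "selected_models.csv")))
  expect_true(file.exists(file.path(layout$root, "selection_summary.txt")))
  # the virtual species' models should discriminate far better than chance
  expect_true(any(ev$results$mean_auc_ratio > 1))
})
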