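test_that("decide applies the strict < T rule", {
  expect_equal(decide(0.10, 0.25), "replica")
  expect_equal(decide(0.39, 0.25), "non-replica")
  expect_equal(decide(0.25, 0.25), "non-replica")  # boundary is non-replica
  expect_equal(decide(c(0, 0.24999, 0.25, 0.3), 0.25),
               c("replica", "replica", "non-replica", "non-replica"))
  expect_error(decide(-0.1, 0.25), regexp = "non-negative")
})

test_that("balanced accuracy: perfect, degenerate and NCCT-shaped cases", {
  ids <- sprintf("s%02d", 1:10)
  truth <- truth_tbl(ids, rep(c("replica", "non-replica"), each = 5))
  expect_equal(balanced_accuracy(truth, truth), 1)
  all_rep <- truth_tbl(ids, rep("replica", 10))
  expect_equal(balanced_accuracy(all_rep, truth), 0.5)
  # 45 replicas all found + 5 non-replicas all correct
  ids50 <- sprintf("s%02d", 1:50)
  truth50 <- truth_tbl(ids50, c(rep("replica", 45), rep("non-replica", 5)))
  expect_equal(balanced_accuracy(truth50, truth50), 1)
  expect_error(balanced_accuracy(truth, truth_tbl(ids, rep("replica", 10))),
               class = "replicheck_single_class")
  expect_error(balanced_accuracy(truth[1:5, ], truth),
               class = "replicheck_id_mismatch")
})

test_that("sweep: separable, inseparable, and exhaustive-cut oracle", {
  ids <- sprintf("s%02d", 1:10)
  truth <- truth_tbl(ids, rep(c("replica", "non-replica"), each = 5))
  sep <- tibble::tibble(id = ids, value = rep(c(0, 1), each = 5))
  sw <- sweep_thresholds(sep, truth)
  expect_equal(sw$optimal_balanced_accuracy, 1)
  flat <- tibble::tibble(id = ids, value = rep(0.4, 10))
  expect_equal(sweep_thresholds(flat, truth)$optimal_balanced_accuracy, 0.5)
  expect_error(sweep_thresholds(sep, truth, step = 0), regexp = "step")
  # seeded overlapping values vs midpoint-scan oracle
  for (seed in 1:10) {
    set.seed(seed)
    is_rep <- rep(c(TRUE, FALSE), each = 8)
    vals <- ifelse(is_rep, rbeta(16, 2, 5), rbeta(16, 5, 2))
    values <- tibble::tibble(id = sprintf("x%02d", 1:16), value = vals)
    tr <- truth_tbl(values$id,
                    ifelse(is_rep, "replica", "non-replica"))
    sw <- sweep_thresholds(values, tr, step = 0.01)
    oracle <- oracle_best_ba(vals, is_rep)
    expect_lte(sw$optimal_balanced_accuracy, oracle + 1e-12)
    # grid optimum within reach of the continuous optimum
    expect_gte(sw$optimal_balanced_accuracy, oracle - 0.5 / 16)
  }
})

test_that("sweep grid invariants and dominance hold on seeded studies", {
  for (seed in 1:5) {
    set.seed(seed * 5)
    n <- 20
    is_rep <- runif(n) < 0.5
    if (all(is_rep) || !any(is_rep)) is_rep[1:2] <- c(TRUE, FALSE)
    values <- tibble::tibble(id = sprintf("s%02d", 1:n), value = runif(n))
    tr <- truth_tbl(values$id, ifelse(is_rep, "replica", "non-replica"))
    sw <- sweep_thresholds(values, tr)
    g <- tidy(sw)
    expect_equal(g$balanced_accuracy,
                 (g$sensitivity + g$specificity) / 2)
    expect_true(all(g$sensitivity >= 0 & g$sensitivity <= 1))
    expect_true(all(g$specificity >= 0 & g$specificity <= 1))
    expect_true(all(sw$optimal_balanced_accuracy >= g$balanced_accuracy))
    expect_gte(sw$optimal_balanced_accuracy, 0.5)
    # smallest threshold on ties
    ties <- g$threshold[g$balanced_accuracy ==
                          sw$optimal_balanced_accuracy]
    expect_equal(sw$optimal_threshold, min(ties))
  }
})

test_that("absolute decision variables sweep a max-scaled grid", {
  ids <- sprintf("s%02d", 1:8)
  truth <- truth_tbl(ids, rep(c("replica", "non-replica"), each = 4))
  values <- tibble::tibble(id = ids, value = c(1, 2, 3, 4, 30, 35, 38, 40))
  sw <- sweep_thresholds(values, truth, decision_variable = "absolute")
  g <- tidy(sw)
  expect_equal(max(g$threshold), 40)
  expect_equal(g$threshold[2] - g$threshold[1], 0.01 * 40)
  expect_equal(sw$optimal_balanced_accuracy, 1)
})

test_that("label-flip symmetry preserves the optimal balanced accuracy", {
  for (seed in 1:5) {
    set.seed(seed * 13)
    n <- 24
    is_rep <- rep(c(TRUE, FALSE), each = 12)
    vals <- runif(n)
    values <- tibble::tibble(id = sprintf("s%02d", 1:n), value = vals)
    tr <- truth_tbl(values$id, ifelse(is_rep, "replica", "non-replica"))
    sw1 <- sweep_thresholds(values, tr)
    flipped <- tibble::tibble(id = values$id, value = 1 - vals)
    tr2 <- truth_tbl(values$id, ifelse(is_rep, "non-replica", "replica"))
    sw2 <- sweep_thresholds(flipped, tr2)
    expect_equal(sw1$optimal_balanced_accuracy,
                 sw2$optimal_balanced_accuracy, tolerance = 1e-9)
  }
})

test_that("margin threshold: printed boundary ratios and degenerate margin", {
  vals <- tibble::tibble(id = c("a", "b"), value = c(0.11, 0.39))
  tr <- truth_tbl(c("a", "b"), c("replica", "non-replica"))
  mt <- margin_threshold(vals, tr)
  expect_equal(as.numeric(mt), 0.25)
  expect_true(attr(mt, "separable"))
  vals2 <- tibble::tibble(id = letters[1:4], value = c(0.0, 0.2, 0.6, 0.8))
  tr2 <- truth_tbl(letters[1:4], rep(c("replica", "non-replica"), each = 2))
  expect_equal(as.numeric(margin_threshold(vals2, tr2)), 0.4)
  # overlapping classes: threshold still defined, flagged non-separable
  vals3 <- tibble::tibble(id = letters[1:4], value = c(0.5, 0.5, 0.5, 0.9))
  mt3 <- margin_threshold(vals3, tr2)
  expect_equal(as.numeric(mt3), 0.5)
  expect_false(attr(mt3, "separable"))
})

test_that("automation counts flags and is monotone in the threshold", {
  vals <- tibble::tibble(id = sprintf("s%02d", 1:10),
                         value = seq(0.05, 0.95, by = 0.1))
  dec <- apply_automation(vals, 0.45)
  expect_equal(attr(dec, "n_flagged"), 4L)
  expect_equal(sum(dec$decision == "replica"), 4L)
  empty <- apply_automation(tibble::tibble(id = character(),
                                           value = numeric()), 0.45)
  expect_equal(attr(empty, "n_flagged"), 0L)
  counts <- vapply(seq(0, 1, by = 0.05), function(th) {
    attr(apply_automation(vals, th), "n_flagged")
  }, integer(1))
  expect_true(all(diff(counts) >= 0L))
})

test_that("ground-truth reader applies the 3-4 rule and refuses silent majority", {
  dir <- withr::local_tempdir()
  agree <- file.path(dir, "agree.csv")
  readr::write_csv(tibble::tibble(
    synthetic_id = c("s1", "s2", "s3"),
    rater1_score = c(4, 3, 1), rater2_score = c(3, 4, 2)), agree)
  gt <- read_ground_truth(agree)
  expect_equal(gt$label, c("replica", "replica", "non-replica"))

  conflict <- file.path(dir, "conflict.csv")
  readr::write_csv(tibble::tibble(
    synthetic_id = c("s1", "s2"),
    rater1_score = c(4, 3), rater2_score = c(3, 2)), conflict)
  expect_error(read_ground_truth(conflict),
               class = "replicheck_unadjudicated")

  adjudicated <- file.path(dir, "adjudicated.csv")
  readr::write_csv(tibble::tibble(
    synthetic_id = c("s1", "s2"),
    rater1_score = c(4, 3), rater2_score = c(3, 2),
    adjudicated = c("replica", "non-replica")), adjudicated)
  gt2 <- read_ground_truth(adjudicated)
  expect_equal(gt2$label, c("replica", "non-replica"))

  direct <- file.path(dir, "direct.csv")
  readr::write_csv(tibble::tibble(synthetic_id = c("s1", "s2"),
                                  label = c("replica", "non-replica")),
                   direct)
  expect_equal(read_ground_truth(direct)$label, c("replica", "non-replica"))
})

test_that("sweep tidiers and autoplot expose the fit", {
  ids <- sprintf("s%02d", 1:10)
  truth <- truth_tbl(ids, rep(c("replica", "non-replica"), each = 5))
  sep <- tibble::tibble(id = ids,
                        value = c(runif(5, 0, 0.2), runif(5, 0.6, 1)))
  sw <- sweep_thresholds(sep, truth, measure = "rmse")
  expect_s3_class(tidy(sw), "tbl_df")
  gl <- glance(sw)
  expect_equal(gl$measure, "rmse")
  expect_equal(gl$optimal_balanced_accuracy, 1)
  expect_s3_class(autoplot(sw), "ggplot")
})
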