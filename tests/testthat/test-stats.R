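test_that("Spearman screen matches hand ranking and base R", {
  expect_equal(spearman_screen(1:6, c(2, 4, 6, 7, 9, 20))$rs, 1)
  expect_equal(spearman_screen(1:6, -(1:6)^3)$rs, -1)
  expect_equal(spearman_screen(c(1, 2, 3, 4), c(1, 3, 2, 4))$rs, 0.8)
  set.seed(16)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    x <- rnorm(n)
    y <- if (i %% 2) rnorm(n) else sample(round(rnorm(n), 1))  # with ties
    got <- spearman_screen(x, y)
    expect_equal(got$rs, cor(x, y, method = "spearman"))
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(spearman_screen(rep(1, 5), rnorm(5)), "constant")
  expect_error(spearman_screen(1:2, 1:2), "at least 3")
})

test_that("exact permutation p-value agrees with base R's exact test", {
  set.seed(17)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(6)                      # no ties
    got <- spearman_screen(x, y, exact = TRUE)
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("AUC equals the exhaustive pairwise oracle and pROC", {
  sep <- roc_auc(c(1, 2, 10, 11), c("n", "n", "p", "p"), "p")
  expect_equal(sep$auc, 1)
  expect_equal(roc_auc(c(1, 3, 2, 4), c("n", "n", "p", "p"), "p")$auc, 0.75)
  set.seed(18)
  for (i in 1:30) {
    n <- sample(6:120, 1)
    scores <- if (i %% 3) rnorm(n) else sample(1:8, n, replace = TRUE)
    labels <- sample(c("pos", "neg"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    got <- roc_auc(scores, labels, "pos")
    expect_equal(got$auc, brute_auc(scores, labels, "pos"))
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- pROC::auc(pROC::roc(labels, scores, levels = c("neg", "pos"),
                                 direction = "<", quiet = TRUE))
      expect_equal(got$auc, as.numeric(ref))
    }
    if (got$auc > 0 && got$auc < 1) expect_gt(got$se, 0)
    expect_lte(got$ci_high, 1); expect_gte(got$ci_low, 0)
    expect_lte(got$ci_low, got$auc); expect_gte(got$ci_high, got$auc)
  }
  expect_error(roc_auc(1:4, rep("p", 4), "p"), "non-empty")
})

test_that("Hanley-McNeil SE matches a frozen hand evaluation", {
  # negatives {1,2,3,4}, positives {0.5, 2.5, 3.5}: 5 of 12 pairs ordered,
  # AUC = 5/12; SE worked by hand through Q1 = A/(2-A), Q2 = 2A^2/(1+A)
  got <- roc_auc(c(1, 2, 3, 4, 0.5, 2.5, 3.5),
                 c("n", "n", "n", "n", "p", "p", "p"), "p")
  expect_equal(got$auc, 5 / 12)
  expect_equal(got$se, 0.2303276483, tolerance = 1e-8)
})

test_that("Youden search equals brute force and picks the stated cutoffs", {
  y <- youden_cutoff(c(1, 2, 3, 4), c("n", "n", "p", "p"), "p")
  expect_equal(y$J, 1)
  expect_equal(y$cutoff, 2.5)
  expect_equal(y$sensitivity, 1); expect_equal(y$specificity, 1)
  set.seed(19)
  for (i in 1:30) {
    n <- sample(8:100, 1)
    scores <- if (i %% 3) rnorm(n) else sample(1:6, n, replace = TRUE)
    labels <- sample(c("pos", "neg"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    got <- youden_cutoff(scores, labels, "pos")
    expect_equal(got$J,
                 brute_best_J(scores, labels, "pos", got$direction))
    # confusion metrics consistent with the stored 2x2 table
    expect_equal(got$sensitivity, got$tp / (got$tp + got$fn))
    expect_equal(got$specificity, got$tn / (got$tn + got$fp))
  }
})

test_that("direction flips so the reported orientation has AUC >= 0.5", {
  # positives score LOW here
  y <- youden_cutoff(c(10, 9, 1, 2), c("n", "n", "p", "p"), "p")
  expect_equal(y$direction, "less_equal")
  expect_equal(y$J, 1)
  expect_equal(y$sensitivity, 1)
})

test_that("AUC and Youden metrics are invariant under monotone transforms", {
  set.seed(20)
  scores <- rnorm(60); labels <- sample(c("p", "n"), 60, replace = TRUE)
  a1 <- roc_auc(scores, labels, "p"); y1 <- youden_cutoff(scores, labels, "p")
  for (tr in list(exp, function(x) x^3, function(x) 5 * x - 2)) {
    a2 <- roc_auc(tr(scores), labels, "p")
    y2 <- youden_cutoff(tr(scores), labels, "p")
    expect_equal(a2$auc, a1$auc)
    expect_equal(y2$J, y1$J)
    expect_equal(y2$sensitivity, y1$sensitivity)
    expect_equal(y2$specificity, y1$specificity)
  }
})

test_that("predictive values reconstruct from rates and class sizes", {
  cm <- confusion_from_rates(20 / 28, 30 / 42, 28, 42)
  expect_equal(cm$ppv, 0.625)                      # 20 / (20 + 12)
  expect_equal(cm$npv, 30 / 38)                    # 0.789
  expect_equal(cm$tp, 20); expect_equal(cm$tn, 30)
})

test_that("AND-rule combination multiplies rates as expected", {
  cmb <- combined_and_rule(0.714, 0.714, 0.810, 0.571)
  expect_equal(cmb$sensitivity, 0.714 * 0.810)
  expect_equal(cmb$specificity, 1 - (1 - 0.714) * (1 - 0.571))
  # combining with a perfect test changes nothing but specificity -> 1
  id <- combined_and_rule(0.8, 0.6, 1, 1)
  expect_equal(id$sensitivity, 0.8)
  expect_equal(id$specificity, 1)
  expect_error(combined_and_rule(1.2, 0.5, 0.5, 0.5), "\\[0, 1\\]")
  # AND rule bounds: sens below either input, spec above either input
  expect_lte(cmb$sensitivity, min(0.714, 0.810))
  expect_gte(cmb$specificity, max(0.714, 0.571))
})

test_that("volume independence: exact fits and the analytic 3-point oracle", {
  vol <- c(10, 20, 40, 80)
  vi <- suppressWarnings(volume_independence(2 * vol, vol))  # perfect fit
  expect_equal(vi$r, 1)
  expect_equal(vi$slope, 2)
  # normal-equation hand solution for x = (1,2,4), y = (1,2,3)
  vi3 <- volume_independence(c(1, 2, 3), c(1, 2, 4))
  expect_equal(vi3$slope, 9 / 14)
  expect_equal(vi3$intercept, 1 / 2)
  expect_equal(vi3$r_squared, 27 / 28)
  # independent feature stays near r = 0 at large n
  set.seed(22)
  vi0 <- volume_independence(rnorm(2000), runif(2000, 5, 80))
  expect_lt(abs(vi0$r), 0.06)
  expect_error(volume_independence(1:2, 1:2), "at least 3")
})
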