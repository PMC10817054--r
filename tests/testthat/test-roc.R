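# ROC/AUC construction, pair-enumeration equivalence, Youden cutpoints.

test_that("AUC equals the pair-enumeration oracle on the worked examples", {
  # pos = {1,2}, neg = {2,3}, low predicts positive: 4 pairs, one tie
  a <- roc_auc(c(1, 2, 2, 3), c(TRUE, TRUE, FALSE, FALSE), "low")
  expect_equal(a$auc, 0.875)
  # anti-perfect ordering: positives score above negatives, yet low
  # values are declared to predict positive
  expect_equal(roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE), "low")$auc, 0)
  # constant predictor: diagonal
  expect_equal(roc_auc(rep(2, 6), rep(c(TRUE, FALSE), 3), "low")$auc, 0.5)
  # identical distributions
  expect_equal(roc_auc(c(1, 2, 3, 1, 2, 3),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), "low")$auc,
               0.5)
})

test_that("AUC matches pair enumeration on random tied instances", {
  set.seed(2024)
  for (i in 1:300) {
    m <- sample(1:20, 1)
    n <- sample(1:20, 1)
    vals <- sample(0:8, m + n, replace = TRUE) # heavy ties, score-like
    labs <- c(rep(TRUE, m), rep(FALSE, n))
    dir <- sample(c("low", "high"), 1)
    expect_equal(roc_auc(vals, labs, dir)$auc, oracle_auc(vals, labs, dir))
  }
})

test_that("AUC symmetry and monotone invariance", {
  set.seed(5)
  vals <- rnorm(60)
  labs <- rep(c(TRUE, FALSE), 30)
  a_low <- roc_auc(vals, labs, "low")$auc
  a_high <- roc_auc(vals, labs, "high")$auc
  expect_equal(a_low + a_high, 1)
  expect_equal(roc_auc(-vals, labs, "high")$auc, a_low)
  expect_equal(roc_auc(exp(3 * vals), labs, "low")$auc, a_low)
})

test_that("AUC and DeLong variance agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:5) {
    vals <- round(rnorm(80, sd = 2)) + rep(c(0, 1.2), 40)
    labs <- rep(c(FALSE, TRUE), 40)
    mine <- roc_auc(vals, labs, "high")
    ref <- suppressMessages(pROC::roc(labs, vals, direction = "<"))
    expect_equal(mine$auc, as.numeric(pROC::auc(ref)))
    expect_equal(mine$variance, as.numeric(pROC::var(ref, method = "delong")))
  }
})

test_that("ROC curve is monotone and spans both degenerate corners", {
  set.seed(8)
  vals <- sample(0:6, 40, replace = TRUE)
  labs <- rep(c(TRUE, FALSE), 20)
  for (dir in c("low", "high")) {
    rc <- roc_curve(vals, labs, dir)
    expect_true(all(rc$sensitivity >= 0 & rc$sensitivity <= 1))
    expect_true(all(rc$specificity >= 0 & rc$specificity <= 1))
    expect_true(any(rc$sensitivity == 1 & rc$specificity == 0) ||
                any(rc$sensitivity == 0 & rc$specificity == 1))
    ord <- order(rc$sensitivity)
    expect_true(all(diff(rc$specificity[ord]) <= 1e-12))
  }
  expect_error(roc_curve(1:4, rep(TRUE, 4), "low"), "both classes")
})

test_that("Youden cutpoint matches an exhaustive sweep and its tie rules", {
  # separable example: criterion <=1 with perfect sensitivity/specificity
  cut <- youden_cutoff(roc_curve(c(0, 1, 1, 2, 2, 3),
                                 c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                                 "low"))
  expect_equal(cut$criterion, "<=1")
  expect_equal(cut$sensitivity, 100)
  expect_equal(cut$specificity, 100)
  expect_equal(cut$youden_j, 1)

  # constant predictor: no discrimination
  cut <- youden_cutoff(roc_curve(rep(3, 8), rep(c(TRUE, FALSE), 4), "low"))
  expect_equal(cut$youden_j, 0)

  # random sweeps: J must equal the maximum over all achievable thresholds
  set.seed(99)
  for (i in 1:50) {
    vals <- sample(0:8, 30, replace = TRUE)
    labs <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    if (!any(labs) || all(labs)) next
    dir <- sample(c("low", "high"), 1)
    rc <- roc_curve(vals, labs, dir)
    cut <- youden_cutoff(rc)
    expect_equal(cut$youden_j, max(rc$sensitivity + rc$specificity - 1))
    # tie rule: no equal-J point has higher sensitivity
    ties <- which(abs(rc$sensitivity + rc$specificity - 1 - cut$youden_j) < 1e-12)
    expect_gte(cut$sensitivity / 100, max(rc$sensitivity[ties]) - 1e-12)
  }
})

test_that("high-direction criteria render as strict inequalities", {
  cut <- youden_cutoff(roc_curve(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE),
                                 "high"))
  expect_equal(cut$criterion, ">2")
  expect_equal(cut$youden_j, 1)
})
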