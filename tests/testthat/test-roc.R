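test_that("Mann-Whitney AUC matches exhaustive pair counting", {
  expect_equal(
    auc_mann_whitney(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  # tie case worked by hand: 4 pairs, two concordant, two tied -> 3/4
  expect_equal(
    auc_mann_whitney(c(1, 2, 2, 2), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(auc_by_pairs(c(1, 2, 2, 2), c(0, 0, 1, 1)), 0.75)
  set.seed(21)
  for (k in 1:200) {
    n <- sample(4:12, 1)
    scores <- sample(1:5, n, replace = TRUE)  # heavy ties
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    expect_equal(auc_mann_whitney(scores, labels)$auc,
                 auc_by_pairs(scores, labels))
    # complement symmetry
    expect_equal(auc_mann_whitney(scores, labels, "positive_low")$auc,
                 1 - auc_by_pairs(scores, labels))
  }
  expect_error(auc_mann_whitney(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC equals the trapezoidal area under the empirical ROC curve", {
  set.seed(22)
  for (k in 1:100) {
    n <- sample(5:12, 1)
    scores <- round(rnorm(n), 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.4)
    pts <- roc_points(scores, labels)
    trap <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
    expect_equal(auc_mann_whitney(scores, labels)$auc, trap,
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (k in 1:20) {
    n <- sample(10:40, 1)
    scores <- rnorm(n) + rep(c(0, 1), length.out = n)
    labels <- rep(c(FALSE, TRUE), length.out = n)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_mann_whitney(scores, labels)$auc, ref,
                 tolerance = 1e-12)
  }
})

test_that("Youden cutoff matches a brute-force threshold scan", {
  r <- youden_cutoff(c(1, 2, 3, 10), c(0, 0, 1, 1))
  expect_equal(r$cutoff, 2.5)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$youden_j, 1)
  # degenerate overlap
  r0 <- youden_cutoff(c(5, 5), c(TRUE, FALSE))
  expect_equal(r0$youden_j, 0)
  set.seed(24)
  for (k in 1:500) {
    n <- sample(4:14, 1)
    scores <- sample(seq(0, 3, by = 0.5), n, replace = TRUE)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    dir <- sample(c("positive_high", "positive_low"), 1)
    got <- youden_cutoff(scores, labels, dir)
    expect_equal(got$youden_j, youden_by_scan(scores, labels, dir),
                 tolerance = 1e-12)
    expect_equal(got$youden_j, got$sensitivity + got$specificity - 1)
  }
})

test_that("J and AUC are invariant under strictly increasing transforms", {
  set.seed(25)
  scores <- rnorm(40)
  labels <- rep(c(TRUE, FALSE), 20)
  f <- function(x) exp(x) + x^3
  expect_equal(auc_mann_whitney(scores, labels)$auc,
               auc_mann_whitney(f(scores), labels)$auc)
  expect_equal(youden_cutoff(scores, labels)$youden_j,
               youden_cutoff(f(scores), labels)$youden_j)
})

test_that("direction flip mirrors AUC and swaps the error roles", {
  set.seed(26)
  scores <- rnorm(30)
  labels <- rep(c(TRUE, FALSE), 15)
  hi <- auc_mann_whitney(scores, labels, "positive_high")$auc
  lo <- auc_mann_whitney(scores, labels, "positive_low")$auc
  expect_equal(hi + lo, 1)
})

test_that("bootstrap CI is deterministic, degenerate at perfect separation", {
  scores <- c(1:10, 101:110)
  labels <- rep(c(FALSE, TRUE), each = 10)
  ci <- bootstrap_auc_ci(scores, labels, n_boot = 200, seed = 1)
  expect_equal(ci$ci_low, 1)
  expect_equal(ci$ci_high, 1)
  set.seed(99)
  s2 <- rnorm(40)
  l2 <- rep(c(TRUE, FALSE), 20)
  expect_identical(bootstrap_auc_ci(s2, l2, n_boot = 200, seed = 5),
                   bootstrap_auc_ci(s2, l2, n_boot = 200, seed = 5))
  expect_error(bootstrap_auc_ci(s2, l2, n_boot = 50, seed = 1), ">= 100")
})

test_that("null-data bootstrap intervals straddle chance most of the time", {
  set.seed(27)
  hits <- 0
  reps <- 200
  for (k in 1:reps) {
    scores <- rnorm(100)
    labels <- rep(c(TRUE, FALSE), each = 50)
    ci <- bootstrap_auc_ci(scores, labels, n_boot = 500, seed = 1000 + k)
    if (ci$ci_low <= 0.5 && ci$ci_high >= 0.5) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("quality bands follow the published AUC grading", {
  expect_identical(quality_label(1.0), "perfect")
  expect_identical(quality_label(0.995), "perfect")   # rounds to 1.00
  expect_identical(quality_label(0.976), "excellent")
  expect_identical(quality_label(0.892), "good")
  expect_identical(quality_label(0.758), "fair")
  expect_identical(quality_label(0.60), "poor")
  expect_identical(quality_label(0.40), "non_discriminative")
  expect_error(quality_label(1.2), "\\[0, 1\\]")
})

test_that("roc_analysis assembles a consistent result row", {
  set.seed(28)
  scores <- c(rnorm(30, 1), rnorm(30))
  labels <- rep(c(TRUE, FALSE), each = 30)
  r <- roc_analysis(scores, labels, score_name = "demo",
                    n_boot = 200, seed = 3)
  expect_s3_class(r, "roc_result")
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  expect_equal(r$youden_j, r$sensitivity + r$specificity - 1)
  expect_identical(r$quality, quality_label(r$auc))
  expect_lt(r$p_value, 0.01)
})
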