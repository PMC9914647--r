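test_that("no-mediation generative model puts the effect on the direct path", {
  coh <- two_group_cohort(200, c_direct = 2, sigma = 1, seed = 31)
  m <- fit_mediation(coh, c("HC", "MCI"), "Y", n_boot = 300, seed = 1)
  # truth: direct = 2, indirect = 0; allow 3 SEs
  expect_lt(abs(m$direct$b - 2), 3 * m$direct$se)
  expect_lt(abs(m$indirect_age$b), 3 * max(m$indirect_age$se, 1e-6))
  expect_lt(abs(m$indirect_education$b),
            3 * max(m$indirect_education$se, 1e-6))
})

test_that("pure age mediation is recovered as the a*b product", {
  coh <- two_group_cohort(200, a_age = 5, b_age = 0.4, c_direct = 0,
                          sigma = 1, seed = 32)
  m <- fit_mediation(coh, c("HC", "MCI"), "Y", n_boot = 300, seed = 2)
  expect_lt(abs(m$indirect_age$b - 2), 3 * m$indirect_age$se)
  expect_lt(abs(m$direct$b), 3 * m$direct$se)
  # percentile CI brackets the point estimate in this well-posed case
  expect_lte(m$indirect_age$ci_low, m$indirect_age$b)
  expect_gte(m$indirect_age$ci_high, m$indirect_age$b)
})

test_that("total effect decomposes exactly into direct plus indirect", {
  for (seed in 1:5) {
    coh <- two_group_cohort(40, a_age = 3, a_edu = -2, b_age = 0.3,
                            b_edu = -0.5, c_direct = 1.5, sigma = 2,
                            seed = 100 + seed)
    m <- fit_mediation(coh, c("HC", "MCI"), "Y", n_boot = 100, seed = seed)
    expect_equal(m$total,
                 m$direct$b + m$indirect_age$b + m$indirect_education$b,
                 tolerance = 1e-8)
  }
})

test_that("bootstrap is deterministic given the seed", {
  coh <- two_group_cohort(50, a_age = 3, b_age = 0.3, c_direct = 1,
                          sigma = 1, seed = 7)
  m1 <- fit_mediation(coh, c("HC", "MCI"), "Y", n_boot = 200, seed = 9)
  m2 <- fit_mediation(coh, c("HC", "MCI"), "Y", n_boot = 200, seed = 9)
  expect_identical(m1, m2)
  m3 <- fit_mediation(coh, c("HC", "MCI"), "Y", n_boot = 200, seed = 10)
  expect_false(identical(m1$indirect_age$ci_low, m3$indirect_age$ci_low))
  # different seeds move the CI only by the bootstrap Monte-Carlo error
  expect_lt(abs(m1$indirect_age$ci_low - m3$indirect_age$ci_low),
            5 * m1$indirect_age$se / sqrt(200) * 10)
})

test_that("stratified resampling keeps both groups and stays deterministic", {
  coh <- two_group_cohort(30, c_direct = 1, sigma = 1, seed = 8)
  m1 <- fit_mediation(coh, c("HC", "MCI"), "Y", n_boot = 200, seed = 3,
                      stratified = TRUE)
  m2 <- fit_mediation(coh, c("HC", "MCI"), "Y", n_boot = 200, seed = 3,
                      stratified = TRUE)
  expect_identical(m1, m2)
})

test_that("degenerate designs fail naming the offending variable", {
  coh <- two_group_cohort(10, seed = 1)
  coh$age <- 60
  expect_error(fit_mediation(coh, c("HC", "MCI"), "Y", n_boot = 50, seed = 1),
               "age is constant")
  coh <- two_group_cohort(10, seed = 1)
  coh$Y <- 5
  expect_error(fit_mediation(coh, c("HC", "MCI"), "Y", n_boot = 50, seed = 1),
               "outcome is constant")
})

test_that("mediation_table applies the Bonferroni alpha default", {
  expect_equal(bonferroni_alpha(13), 0.004)
  expect_equal(bonferroni_alpha(14), 0.004)  # round(0.003571, 3)
  expect_equal(bonferroni_alpha(1), 0.05)
  coh <- generate_cohort(cohort_config(seed = 20))
  tab <- mediation_table(coh, c("SCD", "HC"),
                         outcomes = default_battery()$id[1:13],
                         n_boot = 50, seed = 5)
  expect_equal(attr(tab, "alpha"), 0.004)
  expect_length(tab, 13)
  tab1 <- mediation_table(coh, c("SCD", "HC"), outcomes = "ACT",
                          n_boot = 50, seed = 5)
  expect_equal(attr(tab1, "alpha"), 0.05)
})

test_that("per-outcome errors are collected without aborting the table", {
  coh <- generate_cohort(cohort_config(seed = 21))
  coh$WMCUT_S1 <- 1  # constant outcome
  tab <- mediation_table(coh, c("HC", "MCI"),
                         outcomes = c("WMCUT_S1", "ACT"),
                         n_boot = 50, seed = 5)
  expect_s3_class(tab[["ACT"]], "mediation_result")
  expect_true(inherits(tab[["WMCUT_S1"]], "error"))
  df <- as.data.frame(tab)
  expect_true(any(df$effect == "error"))
})

test_that("selection keeps purely direct effects only, in registry order", {
  mk <- function(outcome, p_dir, p_age, p_edu) {
    r <- list(outcome = outcome,
              direct = list(p = p_dir), indirect_age = list(p = p_age),
              indirect_education = list(p = p_edu),
              direct_significant = p_dir < 0.004,
              any_indirect_significant = p_age < 0.004 || p_edu < 0.004)
    class(r) <- "mediation_result"
    r
  }
  tab <- structure(list(A = mk("A", 0.001, 0.4, 0.6),
                        B = mk("B", 0.001, 0.002, 0.5),
                        C = mk("C", 0.6, 0.5, 0.5)),
                   pair = c("HC", "MCI"), alpha = 0.004,
                   class = "mediation_table")
  sel <- select_subtasks(tab)
  expect_identical(sel$selected, "A")
  expect_false(sel$empty)
  tab_null <- structure(list(C = mk("C", 0.6, 0.5, 0.5)),
                        pair = c("HC", "MCI"), alpha = 0.004,
                        class = "mediation_table")
  expect_warning(sel0 <- select_subtasks(tab_null), "empty selection")
  expect_true(sel0$empty)
  expect_length(sel0$selected, 0)
})
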