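#' Parallel two-mediator path model for one sub-score and one group pair
#'
#' Fits, by ordinary least squares, the path model with diagnosis (0 = the
#' cognitively better group of the pair, 1 = the worse; HC < SCD < MCI) as
#' predictor, age and education as parallel mediators, and the sub-score as
#' outcome:
#' * `age ~ diagnosis` (path a1), `education ~ diagnosis` (path a2),
#' * `score ~ diagnosis + age + education` (direct effect c', paths b1, b2).
#'
#' The direct effect's standard error, z and two-sided p come from the
#' asymptotic OLS summary. Each indirect effect is the product of
#' coefficients (a1*b1, a2*b2); its confidence interval is the percentile
#' interval over `n_boot` nonparametric resamples of participants (with
#' replacement over the pooled pair by default), its p-value a two-sided
#' normal test of the point estimate against the bootstrap standard
#' deviation. In this linear model the total effect (coefficient of
#' diagnosis in `score ~ diagnosis`) decomposes exactly as
#' direct + indirect(age) + indirect(education).
#'
#' @param cohort Cohort data frame (see [generate_cohort()], [read_cohort()]).
#' @param pair Character vector of two distinct group labels.
#' @param outcome Subtask id (a score column of `cohort`).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed; the bootstrap is deterministic given it.
#' @param alpha Per-test significance level (default 0.004, the
#'   Bonferroni-adjusted level for a 13-outcome family).
#' @param stratified If `TRUE`, resample within each group instead of over
#'   the pooled pair.
#' @return An object of class `mediation_result`: fields `pair`, `outcome`,
#'   `n`, `total` (coefficient of the simple regression), `direct`,
#'   `indirect_age`, `indirect_education` (each a list `b`, `se`, `z`, `p`,
#'   `ci_low`, `ci_high`), `n_boot`, `alpha`, `direct_significant`,
#'   `any_indirect_significant`.
#' @export
fit_mediation <- function(cohort, pair, outcome, n_boot = 1000, seed,
                          alpha = 0.004, stratified = FALSE) {
  if (missing(seed)) stop("fit_mediation() requires a seed")
  pair <- check_pair(cohort, pair)
  if (!outcome %in% names(cohort)) stop("outcome not in cohort: ", outcome)
  d <- cohort[cohort$group %in% pair,
              c("group", "age", "education", outcome)]
  d <- d[stats::complete.cases(d), ]
  if (any(table(d$group)[pair] < 3))
    stop("need >= 3 complete records per group for ", outcome)
  worse <- pair[which.max(group_severity(pair))]
  diag <- as.numeric(d$group == worse)
  y <- d[[outcome]]
  if (stats::var(d$age) == 0) stop("degenerate design: age is constant")
  if (stats::var(d$education) == 0)
    stop("degenerate design: education is constant")
  if (stats::var(y) == 0)
    stop("degenerate design: outcome is constant: ", outcome)

  n <- length(y)
  X1 <- cbind(1, diag)
  X2 <- cbind(1, diag, d$age, d$education)
  a1 <- fast_coef(X1, d$age)[2L]
  a2 <- fast_coef(X1, d$education)[2L]
  fy <- stats::lm.fit(X2, y)
  if (fy$rank < ncol(X2)) stop("degenerate design: rank-deficient fit for ",
                               outcome)
  b1 <- fy$coefficients[3L]
  b2 <- fy$coefficients[4L]
  cdir <- fy$coefficients[2L]
  # asymptotic SE of the direct effect: sigma^2 * [(X'X)^-1]_22 via the
  # (possibly pivoted) QR factor
  sigma2 <- sum(fy$residuals^2) / fy$df.residual
  V <- matrix(NA_real_, ncol(X2), ncol(X2))
  piv <- fy$qr$pivot
  V[piv, piv] <- chol2inv(qr.R(fy$qr))
  se_dir <- sqrt(sigma2 * V[2L, 2L])
  total <- fast_coef(X1, y)[2L]

  set.seed(seed)
  ind1 <- ind2 <- numeric(n_boot)
  grp_idx <- split(seq_len(n), d$group)
  b <- 1L
  while (b <= n_boot) {
    idx <- if (stratified) {
      unlist(lapply(grp_idx, function(g) sample(g, length(g), replace = TRUE)),
             use.names = FALSE)
    } else {
      sample.int(n, n, replace = TRUE)
    }
    db <- diag[idx]
    if (stats::var(db) == 0 || stats::var(d$age[idx]) == 0 ||
        stats::var(d$education[idx]) == 0) next
    Xb1 <- cbind(1, db)
    a1b <- fast_coef(Xb1, d$age[idx])[2L]
    a2b <- fast_coef(Xb1, d$education[idx])[2L]
    cb <- fast_coef(cbind(1, db, d$age[idx], d$education[idx]), y[idx])
    ind1[b] <- a1b * cb[3L]
    ind2[b] <- a2b * cb[4L]
    b <- b + 1L
  }

  direct <- effect_estimate(cdir, se_dir)
  indirect_age <- boot_effect(a1 * b1, ind1)
  indirect_edu <- boot_effect(a2 * b2, ind2)
  res <- list(pair = pair, outcome = outcome, n = n, total = unname(total),
              direct = direct, indirect_age = indirect_age,
              indirect_education = indirect_edu,
              n_boot = n_boot, alpha = alpha,
              direct_significant = direct$p < alpha,
              any_indirect_significant =
                indirect_age$p < alpha || indirect_edu$p < alpha)
  class(res) <- "mediation_result"
  res
}

#' OLS coefficients via the bare QR path, pivoted back to column order
#' @keywords internal
fast_coef <- function(X, y) {
  f <- stats::.lm.fit(X, y)
  co <- numeric(ncol(X))
  co[f$pivot] <- f$coefficients
  co
}

#' @keywords internal
effect_estimate <- function(b, se, level = 0.95) {
  z <- b / se
  q <- stats::qnorm(1 - (1 - level) / 2)
  list(b = unname(b), se = unname(se), z = unname(z),
       p = unname(2 * stats::pnorm(-abs(z))),
       ci_low = unname(b - q * se), ci_high = unname(b + q * se))
}

#' @keywords internal
boot_effect <- function(b, draws, level = 0.95) {
  se <- stats::sd(draws)
  ci <- unname(stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2)))
  z <- if (se > 0) b / se else 0
  list(b = unname(b), se = se, z = unname(z),
       p = unname(2 * stats::pnorm(-abs(z))),
       ci_low = ci[1L], ci_high = ci[2L])
}

#' @keywords internal
check_pair <- function(cohort, pair) {
  if (length(pair) != 2L || anyDuplicated(pair))
    stop("pair must be two distinct group labels")
  group_severity(pair)
  missing <- setdiff(pair, unique(cohort$group))
  if (length(missing))
    stop("group absent from cohort: ", paste(missing, collapse = ", "))
  pair
}

#' Mediation table over many outcomes
#'
#' Runs [fit_mediation()] for every outcome, deriving a per-outcome seed
#' deterministically from the master seed. The default per-test alpha is the
#' Bonferroni level `0.05 / length(outcomes)` rounded to three decimals —
#' 0.004 for the battery's 13- (or 14-) outcome families.
#'
#' @inheritParams fit_mediation
#' @param outcomes Character vector of subtask ids; defaults to every
#'   registry subtask present as a column of `cohort`.
#' @param alpha Per-test level; `NULL` (default) applies the Bonferroni rule.
#' @param registry Battery registry (sets the default outcome order).
#' @return Object of class `mediation_table`: a list of `mediation_result`
#'   (or error condition objects for outcomes whose fit failed), with
#'   attributes `pair` and `alpha`. Coerce with `as.data.frame()` for the
#'   report layout.
#' @export
mediation_table <- function(cohort, pair, outcomes = NULL, n_boot = 1000,
                            seed, alpha = NULL, stratified = FALSE,
                            registry = default_battery()) {
  if (missing(seed)) stop("mediation_table() requires a seed")
  pair <- check_pair(cohort, pair)
  if (is.null(outcomes))
    outcomes <- intersect(registry$id, names(cohort))
  if (!length(outcomes)) stop("no outcomes to test")
  if (is.null(alpha)) alpha <- round(0.05 / length(outcomes), 3)
  res <- vector("list", length(outcomes))
  names(res) <- outcomes
  for (k in seq_along(outcomes)) {
    res[[k]] <- tryCatch(
      fit_mediation(cohort, pair, outcomes[k], n_boot = n_boot,
                    seed = seed + k, alpha = alpha, stratified = stratified),
      error = function(e) e)
  }
  structure(res, pair = pair, alpha = alpha, class = "mediation_table")
}

#' Bonferroni per-test level used by the mediation stage
#'
#' @param n_outcomes Number of outcomes in the family.
#' @param family_alpha Family-wise level (default 0.05).
#' @return `family_alpha / n_outcomes`, rounded to 3 decimals.
#' @examples
#' bonferroni_alpha(13)  # 0.004
#' @export
bonferroni_alpha <- function(n_outcomes, family_alpha = 0.05) {
  round(family_alpha / n_outcomes, 3)
}

#' Select sub-scores whose group difference is purely direct
#'
#' A sub-score is selected when its direct diagnosis effect is significant
#' at the table's alpha while neither indirect (age, education) effect is.
#' Only such scores enter the composite, so that the resulting total score
#' discriminates diagnosis rather than demographics.
#'
#' @param table A [mediation_table()].
#' @return Object of class `selection_result`: fields `pair`, `selected`
#'   (ids, registry order), `empty` flag, `table`. An empty selection is
#'   reported with a warning, not an error.
#' @export
select_subtasks <- function(table) {
  if (!inherits(table, "mediation_table")) stop("expected a mediation_table")
  ok <- vapply(table, function(r) {
    inherits(r, "mediation_result") &&
      r$direct_significant && !r$any_indirect_significant
  }, logical(1))
  selected <- names(table)[ok]
  empty <- length(selected) == 0L
  if (empty)
    warning("empty selection: no sub-score shows a purely direct effect at ",
            "alpha = ", attr(table, "alpha"))
  structure(list(pair = attr(table, "pair"), selected = selected,
                 empty = empty, alpha = attr(table, "alpha"), table = table),
            class = "selection_result")
}

#' @export
as.data.frame.mediation_table <- function(x, ...) {
  rows <- list()
  for (id in names(x)) {
    r <- x[[id]]
    if (!inherits(r, "mediation_result")) {
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = id, effect = "error", b = NA_real_, se = NA_real_,
        z = NA_real_, p = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        note = conditionMessage(r), stringsAsFactors = FALSE)
      next
    }
    for (eff in c("direct", "indirect_age", "indirect_education")) {
      e <- r[[eff]]
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = id, effect = eff, b = e$b, se = e$se, z = e$z, p = e$p,
        ci_low = e$ci_low, ci_high = e$ci_high, note = "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pair") <- attr(x, "pair")
  attr(out, "alpha") <- attr(x, "alpha")
  out
}

#' Write a mediation report
#'
#' Emits the two-block layout used for reporting path models — an `(a)`
#' block of direct effects and a `(b)` block of the bootstrap indirect
#' effects, columns b, SE, z, p and the 95% CI bounds — as CSV or JSON.
#'
#' @param table A [mediation_table()].
#' @param path Output file; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_mediation_report <- function(table, path) {
  df <- as.data.frame(table)
  df$block <- ifelse(df$effect == "direct", "a_direct", "b_indirect")
  df <- df[order(df$block), ]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(pair = attr(table, "pair"), alpha = attr(table, "alpha"),
           effects = df),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
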