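#' Run the full discrimination analysis for one group pair
#'
#' Executes the stages in order: mediation table over all battery outcomes
#' present in the cohort; selection of the sub-scores with a purely direct
#' diagnosis effect; orientation and min-max normalization over the pooled
#' pair; per-subtask weights (SD after normalization, AUC); the eight
#' composite total scores; one ROC/Youden row per composite (composites are
#' higher-is-better, so the impaired side is low: `positive_low`); and the
#' best-formula pick. On an empty selection the report carries the warning
#' and no composite stage. Deterministic given `seed`.
#'
#' @param cohort Cohort data frame with both groups of the pair.
#' @param pair Two group labels; the worse group (HC < SCD < MCI) is the
#'   positive class.
#' @param seed Integer master seed for the mediation and CI bootstraps.
#' @param n_boot Bootstrap resamples for the indirect effects (default 1000).
#' @param ci_boot Bootstrap resamples for each AUC confidence interval
#'   (default 2000).
#' @param alpha Per-test significance level (default 0.004); `NULL` applies
#'   the Bonferroni rule over the tested outcomes.
#' @param outcomes Outcomes to test; default: all registry subtasks present.
#' @param stratified Stratify the mediation bootstrap within groups.
#' @param registry Battery registry.
#' @return Object of class `pairwise_report`: fields `pair`, `positive`,
#'   `mediation`, `selection`, `weights`, `normalized`, `composites`,
#'   `roc`, `best`, `meta`.
#' @export
run_pair <- function(cohort, pair, seed, n_boot = 1000, ci_boot = 2000,
                     alpha = 0.004, outcomes = NULL, stratified = FALSE,
                     registry = default_battery()) {
  if (missing(seed)) stop("run_pair() requires a seed")
  pair <- check_pair(cohort, pair)
  worse <- pair[which.max(group_severity(pair))]
  med <- mediation_table(cohort, pair, outcomes = outcomes, n_boot = n_boot,
                         seed = seed, alpha = alpha, stratified = stratified,
                         registry = registry)
  sel <- withCallingHandlers(
    select_subtasks(med),
    warning = function(w) invokeRestart("muffleWarning"))
  meta <- list(seed = seed, n_boot = n_boot, ci_boot = ci_boot,
               alpha = attr(med, "alpha"),
               package_version = as.character(utils::packageVersion("r4alzr")))
  if (sel$empty) {
    rep <- list(pair = pair, positive = worse, mediation = med,
                selection = sel, weights = NULL, normalized = NULL,
                composites = NULL, roc = NULL, best = NULL,
                warning = "empty selection: no purely direct sub-score",
                meta = meta)
    class(rep) <- "pairwise_report"
    return(rep)
  }
  norm <- normalize_scores(cohort, pair, sel$selected, registry)
  comp <- compute_composites(norm)
  pos <- comp$group == worse
  rocs <- lapply(seq_along(composite_formulas()), function(k) {
    f <- composite_formulas()[k]
    roc_analysis(comp[[f]], pos, score_name = f, pair = pair,
                 direction = "positive_low", n_boot = ci_boot,
                 seed = seed + 10000L + k)
  })
  names(rocs) <- composite_formulas()
  best <- pick_best_formula(rocs)
  rep <- list(pair = pair, positive = worse, mediation = med,
              selection = sel, weights = attr(comp, "weights"),
              normalized = norm, composites = comp, roc = rocs, best = best,
              warning = NULL, meta = meta)
  class(rep) <- "pairwise_report"
  rep
}

#' Run the analysis for the three canonical group pairs
#'
#' (SCD, HC), (SCD, MCI) and (HC, MCI), each with independent per-pair
#' weights and cutoffs. Pairs whose groups are missing from the cohort are
#' reported as error conditions instead of reports.
#'
#' @inheritParams run_pair
#' @return Named list of three `pairwise_report` (or error) objects:
#'   `SCD_vs_HC`, `SCD_vs_MCI`, `HC_vs_MCI`.
#' @export
run_all <- function(cohort, seed, n_boot = 1000, ci_boot = 2000,
                    alpha = 0.004, stratified = FALSE,
                    registry = default_battery()) {
  if (missing(seed)) stop("run_all() requires a seed")
  pairs <- list(SCD_vs_HC = c("SCD", "HC"),
                SCD_vs_MCI = c("SCD", "MCI"),
                HC_vs_MCI = c("HC", "MCI"))
  out <- lapply(seq_along(pairs), function(k) {
    tryCatch(run_pair(cohort, pairs[[k]], seed = seed + 100000L * k,
                      n_boot = n_boot, ci_boot = ci_boot, alpha = alpha,
                      stratified = stratified, registry = registry),
             error = function(e) e)
  })
  names(out) <- names(pairs)
  out
}

#' Pick the composite formula with the best sensitivity/specificity trade-off
#'
#' Maximizes the Youden index; ties are broken by higher AUC, then by the
#' canonical formula order (plain sum first). The full comparison trace is
#' returned so any other criterion can be applied to the same rows.
#'
#' @param roc_rows Named list of `roc_result` objects, one per formula.
#' @return List: `formula` (winning name), `trace` (data frame with
#'   `formula`, `youden_j`, `auc`, `sensitivity`, `specificity`,
#'   `selected`).
#' @export
pick_best_formula <- function(roc_rows) {
  stopifnot(length(roc_rows) >= 1)
  trace <- data.frame(
    formula = names(roc_rows),
    youden_j = vapply(roc_rows, function(r) r$youden_j, numeric(1)),
    auc = vapply(roc_rows, function(r) r$auc, numeric(1)),
    sensitivity = vapply(roc_rows, function(r) r$sensitivity, numeric(1)),
    specificity = vapply(roc_rows, function(r) r$specificity, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  best_i <- 1L
  for (i in seq_len(nrow(trace))[-1]) {
    if (trace$youden_j[i] > trace$youden_j[best_i] + 1e-12 ||
        (abs(trace$youden_j[i] - trace$youden_j[best_i]) <= 1e-12 &&
           trace$auc[i] > trace$auc[best_i] + 1e-12)) {
      best_i <- i
    }
  }
  trace$selected <- seq_len(nrow(trace)) == best_i
  list(formula = trace$formula[best_i], trace = trace)
}

#' Classification table of the eight formulas for one report
#'
#' Rows in canonical formula order, columns Cutoff, AUC, Sensitivity,
#' Specificity, the 95% CI bounds and the p-value versus chance; the
#' best-formula row is flagged.
#'
#' @param report A `pairwise_report` from [run_pair()].
#' @return Data frame, one row per formula.
#' @export
classification_table <- function(report) {
  if (!inherits(report, "pairwise_report")) stop("expected a pairwise_report")
  if (is.null(report$roc)) stop("report has no ROC stage (empty selection)")
  rows <- lapply(report$roc, function(r) {
    data.frame(formula = r$score_name, cutoff = r$cutoff, auc = r$auc,
               sensitivity = r$sensitivity, specificity = r$specificity,
               ci_low = r$ci_low, ci_high = r$ci_high, p_value = r$p_value,
               quality = r$quality, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$best <- out$formula == report$best$formula
  out
}

#' Write a report bundle
#'
#' One JSON document (`report.json`) plus flat CSV tables per pair: the
#' mediation effects, the weight table, the per-participant composites and
#' the classification table.
#'
#' @param reports A single `pairwise_report` or the list from [run_all()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(reports, dir) {
  if (inherits(reports, "pairwise_report"))
    reports <- stats::setNames(list(reports),
                               paste(reports$pair, collapse = "_vs_"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- list()
  for (nm in names(reports)) {
    rep <- reports[[nm]]
    if (!inherits(rep, "pairwise_report")) {
      bundle[[nm]] <- list(error = conditionMessage(rep))
      next
    }
    write_mediation_report(rep$mediation,
                           file.path(dir, paste0(nm, "_mediation.csv")))
    if (!is.null(rep$composites)) {
      write_weight_table(rep$composites,
                         file.path(dir, paste0(nm, "_weights.csv")))
      utils::write.csv(as.data.frame(rep$composites),
                       file.path(dir, paste0(nm, "_composites.csv")),
                       row.names = FALSE)
      utils::write.csv(classification_table(rep),
                       file.path(dir, paste0(nm, "_classification.csv")),
                       row.names = FALSE)
    }
    bundle[[nm]] <- report_summary(rep)
  }
  jsonlite::write_json(bundle, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

#' Summarize a pairwise report as plain lists (JSON-ready)
#' @param report A `pairwise_report`.
#' @return Nested list mirroring the report's headline content.
#' @export
report_summary <- function(report) {
  out <- list(pair = report$pair, positive_class = report$positive,
              alpha = report$meta$alpha, seed = report$meta$seed,
              n_boot = report$meta$n_boot,
              selected = report$selection$selected,
              warning = report$warning, meta = report$meta)
  if (!is.null(report$roc)) {
    out$weights <- report$weights
    out$classification <- classification_table(report)
    out$best_formula <- report$best$formula
  }
  out
}

#' @export
print.pairwise_report <- function(x, ...) {
  cat("Pairwise discrimination report: ", x$pair[1], " vs ", x$pair[2],
      " (positive class: ", x$positive, ")\n", sep = "")
  cat("  alpha =", x$meta$alpha, " n_boot =", x$meta$n_boot, "\n")
  if (x$selection$empty) {
    cat("  empty selection: no sub-score with a purely direct effect\n")
    return(invisible(x))
  }
  cat("  selected sub-scores:", paste(x$selection$selected, collapse = ", "),
      "\n")
  ct <- classification_table(x)
  cat("  best formula:", x$best$formula,
      sprintf("(AUC %.3f, sens %.1f%%, spec %.1f%%, cutoff %.4f)\n",
              ct$auc[ct$best], 100 * ct$sensitivity[ct$best],
              100 * ct$specificity[ct$best], ct$cutoff[ct$best]))
  invisible(x)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC %s: AUC %.3f [%.3f, %.3f], p %.3g, cutoff %.4f (%s), sens %.3f, spec %.3f, %s\n",
    x$score_name, x$auc, x$ci_low, x$ci_high, x$p_value, x$cutoff,
    x$direction, x$sensitivity, x$specificity, x$quality))
  invisible(x)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation:", x$pair[1], "vs", x$pair[2], "->", x$outcome,
      sprintf("(n = %d, %d bootstrap draws, alpha = %g)\n",
              x$n, x$n_boot, x$alpha))
  f <- function(e) sprintf("b = %8.3f  se = %6.3f  z = %6.2f  p = %.4f  [%.3f, %.3f]",
                           e$b, e$se, e$z, e$p, e$ci_low, e$ci_high)
  cat("  direct:            ", f(x$direct), "\n")
  cat("  indirect (age):    ", f(x$indirect_age), "\n")
  cat("  indirect (edu):    ", f(x$indirect_education), "\n")
  invisible(x)
}
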