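#' Min-max normalization
#'
#' Rescales a vector onto `[0, 1]` via `(x - min) / (max - min)`. The
#' observed minimum maps to 0 and the maximum to 1, so every normalized
#' column attains both endpoints; the transform is invariant to positive
#' affine changes of the input.
#'
#' @param values Numeric vector, length >= 2.
#' @param id Optional identifier used in the degenerate-column error.
#' @return List: `values` (normalized vector), `min_used`, `max_used`.
#' @examples
#' minmax_normalize(c(2, 4, 6))$values  # 0, 0.5, 1
#' @export
minmax_normalize <- function(values, id = NULL) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop("need at least 2 observed values")
  lo <- min(v)
  hi <- max(v)
  if (hi == lo) {
    e <- simpleError(paste0("degenerate column",
                            if (!is.null(id)) paste0(" '", id, "'"),
                            ": max equals min"))
    class(e) <- c("degenerate_column", class(e))
    attr(e, "subtask") <- id
    stop(e)
  }
  list(values = (values - lo) / (hi - lo), min_used = lo, max_used = hi)
}

#' Orient and min-max normalize the selected sub-scores of a group pair
#'
#' Restricts the cohort to the two groups, orients every selected score so
#' higher means cognitively better ([orient_score()]), normalizes each onto
#' `[0, 1]` over the pooled pair, and attaches the per-subtask weights the
#' composite formulas use: the sample SD (denominator n-1) of the normalized
#' column and its ROC AUC for the pair. The AUC is computed with the worse
#' group as positive class and reported as `max(AUC, 1 - AUC)` (the polarity
#' actually observed is kept in `auc_polarity`), mirroring how per-variable
#' discrimination is conventionally tabulated.
#'
#' Degenerate (zero-range) columns are dropped with a warning rather than
#' failing the run; dropped ids are recorded in the `dropped` field.
#'
#' @param cohort Cohort data frame.
#' @param pair Two group labels; the worse group (higher severity) is the
#'   positive class.
#' @param subtasks Ids of the selected sub-scores.
#' @param registry Battery registry.
#' @return Object of class `normalized_matrix`: `ids` (participant ids),
#'   `group`, `pair`, `subtasks`, `values` (participants x subtasks matrix
#'   in `[0, 1]`), `min_used`, `max_used`, `sd_norm`, `auc`, `auc_polarity`,
#'   `dropped`.
#' @export
normalize_scores <- function(cohort, pair, subtasks,
                             registry = default_battery()) {
  pair <- check_pair(cohort, pair)
  if (!length(subtasks)) stop("no subtasks to normalize")
  missing_cols <- setdiff(subtasks, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks score columns: ", paste(missing_cols, collapse = ", "))
  d <- cohort[cohort$group %in% pair, , drop = FALSE]
  worse <- pair[which.max(group_severity(pair))]
  pos <- d$group == worse

  keep <- character(0)
  dropped <- character(0)
  vals <- list()
  min_used <- max_used <- sd_norm <- auc <- numeric(0)
  auc_polarity <- character(0)
  for (s in subtasks) {
    oriented <- orient_score(s, d[[s]], registry)
    nm <- tryCatch(minmax_normalize(oriented, id = s),
                   degenerate_column = function(e) e)
    if (inherits(nm, "degenerate_column")) {
      warning("dropping degenerate column '", s, "' (zero range)")
      dropped <- c(dropped, s)
      next
    }
    keep <- c(keep, s)
    vals[[s]] <- nm$values
    min_used <- c(min_used, nm$min_used)
    max_used <- c(max_used, nm$max_used)
    sd_norm <- c(sd_norm, stats::sd(nm$values))
    a <- auc_mann_whitney(nm$values, pos, direction = "positive_high")$auc
    auc_polarity <- c(auc_polarity,
                      if (a >= 0.5) "positive_high" else "positive_low")
    auc <- c(auc, max(a, 1 - a))
  }
  if (!length(keep)) stop("all selected columns are degenerate")
  values <- do.call(cbind, vals[keep])
  rownames(values) <- d$id
  names(min_used) <- names(max_used) <- names(sd_norm) <- names(auc) <-
    names(auc_polarity) <- keep
  structure(list(ids = d$id, group = d$group, pair = pair, subtasks = keep,
                 values = values, min_used = min_used, max_used = max_used,
                 sd_norm = sd_norm, auc = auc, auc_polarity = auc_polarity,
                 dropped = dropped),
            class = "normalized_matrix")
}

#' Names of the eight composite total-score formulas
#'
#' @param aliases If `TRUE`, return the canonical display aliases
#'   (S-Sigma notation) instead of the column names.
#' @return Character vector of length 8, in canonical order.
#' @export
composite_formulas <- function(aliases = FALSE) {
  cols <- c("s_sum", "s_sumsq", "s_sumsq_auc", "s_sumsq_auc2",
            "s_sum_sd", "s_sumsq_sd", "s_sumsq_auc_sd", "s_sumsq_auc2_sd")
  if (!aliases) return(cols)
  c("S\u03a3", "S\u03a32", "S\u03a32AUC", "S\u03a32AUC2",
    "S\u03a3\u03c3", "S\u03a32\u03c3", "S\u03a32AUC\u03c3",
    "S\u03a32AUC2\u03c3")
}

#' Compute the eight composite total scores
#'
#' Given normalized scores `X_i` in `[0, 1]` with per-subtask weights
#' `AUC_i` and `sigma_i` (SD after normalization), emits per participant:
#' \describe{
#'   \item{s_sum}{`sum(X_i)` — plain sum.}
#'   \item{s_sumsq}{`sum(X_i^2)` — squaring widens the gap between values
#'     near 1 (0.9^2 = 0.81, a 10% reduction) and values far from 1
#'     (0.5^2 = 0.25, a 50% reduction).}
#'   \item{s_sumsq_auc}{`sum(X_i^2 * AUC_i)`.}
#'   \item{s_sumsq_auc2}{`sum(X_i^2 * AUC_i^2)`.}
#'   \item{s_sum_sd}{`sum(X_i / sigma_i)`.}
#'   \item{s_sumsq_sd}{`sum(X_i^2 / sigma_i)`.}
#'   \item{s_sumsq_auc_sd}{`sum((X_i^2 / sigma_i) * AUC_i)`.}
#'   \item{s_sumsq_auc2_sd}{`sum((X_i^2 / sigma_i) * AUC_i^2)`.}
#' }
#'
#' @param norm A [normalize_scores()] result.
#' @return Object of class `composite_table`: a data frame with `id`,
#'   `group` and the eight score columns; the weight snapshot is attached
#'   as `attr(, "weights")` (subtask, sd_norm, auc).
#' @export
compute_composites <- function(norm) {
  if (!inherits(norm, "normalized_matrix"))
    stop("expected a normalized_matrix")
  X <- norm$values
  if (!setequal(colnames(X), names(norm$auc)) ||
      !setequal(colnames(X), names(norm$sd_norm)))
    stop("weights do not match normalized columns")
  auc <- norm$auc[colnames(X)]
  sd_ <- norm$sd_norm[colnames(X)]
  if (any(sd_ <= 0)) stop("sd_norm must be > 0 for every retained column")
  X2 <- X^2
  out <- data.frame(
    id = norm$ids,
    group = norm$group,
    s_sum           = rowSums(X),
    s_sumsq         = rowSums(X2),
    s_sumsq_auc     = as.vector(X2 %*% auc),
    s_sumsq_auc2    = as.vector(X2 %*% auc^2),
    s_sum_sd        = as.vector(X %*% (1 / sd_)),
    s_sumsq_sd      = as.vector(X2 %*% (1 / sd_)),
    s_sumsq_auc_sd  = as.vector(X2 %*% (auc / sd_)),
    s_sumsq_auc2_sd = as.vector(X2 %*% (auc^2 / sd_)),
    stringsAsFactors = FALSE
  )
  attr(out, "weights") <- data.frame(subtask = colnames(X),
                                     sd_norm = unname(sd_),
                                     auc = unname(auc),
                                     stringsAsFactors = FALSE)
  attr(out, "pair") <- norm$pair
  class(out) <- c("composite_table", "data.frame")
  out
}

#' Write the per-pair weight table (SD after normalization, AUC)
#'
#' @param norm A [normalize_scores()] result (or a `composite_table`).
#' @param path Output file, `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(norm, path) {
  w <- if (inherits(norm, "composite_table")) attr(norm, "weights")
       else data.frame(subtask = norm$subtasks,
                       sd_norm = unname(norm$sd_norm[norm$subtasks]),
                       auc = unname(norm$auc[norm$subtasks]))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(w, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    utils::write.csv(w, path, row.names = FALSE)
  }
  invisible(path)
}
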