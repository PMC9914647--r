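#' Mann-Whitney AUC with Hanley-McNeil standard error
#'
#' The empirical AUC is the fraction of (positive, negative) pairs in which
#' the positive participant scores on the impaired side, ties counted one
#' half — the normalized Mann-Whitney U statistic, computed via midranks.
#' With `direction = "positive_high"` the impaired side is high scores; with
#' `"positive_low"` (the convention for the oriented composites, where
#' higher means cognitively better) it is low scores.
#'
#' @param scores Numeric vector.
#' @param labels Logical (or 0/1) vector, `TRUE` = positive (impaired) class.
#' @param direction `"positive_high"` or `"positive_low"`.
#' @return List: `auc`, `se` (Hanley-McNeil), `n_pos`, `n_neg`.
#' @examples
#' auc_mann_whitney(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc  # 1
#' @export
auc_mann_whitney <- function(scores, labels,
                             direction = c("positive_high", "positive_low")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks: ties counted 1/2
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  if (direction == "positive_low") auc <- 1 - auc
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  list(auc = auc, se = se, n_pos = n_pos, n_neg = n_neg)
}

#' Two-sided p-value of the AUC against chance
#'
#' Normal approximation to the Mann-Whitney U statistic with the usual tie
#' correction of its null variance.
#'
#' @inheritParams auc_mann_whitney
#' @return Two-sided p-value for the null AUC = 0.5.
#' @export
auc_p_value <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  n <- n_pos + n_neg
  auc <- auc_mann_whitney(scores, labels)$auc
  U <- auc * n_pos * n_neg
  ties <- table(scores)
  var_u <- n_pos * n_neg / 12 *
    ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (var_u <= 0) return(1)
  z <- (U - n_pos * n_neg / 2) / sqrt(var_u)
  2 * stats::pnorm(-abs(z))
}

#' Youden-index-optimal cutoff
#'
#' Scans every achievable threshold — the midpoints between adjacent
#' distinct observed scores plus -Inf/+Inf sentinels — and returns the one
#' maximizing J = sensitivity + specificity - 1. A participant is called
#' impaired when their score lies on the impaired side of the cutoff
#' (above it for `positive_high`, below for `positive_low`). Ties in J are
#' broken in favour of higher sensitivity (screening preference), then the
#' lower cutoff.
#'
#' @inheritParams auc_mann_whitney
#' @return List: `cutoff`, `sensitivity`, `specificity`, `youden_j`,
#'   `direction`.
#' @examples
#' youden_cutoff(c(1, 2, 3, 10), c(FALSE, FALSE, TRUE, TRUE))  # cutoff 2.5
#' @export
youden_cutoff <- function(scores, labels,
                          direction = c("positive_high", "positive_low")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  if (!any(labels) || all(labels)) stop("both classes must be present")
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  pos <- scores[labels]
  neg <- scores[!labels]
  best <- NULL
  for (t in thr) {
    if (direction == "positive_high") {
      sens <- mean(pos > t)
      spec <- mean(neg <= t)
    } else {
      sens <- mean(pos < t)
      spec <- mean(neg >= t)
    }
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden_j + 1e-12 ||
        (abs(j - best$youden_j) <= 1e-12 &&
           (sens > best$sensitivity + 1e-12 ||
              (abs(sens - best$sensitivity) <= 1e-12 && t < best$cutoff)))) {
      best <- list(cutoff = t, sensitivity = sens, specificity = spec,
                   youden_j = j, direction = direction)
    }
  }
  best
}

#' Bootstrap percentile confidence interval for the AUC
#'
#' Class-stratified nonparametric bootstrap (both classes are resampled
#' within themselves, so every resample keeps both classes), percentile
#' interval; deterministic given `seed`.
#'
#' @inheritParams auc_mann_whitney
#' @param n_boot Number of resamples, at least 100 (default 2000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return List: `ci_low`, `ci_high`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 2000, seed,
                             level = 0.95,
                             direction = c("positive_high", "positive_low")) {
  direction <- match.arg(direction)
  if (missing(seed)) stop("bootstrap_auc_ci() requires a seed")
  if (n_boot < 100) stop("n_boot must be >= 100")
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  if (!length(pos) || !length(neg)) stop("both classes must be present")
  set.seed(seed)
  draws <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    sb <- c(sample(pos, length(pos), replace = TRUE),
            sample(neg, length(neg), replace = TRUE))
    lb <- rep(c(TRUE, FALSE), c(length(pos), length(neg)))
    draws[b] <- auc_mann_whitney(sb, lb, direction)$auc
  }
  ci <- unname(stats::quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2)))
  list(ci_low = ci[1L], ci_high = ci[2L])
}

#' Discrimination-quality label for an AUC
#'
#' Bands applied to the AUC rounded to two decimals: 1.0 is perfect,
#' 0.90-0.99 excellent, 0.80-0.89 good, 0.70-0.79 fair, 0.51-0.69 poor;
#' anything below 0.51 is labelled `non_discriminative`.
#'
#' @param auc Number in `[0, 1]`.
#' @return One of `"perfect"`, `"excellent"`, `"good"`, `"fair"`, `"poor"`,
#'   `"non_discriminative"`.
#' @examples
#' quality_label(0.976)  # "excellent"
#' quality_label(0.758)  # "fair"
#' @export
quality_label <- function(auc) {
  if (length(auc) != 1L || is.na(auc) || auc < 0 || auc > 1)
    stop("auc must be a single number in [0, 1]")
  a <- round(auc, 2)
  if (a >= 1) "perfect"
  else if (a >= 0.90) "excellent"
  else if (a >= 0.80) "good"
  else if (a >= 0.70) "fair"
  else if (a >= 0.51) "poor"
  else "non_discriminative"
}

#' Full ROC analysis of one score for one group pair
#'
#' Combines [auc_mann_whitney()], [bootstrap_auc_ci()], [auc_p_value()],
#' [youden_cutoff()] and [quality_label()] into the per-score row of a
#' classification table.
#'
#' @inheritParams auc_mann_whitney
#' @param score_name Name reported for the score.
#' @param pair Group-pair labels for the report.
#' @param n_boot,seed,level Bootstrap CI parameters (see
#'   [bootstrap_auc_ci()]).
#' @return Object of class `roc_result`: `score_name`, `pair`, `n_pos`,
#'   `n_neg`, `auc`, `ci_low`, `ci_high`, `p_value`, `cutoff`,
#'   `sensitivity`, `specificity`, `youden_j`, `direction`, `quality`.
#' @export
roc_analysis <- function(scores, labels, score_name = "score", pair = NULL,
                         direction = c("positive_high", "positive_low"),
                         n_boot = 2000, seed, level = 0.95) {
  direction <- match.arg(direction)
  a <- auc_mann_whitney(scores, labels, direction)
  ci <- bootstrap_auc_ci(scores, labels, n_boot = n_boot, seed = seed,
                         level = level, direction = direction)
  yc <- youden_cutoff(scores, labels, direction)
  res <- list(score_name = score_name, pair = pair,
              n_pos = a$n_pos, n_neg = a$n_neg,
              auc = a$auc, auc_se = a$se,
              ci_low = ci$ci_low, ci_high = ci$ci_high,
              p_value = auc_p_value(scores, labels),
              cutoff = yc$cutoff, sensitivity = yc$sensitivity,
              specificity = yc$specificity, youden_j = yc$youden_j,
              direction = direction, quality = quality_label(a$auc))
  class(res) <- "roc_result"
  res
}

#' Empirical ROC curve points
#'
#' Threshold / false-positive-rate / true-positive-rate triples over the
#' same achievable thresholds [youden_cutoff()] scans; suitable for
#' plotting or export.
#'
#' @inheritParams auc_mann_whitney
#' @return Data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels,
                       direction = c("positive_high", "positive_low")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  pos <- scores[labels]
  neg <- scores[!labels]
  if (direction == "positive_high") {
    tpr <- vapply(thr, function(t) mean(pos > t), numeric(1))
    fpr <- vapply(thr, function(t) mean(neg > t), numeric(1))
  } else {
    tpr <- vapply(thr, function(t) mean(pos < t), numeric(1))
    fpr <- vapply(thr, function(t) mean(neg < t), numeric(1))
  }
  o <- order(fpr, tpr)
  data.frame(threshold = thr[o], fpr = fpr[o], tpr = tpr[o])
}
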