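# Builders for small synthetic cohorts used across test files.

# Two-group cohort with explicit mediation paths: age and education means
# differ between groups by a_age / a_edu, and the outcome follows
# intercept + c_direct * diag + b_age * age + b_edu * edu + N(0, sigma).
# Returns a plain cohort data frame with one score column "Y" registered
# on the fly as an unbounded performance score.
two_group_cohort <- function(n_per_group, a_age = 0, a_edu = 0,
                             b_age = 0, b_edu = 0, c_direct = 0,
                             sigma = 1, seed,
                             groups = c("HC", "MCI")) {
  set.seed(seed)
  n <- 2 * n_per_group
  diag <- rep(c(0, 1), each = n_per_group)
  age <- 62 + a_age * diag + rnorm(n, 0, 5)
  edu <- 14 + a_edu * diag + rnorm(n, 0, 3)
  y <- 10 + c_direct * diag + b_age * age + b_edu * edu + rnorm(n, 0, sigma)
  structure(
    data.frame(id = sprintf("T%04d", seq_len(n)),
               group = rep(groups, each = n_per_group),
               age = age, education = edu,
               gender = "F", Y = y, stringsAsFactors = FALSE),
    class = c("r4alz_cohort", "data.frame"))
}

# Registry with a single unbounded higher-better score "Y", for pipelines
# that bypass the battery definition.
y_registry <- function() {
  reg <- data.frame(id = "Y", label = "test score",
                    kind = "performance_score",
                    min_score = NA_real_, max_score = NA_real_,
                    orientation = "higher_better",
                    stringsAsFactors = FALSE)
  class(reg) <- c("battery_registry", "data.frame")
  reg
}

# Brute-force AUC oracle: enumerate all positive-negative pairs.
auc_by_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Brute-force Youden oracle: scan every observed value and midpoint.
youden_by_scan <- function(scores, labels, direction = "positive_high") {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cand <- sort(unique(c(-Inf, Inf, scores,
                        (sort(unique(scores))[-1] +
                           rev(rev(sort(unique(scores)))[-1])) / 2)))
  best <- -Inf
  for (t in cand) {
    if (direction == "positive_high") {
      j <- mean(pos > t) + mean(neg <= t) - 1
    } else {
      j <- mean(pos < t) + mean(neg >= t) - 1
    }
    if (j > best) best <- j
  }
  best
}
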