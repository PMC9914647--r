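#' Default path coefficients for the synthetic cohort generator
#'
#' One row per sub-score with the linear path model used by
#' [generate_cohort()]:
#' `score = intercept + c_direct * severity + b_age * (age - 65) +
#'  b_edu * (education - 14) + noise`,
#' where `severity` is 0 (HC), 1 (SCD), 2 (MCI). `c_direct` is the direct
#' diagnosis effect per severity step; `sigma` the residual SD. Defaults
#' emulate moderate separation: roughly one residual SD between the extreme
#' groups on the discriminating subtasks, error-like scores worsening mildly
#' with age and improving mildly with education, and intercepts placed so
#' bounded scores rarely clip.
#'
#' @return Data frame with columns `id`, `intercept`, `c_direct`, `b_age`,
#'   `b_edu`, `sigma`.
#' @export
default_path_table <- function() {
  reg <- default_battery()
  tab <- data.frame(
    id        = reg$id,
    intercept = c(6, 5, 10, 40, 60, 2, 2, 12, 2, 2.5, 3, 8, 3, 5),
    c_direct  = c(-0.10, -0.30, -0.61, 1.83, 4.05, 0.33, 0.51, 1.28,
                  0.50, 0.69, 0.49, -0.65, 0.87, 0.59),
    sigma     = c(0.42, 0.45, 1.17, 3.78, 5.20, 0.54, 0.76, 1.63,
                  0.97, 0.82, 1.01, 0.96, 1.30, 1.18),
    stringsAsFactors = FALSE
  )
  worse_up <- ifelse(reg$orientation == "higher_worse", 1, -1)
  tab$b_age <- 0.02 * tab$sigma * worse_up
  tab$b_edu <- -0.03 * tab$sigma * worse_up
  tab[c("id", "intercept", "c_direct", "b_age", "b_edu", "sigma")]
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study-design conditions the pipeline assumes:
#' three diagnostic groups of 20 HC / 29 SCD / 31 MCI; ages about
#' 61.6 (SD 6.58), 61.2 (SD 7.00) and 68.7 (SD 8.43) years; education about
#' 16.3 (SD 3.04), 13.3 (SD 4.20) and 13.5 (SD 4.31) years; and sub-scores
#' produced by the linear two-mediator path structure of
#' [default_path_table()]. Because the generator draws group-specific
#' age/education means, the implied diagnosis-to-mediator paths of a pair
#' are the differences of those means.
#'
#' @param group_sizes Named integer vector over `HC`, `SCD`, `MCI` (a group
#'   may be omitted); each size must be at least 2.
#' @param age_mean,age_sd,edu_mean,edu_sd Named numeric vectors per group.
#' @param paths Path-coefficient table, see [default_path_table()].
#' @param prop_female Named numeric vector, probability a participant is
#'   female, per group.
#' @param score_noise_family `"truncated_gaussian"` (bounded scores clipped
#'   to their registry bounds, clip count reported) or `"gaussian"` (no
#'   clipping).
#' @param seed Integer seed; mandatory, the generator is fully deterministic
#'   given the configuration.
#' @param registry Battery registry defining bounds and orientation.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(HC = 20, SCD = 29, MCI = 31),
                          age_mean = c(HC = 61.60, SCD = 61.17, MCI = 68.67),
                          age_sd   = c(HC = 6.58,  SCD = 7.00,  MCI = 8.43),
                          edu_mean = c(HC = 16.30, SCD = 13.31, MCI = 13.45),
                          edu_sd   = c(HC = 3.04,  SCD = 4.20,  MCI = 4.31),
                          paths = default_path_table(),
                          prop_female = c(HC = 14 / 20, SCD = 20 / 29,
                                          MCI = 24 / 31),
                          score_noise_family = c("truncated_gaussian",
                                                 "gaussian"),
                          seed,
                          registry = default_battery()) {
  score_noise_family <- match.arg(score_noise_family)
  if (missing(seed)) stop("cohort_config() requires an integer seed")
  groups <- names(group_sizes)
  if (is.null(groups) || !all(groups %in% c("HC", "SCD", "MCI")))
    stop("group_sizes must be named with HC/SCD/MCI")
  if (any(group_sizes < 2)) stop("each simulated group needs size >= 2")
  for (v in list(age_mean, age_sd, edu_mean, edu_sd, prop_female))
    if (!all(groups %in% names(v)))
      stop("per-group parameter vectors must cover all simulated groups")
  if (any(age_sd[groups] <= 0) || any(edu_sd[groups] <= 0))
    stop("spreads must be > 0")
  if (!all(paths$id %in% registry$id))
    stop("paths table names subtasks absent from the registry")
  if (any(paths$sigma <= 0)) stop("residual sigma must be > 0")
  structure(list(group_sizes = group_sizes, age_mean = age_mean,
                 age_sd = age_sd, edu_mean = edu_mean, edu_sd = edu_sd,
                 paths = paths, prop_female = prop_female,
                 score_noise_family = score_noise_family,
                 seed = as.integer(seed), registry = registry),
            class = "cohort_config")
}

#' Severity ordering of the diagnostic groups
#'
#' HC < SCD < MCI; used for severity coding in the generator and for the
#' 0/1 diagnosis dummy (better group 0, worse group 1) within a pair.
#' @param group Character vector of group labels.
#' @return Integer severity ranks (HC 0, SCD 1, MCI 2).
#' @export
group_severity <- function(group) {
  sev <- c(HC = 0L, SCD = 1L, MCI = 2L)[group]
  if (anyNA(sev)) stop("unknown diagnostic group label")
  unname(sev)
}

#' Generate a synthetic cohort
#'
#' Draws demographics per group and sub-scores from the linear path model
#' `score = intercept + c_direct * severity + b_age * (age - 65) +
#'  b_edu * (education - 14) + N(0, sigma)`. Bounded scores are clipped to
#' their registry bounds under the default `truncated_gaussian` family; the
#' number of clipped values is recorded in `attr(cohort, "n_clipped")`.
#'
#' @param config A [cohort_config()].
#' @return Data frame of class `r4alz_cohort`: columns `id`, `group`, `age`,
#'   `education`, `gender`, then one column per subtask in `config$paths`.
#'   Attributes: `provenance` (`"synthetic"`), `seed`, `n_clipped`.
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 7))
#' table(coh$group)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  set.seed(config$seed)
  groups <- names(config$group_sizes)
  group <- rep(groups, times = config$group_sizes)
  n <- length(group)
  age <- stats::rnorm(n, config$age_mean[group], config$age_sd[group])
  edu <- pmax(0, stats::rnorm(n, config$edu_mean[group], config$edu_sd[group]))
  gender <- ifelse(stats::runif(n) < config$prop_female[group], "F", "M")
  sev <- group_severity(group)
  coh <- data.frame(
    id = sprintf("P%03d", seq_len(n)),
    group = group, age = age, education = edu, gender = gender,
    stringsAsFactors = FALSE
  )
  n_clipped <- 0L
  for (k in seq_len(nrow(config$paths))) {
    p <- config$paths[k, ]
    s <- p$intercept + p$c_direct * sev + p$b_age * (age - 65) +
      p$b_edu * (edu - 14) + stats::rnorm(n, 0, p$sigma)
    if (config$score_noise_family == "truncated_gaussian") {
      spec <- subtask_spec(p$id, config$registry)
      lo <- spec$min_score
      hi <- spec$max_score
      if (!is.na(lo)) { n_clipped <- n_clipped + sum(s < lo); s <- pmax(s, lo) }
      if (!is.na(hi)) { n_clipped <- n_clipped + sum(s > hi); s <- pmin(s, hi) }
    }
    coh[[p$id]] <- s
  }
  structure(coh, provenance = "synthetic", seed = config$seed,
            n_clipped = n_clipped,
            class = c("r4alz_cohort", "data.frame"))
}

#' Read / write a cohort as delimited text
#'
#' One row per participant, columns `id, group, age, education, gender`
#' followed by the subtask scores; missing scores are empty fields.
#'
#' @param cohort Cohort data frame.
#' @param path CSV file path.
#' @return `read_cohort()` returns an `r4alz_cohort` with
#'   `provenance = "file"`; `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  coh <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group", "age", "education", "gender")
  if (!all(need %in% names(coh)))
    stop("cohort file must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(coh$id)) stop("participant ids must be unique")
  group_severity(coh$group)  # validates labels
  structure(coh, provenance = "file",
            class = c("r4alz_cohort", "data.frame"))
}

#' Closed-form AUC of two independent normal distributions
#'
#' The probability that a draw from the second (positive) group exceeds a
#' draw from the first: `pnorm((mu_b - mu_a) / sqrt(sd_a^2 + sd_b^2))`.
#' Used as the analytic oracle in recovery tests of the empirical ROC stage.
#'
#' @param mu_a,sd_a Mean and SD of the negative group.
#' @param mu_b,sd_b Mean and SD of the positive group.
#' @return AUC in `[0, 1]`.
#' @examples
#' binormal_auc(0, 1, 1, 1)  # pnorm(1 / sqrt(2)) ~ 0.7602
#' @export
binormal_auc <- function(mu_a, sd_a, mu_b, sd_b) {
  if (sd_a <= 0 || sd_b <= 0) stop("spreads must be > 0")
  stats::pnorm((mu_b - mu_a) / sqrt(sd_a^2 + sd_b^2))
}
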