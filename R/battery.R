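#' The R4Alz-R battery registry
#'
#' The battery comprises 14 separate sub-scores: three working-memory
#' capacity/updating subtask totals (WMCUT S1-S3), attentional control (ACT),
#' inhibition and task/rule switching (ICT-RST subtasks 1 & 2 total, switch
#' errors, failed sets), cognitive flexibility (CFT), the three error-scored
#' conditions of the second cognitive-flexibility task (CFT2 A-C, 8 sets each
#' so at most 8 errors), a visual fluency condition (VFT, at most 24 correct
#' orderings of 4 pads), and the two episodic-memory window-recognition
#' conditions (EMT-W A/B, 15 windows so at most 15 errors).
#'
#' Each entry records the score `kind` (`error_count`, `correct_count` or
#' `performance_score`), bounds where the task defines them (`NA` for the
#' baseline tasks, whose internal scoring is treated as an opaque numeric),
#' and the `orientation` used before normalization: `higher_worse` exactly
#' for error counts, `higher_better` otherwise.
#'
#' @return A data frame of class `battery_registry` with columns
#'   `id`, `label`, `kind`, `min_score`, `max_score`, `orientation`,
#'   one row per sub-score, in the battery's canonical order.
#' @examples
#' reg <- default_battery()
#' nrow(reg)              # 14
#' reg[reg$id == "VFT", ]
#' @export
default_battery <- function() {
  reg <- data.frame(
    id = c("WMCUT_S1", "WMCUT_S2", "WMCUT_S3", "ACT",
           "ICT_RST_12", "ICT_RST_SE", "ICT_RST_FS", "CFT",
           "CFT2_A", "CFT2_B", "CFT2_C", "VFT", "EMTW_A", "EMTW_B"),
    label = c(
      "Working Memory Capacity & Updating Task, Subtask 1 (short-term store)",
      "Working Memory Capacity & Updating Task, Subtask 2 (central executive)",
      "Working Memory Capacity & Updating Task, Subtask 3 (updating/episodic buffer)",
      "Attentional Control Task",
      "Inhibitory Control & Task/Rule Switching Task, Subtasks 1 & 2",
      "Inhibitory Control & Task/Rule Switching Task, switch errors",
      "Inhibitory Control & Task/Rule Switching Task, failed sets",
      "Cognitive Flexibility Task",
      "Cognitive Flexibility Task 2, Condition A (errors over 8 sets)",
      "Cognitive Flexibility Task 2, Condition B (errors over 8 sets)",
      "Cognitive Flexibility Task 2, Condition C (errors over 8 sets)",
      "Visual Fluency Task (distinct orderings of 4 pads in 60 s)",
      "Episodic Memory Task - Windows, Condition A (errors over 15 windows)",
      "Episodic Memory Task - Windows, Condition B (errors over 15 windows)"),
    kind = c("performance_score", "performance_score", "performance_score",
             "error_count", "error_count", "error_count",
             "error_count", "error_count",
             "error_count", "error_count", "error_count",
             "correct_count", "error_count", "error_count"),
    min_score = c(NA, NA, NA, NA, NA, 0, 0, NA, 0, 0, 0, 0, 0, 0),
    max_score = c(NA, NA, NA, NA, NA, NA, NA, NA, 8, 8, 8, 24, 15, 15),
    stringsAsFactors = FALSE
  )
  # Baseline-task kinds follow the sign of the diagnosis effect on each
  # score: ACT / ICT-RST / CFT totals are error- or time-like (worsen, i.e.
  # rise, with impairment; no stated cap), WMCUT accuracy-like totals and
  # VFT correct counts fall with impairment.
  reg$orientation <- ifelse(reg$kind == "error_count", "higher_worse",
                            "higher_better")
  class(reg) <- c("battery_registry", "data.frame")
  validate_battery(reg)
  reg
}

#' @keywords internal
validate_battery <- function(reg) {
  stopifnot(is.data.frame(reg),
            all(c("id", "label", "kind", "min_score", "max_score",
                  "orientation") %in% names(reg)))
  if (anyDuplicated(reg$id)) stop("duplicate subtask ids in registry")
  bounded <- !is.na(reg$min_score) & !is.na(reg$max_score)
  if (any(reg$min_score[bounded] >= reg$max_score[bounded]))
    stop("bounded specs must satisfy min_score < max_score")
  bad <- (reg$kind == "error_count") != (reg$orientation == "higher_worse")
  if (any(bad)) stop("orientation inconsistent with score kind: ",
                     paste(reg$id[bad], collapse = ", "))
  invisible(reg)
}

#' Look up one subtask spec
#'
#' @param id Canonical subtask identifier, e.g. `"EMTW_A"`.
#' @param registry A battery registry, by default [default_battery()].
#' @return A one-row data frame (the registry row).
#' @export
subtask_spec <- function(id, registry = default_battery()) {
  i <- match(id, registry$id)
  if (is.na(i)) stop("unknown subtask id: ", id)
  registry[i, , drop = FALSE]
}

#' Read / write a battery registry as JSON
#'
#' The registry round-trips through a plain JSON array of objects with fields
#' `id`, `label`, `kind`, `min_score`, `max_score`, `orientation`. A copy of
#' the default registry ships in `inst/extdata/battery.json`.
#'
#' @param path File path.
#' @param registry A battery registry data frame.
#' @return `read_battery()` returns a validated `battery_registry`;
#'   `write_battery()` returns `path` invisibly.
#' @export
read_battery <- function(path) {
  reg <- jsonlite::fromJSON(path)
  reg$min_score <- as.numeric(reg$min_score)
  reg$max_score <- as.numeric(reg$max_score)
  class(reg) <- c("battery_registry", "data.frame")
  validate_battery(reg)
  reg
}

#' @rdname read_battery
#' @export
write_battery <- function(registry, path) {
  validate_battery(registry)
  jsonlite::write_json(as.data.frame(registry), path, pretty = TRUE,
                       na = "null", digits = NA)
  invisible(path)
}

#' Enumerate pad orderings for the visual fluency task
#'
#' The task asks the examinee to deactivate all pads in as many distinct
#' orders as possible; with 4 pads there are 24 achievable orderings, which
#' is the task's score ceiling. Enumeration is capped at 8 pads.
#'
#' @param n_pads Number of pads, an integer in 1..8.
#' @return An integer matrix with `factorial(n_pads)` rows, each row one
#'   permutation of `1:n_pads`, in lexicographic order.
#' @examples
#' enumerate_pad_orderings(2)   # rbind(c(1, 2), c(2, 1))
#' nrow(enumerate_pad_orderings(4))  # 24
#' @export
enumerate_pad_orderings <- function(n_pads) {
  if (length(n_pads) != 1L || is.na(n_pads) || n_pads != as.integer(n_pads) ||
      n_pads < 1 || n_pads > 8)
    stop("n_pads must be a single integer in 1..8")
  n_pads <- as.integer(n_pads)
  if (n_pads == 1L) return(matrix(1L, 1L, 1L))
  p <- pracma::perms(seq_len(n_pads))
  storage.mode(p) <- "integer"
  p[do.call(order, as.data.frame(p)), , drop = FALSE]
}

#' Score the window-recognition (episodic memory) responses
#'
#' One response per presented window; the score is the number of incorrect
#' recognitions, at most `n_items` (15 windows in the battery).
#'
#' @param n_items Number of presented items.
#' @param responses Vector of length `n_items`: `"correct"`/`"incorrect"`,
#'   or a logical vector with `TRUE` = correct.
#' @return Integer error count in `[0, n_items]`.
#' @export
score_recognition_errors <- function(n_items, responses) {
  ok <- as_correct(responses, c("correct", "incorrect"))
  if (length(ok) != n_items)
    stop("expected ", n_items, " responses, got ", length(ok))
  sum(!ok)
}

#' Score erroneous sets in the cognitive-flexibility conditions
#'
#' Each CFT2 condition comprises `n_sets` sets (8 in the battery) and is
#' rated by the number of erroneous sets.
#'
#' @param n_sets Number of sets.
#' @param set_outcomes Vector of length `n_sets`: `"clean"`/`"erroneous"`,
#'   or a logical vector with `TRUE` = clean.
#' @return Integer error count in `[0, n_sets]`.
#' @export
score_set_errors <- function(n_sets, set_outcomes) {
  ok <- as_correct(set_outcomes, c("clean", "erroneous"))
  if (length(ok) != n_sets)
    stop("expected ", n_sets, " set outcomes, got ", length(ok))
  sum(!ok)
}

#' @keywords internal
as_correct <- function(x, levels) {
  if (is.logical(x)) return(x)
  if (!all(x %in% levels))
    stop("responses must be one of: ", paste(levels, collapse = ", "))
  x == levels[1L]
}

#' Orient a raw score so that higher means cognitively better
#'
#' Error-like (`higher_worse`) scores are reflected before normalization so
#' that, after min-max scaling, values near 1 belong to the better-performing
#' group for every subtask. Bounded scores are reflected onto their own range
#' (`max_score - raw`); unbounded `higher_worse` scores are negated. Min-max
#' normalization is affine-invariant, so reflection versus negation does not
#' change any downstream composite; reflection keeps intermediate values on
#' the documented scale.
#'
#' @param spec A one-row registry entry (see [subtask_spec()]) or a subtask id.
#' @param raw Numeric score(s); must lie within the spec's bounds if bounded.
#' @param registry Registry used when `spec` is given as an id.
#' @return Oriented numeric score(s), same length as `raw`.
#' @examples
#' orient_score("EMTW_A", 0)   # 15: error-free performance tops the range
#' orient_score("VFT", 24)     # 24: identity for higher-is-better scores
#' @export
orient_score <- function(spec, raw, registry = default_battery()) {
  if (is.character(spec)) spec <- subtask_spec(spec, registry)
  lo <- spec$min_score
  hi <- spec$max_score
  keep <- is.na(raw)
  if (!is.na(lo) && any(raw[!keep] < lo)) stop(spec$id, ": score below ", lo)
  if (!is.na(hi) && any(raw[!keep] > hi)) stop(spec$id, ": score above ", hi)
  if (spec$orientation == "higher_better") return(raw)
  if (!is.na(hi)) hi - raw else -raw
}
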