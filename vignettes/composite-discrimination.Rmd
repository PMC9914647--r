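---
title: "Composite diagnostic scores for the R4Alz-R battery: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite diagnostic scores for the R4Alz-R battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(r4alzr)
```

## The problem

Subjective cognitive decline (SCD) — self-reported worsening without
objective deficits — precedes mild cognitive impairment (MCI) in the course
of neurodegeneration, and separating SCD from both healthy cognition (HC)
and MCI is hard for brief screening instruments. The R4Alz-R battery
attacks this with 14 sub-scores that emphasize cognitive control (updating,
inhibition, switching, flexibility) and episodic memory. The package
implements the analysis that converts those sub-scores into one diagnostic
score per group pair with a Youden-optimal cutoff, and a synthetic cohort
generator that makes the whole chain reproducible without participant
data.

## The battery model

`default_battery()` records, for each sub-score, its kind, bounds and
orientation. The three digitally administered task families have hard
score ceilings tied to their structure: the second cognitive-flexibility
task's conditions A–C are rated by erroneous sets out of 8; the visual
fluency condition counts distinct orderings of 4 pads (at most
4! = 24, see `enumerate_pad_orderings()`); the window-recognition episodic
memory conditions count errors out of 15 presented windows. The baseline
tasks' internal scoring is treated as an opaque numeric: only the
orientation matters downstream, and it is taken from the direction in
which impairment moves each score (error/time-like totals rise, accuracy
and fluency totals fall).

Orientation (`orient_score()`) reflects `higher_worse` scores before
normalization — `max − raw` for bounded scores, negation for unbounded
ones. Min–max normalization is affine-invariant, so reflection versus
negation cannot change any composite; reflection merely keeps intermediate
values on the documented range, which makes the transformation auditable:
the normalized reflected score equals one minus the normalized raw score.

## The mediation stage

For a pair of groups, each sub-score is regressed in the parallel
two-mediator layout: `age ~ diagnosis` (a₁), `education ~ diagnosis` (a₂),
`score ~ diagnosis + age + education` (c′, b₁, b₂), with diagnosis coded 0
for the cognitively better group and 1 for the worse (HC < SCD < MCI).
This coding is what makes error-like outcomes carry positive direct
effects. Estimation is ordinary least squares per path; the direct
effect's inference uses the asymptotic z, while each indirect effect
(a·b product) gets a percentile interval over 1000 nonparametric bootstrap
resamples and a two-sided normal p based on the bootstrap standard
deviation. Both the percentile CI and the bootstrap-z p are computed; the
z-based p is what the selection rule consumes. Resampling is over the
pooled pair by default, with stratified resampling available — with two
groups of 20–31 the unstratified scheme occasionally draws a single-group
resample, which is redrawn.

In this linear system the decomposition *total = c′ + a₁b₁ + a₂b₂* is an
algebraic identity; the tests assert it to 1e−8 on every fit, which guards
the implementation against silent design-matrix errors.

Selection (`select_subtasks()`) keeps sub-scores with a significant direct
effect and **no** significant indirect effect at the same per-test α. The
default α is 0.004 — the Bonferroni level 0.05/13 rounded to three
decimals (`bonferroni_alpha()`); with all 14 outcomes tested the rounded
level is the same. The rule "both indirect paths non-significant" is a
formalization choice: the alternative (any-indirect) is not offered because
a sub-score with even one demographic pathway re-introduces the bias the
selection exists to remove. An empty selection is a warning-carrying
report, not an error, since it is a legitimate scientific outcome.

## Normalization, weights and the eight formulas

Weights and normalization are computed on the pooled two-group subsample of
the pair under analysis, not the full cohort: cutoffs are pair-specific,
and pooling a third group would shift every min, max, σ and AUC. σ is the
sample standard deviation (n − 1) of the normalized column. The
per-variable AUC uses the worse group as positive class on oriented scores
and is reported folded above 0.5 (`max(AUC, 1 − AUC)`, polarity retained in
the result) so the weight always rewards discrimination regardless of
direction conventions.

The eight composites (`compute_composites()`) combine the normalized
scores: the plain sum; the squared sum (squaring shrinks mid-range values —
0.5² = 0.25 — much more than near-ceiling values — 0.9² = 0.81 — widening
the gap between groups); AUC- and AUC²-scaled squared sums (boosting the
individually discriminative variables); and the same four divided by σᵢ
(boosting variables whose values cluster near the ends of [0, 1], which is
what a well-separating variable looks like after min–max scaling). All
weights are positive, so every composite is monotone in every normalized
score.

## ROC analysis and cutoffs

`auc_mann_whitney()` computes the empirical AUC as the normalized
Mann–Whitney U via midranks (ties ½) with the Hanley–McNeil standard
error. `youden_cutoff()` scans every achievable threshold — midpoints
between adjacent distinct scores plus ∓∞ sentinels — and maximizes
J = sensitivity + specificity − 1. Ties in J are broken toward higher
sensitivity (screening preference: a missed impaired participant costs
more than a false alarm), then the lower cutoff. Confidence intervals are
class-stratified percentile bootstrap (2000 resamples by default); the
p-value against AUC = 0.5 is the tie-corrected normal approximation to the
U statistic. The CI and p-value methods are the package's own choices —
conventional reporting only prints "95% CI" and "< 0.001" without naming a
method — and are therefore configurable at the call sites.

Composites are higher-is-better after orientation, so their ROC direction
is `positive_low`: a participant is called impaired when the composite
falls below the cutoff. Quality labels follow the usual AUC banding
applied to the value rounded to two decimals: 1.0 perfect, 0.90–0.99
excellent, 0.80–0.89 good, 0.70–0.79 fair, 0.51–0.69 poor; below 0.51 the
package reports `non_discriminative` rather than forcing the lowest named
band.

`pick_best_formula()` maximizes J with AUC and then canonical-order
tie-breaks. The "best sensitivity/specificity combination" is not uniquely
defined; J is the standard scalarization, and the full eight-row
classification table is always emitted so users can apply a different
criterion.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions the analysis assumes:
group sizes 20 HC / 29 SCD / 31 MCI; ages drawn per group with means
61.60 / 61.17 / 68.67 and SDs 6.58 / 7.00 / 8.43 years; education
16.30 / 13.31 / 13.45 with SDs 3.04 / 4.20 / 4.31 years; female
proportions 14/20, 20/29, 24/31. Sub-scores follow
`intercept + c_direct·severity + b_age·(age − 65) + b_edu·(edu − 14) + N(0, σ)`
with severity 0/1/2 for HC/SCD/MCI, so group differences in the mediators
are themselves the diagnosis→mediator paths of any pair. The default path
coefficients (`default_path_table()`) were chosen once to give moderate
direct effects — about one residual SD between the extreme groups on the
discriminating subtasks (e.g. the inhibition/switching total: 4.05 per
severity step against a residual SD of 5.2) — with weak demographic paths
(|b_age| = 2% and |b_edu| = 3% of σ per year) so that, as in real use of
this battery, the demographic pathways exist but rarely reach the 0.004
level at these sample sizes.

Bounded scores are clipped to their registry bounds
(`truncated_gaussian`, the default), with the clip count recorded on the
cohort; under the defaults clipping is rare (about one value per cohort).
The `gaussian` family skips clipping and is used for the analytic AUC
recovery checks. What the generator does **not** emulate: discreteness of
real error counts, inter-task correlation beyond the shared mediators,
floor/ceiling pile-ups, or practice and order effects. Passing tests
therefore demonstrate that the pipeline's machinery is correct and
well-calibrated under its stated model, not that the battery itself
achieves any particular accuracy in the clinic.

`binormal_auc()` supplies the closed-form AUC of two normals,
Φ(Δ/√(σ₁² + σ₂²)), as an independent oracle: the empirical AUC of an
unbounded generated score converges to it (checked at 2000 per group,
tolerance 0.02 over five parameter settings). Note severity coding makes
`c_direct` a per-step effect: an HC/MCI contrast realizes twice it, which
is why the recovery tests use one-step pairs.

## Numerical and degenerate-input choices

* Min–max with zero range raises a typed `degenerate_column` condition;
  the pipeline drops such columns with a warning instead of failing,
  because a constant column carries no pair information.
* Bootstrap resamples that lose a class or a mediator's variance are
  redrawn; with stratification this cannot occur for the class.
* Youden threshold ties are resolved deterministically (higher
  sensitivity, then lower cutoff) so reports are bit-reproducible.
* All randomness flows from explicit integer seeds; per-outcome and
  per-formula seeds are derived from the master seed by fixed offsets, so
  `run_all()` twice with one seed writes byte-identical bundles.

## Problem sizes used by the test suite

The suite keeps its checks at sizes where the asserted tolerances are
meaningful at interactive runtimes: exhaustive ROC oracles on all label
assignments of tied score vectors up to length 7 plus 1000 random
instances (n ≤ 12); mediation recovery on 200 replicate cohorts of 500 per
group; type-I calibration on 500 null cohorts of 50 per group; AUC
recovery at 2000 per group; and the weighted-versus-plain-sum sweep on 120
cohorts at the 20/29/31 design. The sweep runs the composite/ROC stage on
a fixed five-subtask selection, since the best-formula comparison is
entirely downstream of selection.

## Known limitations

* The mediation stage is the linear OLS path model; it will not reproduce
  latent-variable SEM estimates beyond the linear case, and moderated or
  multi-category mediation is out of scope.
* Group labels are fixed to the HC/SCD/MCI ordering; three-way
  classification is intentionally absent — the analysis is pairwise by
  design.
* Min–max weights are sample quantities: cutoffs transfer to new samples
  only after renormalizing with the original min/max/σ/AUC snapshot,
  which `run_pair()` stores in its report for exactly that purpose.
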