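---
title: "Multi-grader DR concordance: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-grader DR concordance: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drconcord)
```

## The problem

Diabetic retinopathy (DR) screening programs grade fundus photographs on the
International Clinical Diabetic Retinopathy (ICDR) severity scale. Human
grading is subjective: even retina specialists disagree substantially on
individual eyes, and automated graders add a fourth opinion on a different
scale and at a different granularity (one grade per patient instead of per
eye). Quantifying that disagreement — who agrees with whom, how often, and
how much better than chance — is the core of any grader-variability study.

`drconcord` implements this analysis as a reusable, fully tested pipeline:
from raw per-eye grades to consensus grades, agreement taxonomies, Cohen's
kappa statistics, and a referable-DR screening analysis, together with a
synthetic data generator whose exact expectations make every stage
verifiable.

## Scales and encodings

Grades are 0-based integers:

| code | 5-point (per eye) | 4-point (per patient) |
|------|-------------------|-----------------------|
| 0 | no DR | no DR |
| 1 | mild NPDR | mild NPDR |
| 2 | moderate NPDR | moderate NPDR |
| 3 | severe NPDR | sight-threatening DR |
| 4 | proliferative DR | — |

The 4-point scale is the 5-point scale with the two most severe levels
merged (`compress_5_to_4()`), matching the output granularity of
patient-level automated graders. An *ungradable* decision — a rater judging
image quality insufficient — is encoded `NA` (the literal token `NA` in
CSV). It is a first-class outcome, distinct from a *missing* assessment (no
row at all): the exclusion rules key on the former, the
completeness/malformedness checks on the latter.

Three deterministic transforms connect the representations:

* `compress_5_to_4()` — monotone scale compression, `4 -> 3`, identity below;
* `patient_grade()` — worse-eye maximum: the patient-level grade for one
  grader is the maximum of that grader's gradable eye grades, because the
  worse eye drives referral;
* `binarize_rdr()` — the referable-DR cutoff: grade `>= 2` (moderate DR and
  above) is referable.

Because all three maps are monotone they commute: compressing then taking
the worse eye equals taking the worse eye then compressing, and likewise for
binarization. The test suite asserts this by exhaustive enumeration over all
grade pairs, so downstream code may pick whichever order is convenient.

## Consensus and adjudication

Each eye is graded by three ophthalmologists. The agreement pattern of an
eye is the partition of the three grades: `3:0` (unanimous), `2:1`
(majority), `1:1:1` (fully discordant). Unanimous and majority eyes resolve
to the modal grade. Fully discordant eyes cannot be resolved numerically: a
human adjudication panel must decide, so the pipeline emits a worklist
(`adjudication_worklist()`) and refuses to continue
(`drc_adjudication_required`) rather than guessing.

Adjudication entries are an *input* (a CSV of eye-level final grades), never
a computation. One deliberate rule: **an explicit adjudication entry always
overrides the modal grade**, even for an eye that had a 2:1 majority. Panels
reviewing a patient often re-grade both eyes, and the recorded panel
decision should win over arithmetic. This is the only path by which a final
grade can lie outside the three graders' multiset.

On the patient level the automated grader joins as a fourth rater and the
partition refines by AI membership into seven classes
(`classify_agreement_4()`): `4:0`, `3:1` with the AI inside or outside the
majority, `2:2`, `2:1:1` with the AI inside or outside the pair, and
`1:1:1:1`. The classification is invariant under permutation of the human
positions but *not* under swapping the AI with a human — that asymmetry is
the point of the refinement and is covered by a directed test plus a
brute-force equivalence check over every grade combination and AI position.

## Quality exclusion

A patient is analyzable only if no human flagged any eye ungradable and the
AI produced a grade. Every excluded patient is counted exactly once, in a
fixed precedence order chosen to make flow diagrams reproducible:
structurally incomplete records, then patients no rater could grade, then
any human quality flag, then AI-only failures. The precedence is a
bookkeeping convention (the categories overlap), not a clinical statement;
changing the order changes which mutually exclusive box a doubly excluded
patient lands in, never the analyzable set.

Per-image counts weight each eye's agreement class by that eye's image
count — the only attribution consistent with one grade per eye.

## Kappa conventions

`cohen_kappa()` computes `(p_o - p_e) / (1 - p_e)` from a contingency table
whose dimension is fixed by the scale (zero rows/columns retained), so
values are comparable across rater pairs. The headline statistics are
*unweighted* kappas on the 5-point per-eye scale: per grader against the
adjudicated final grades, and pairwise between graders with per-grader
means. Linear and quadratic weightings (`1 - d` and `1 - d^2` in normalized
ordinal distance) are available for sensitivity analyses but are not used in
the default report. Degenerate edge: if both raters are constant and
identical, `p_e = 1` and kappa is defined as 1.

The referable-DR post hoc analysis deliberately uses the *original* grades,
not the adjudicated ones: on a binary scale three raters always have a
majority (full discordance is impossible by pigeonhole — also a test), so
adjudication is unnecessary and including it would mix two different
reference standards.

Percentages in report tables are rounded half-up to two decimals; printed
tables elsewhere sometimes truncate instead, so regenerated values can
differ in the last digit from their printed counterparts (e.g. 96.43 vs a
truncated 96.42). The package always recomputes, never copies.

## The synthetic grader world

`simulate_dataset()` draws, per patient:

1. a true 5-point severity for the right eye from `prevalence`, and for the
   left eye a copy of the right with probability `inter_eye_concordance`,
   else a fresh draw (a copy mixture keeps each eye's marginal distribution
   equal to the prevalence while reproducing the strong left/right symmetry
   real screening data show);
2. each grader's assigned grade from that grader's 5×5 row-stochastic
   confusion matrix, conditionally independent given the truth;
3. independent per-grader-per-eye quality failures (`quality_fail`);
4. a patient-level AI grade from a 4×4 confusion matrix applied to the
   compressed true patient grade, with its own failure probability;
5. an image count per eye, uniform on `images_per_eye`;
6. adjudication entries for every eye, equal to the true grade
   (`adjudication_policy = "truth"`) or to the grader median
   (`"grader_median"`).

A master seed derives independent substreams (truth, each grader, quality,
AI, image counts), so adding a grader does not perturb existing streams and
fixed-seed output is byte-identical across runs.

Conditional independence given the truth is the modelling assumption that
makes exact oracles possible: `analytic_kappa()` builds the exact joint
`P(a = i, b = j) = sum_t pi_t A[t, i] B[t, j]` and returns its kappa, and
`expected_agreement_frequencies()` enumerates all `5^4` truth-by-grader
outcomes exactly. Real graders looking at the *same* images have correlated
errors (shared artifacts, shared ambiguous lesions), which this model does
not emulate; passing parameter-recovery tests therefore validates the
pipeline's arithmetic, not the realism of any particular error structure.
The AI is modelled at patient level directly, matching its observed output
granularity, not its internal per-image pipeline.

The default configuration is a plausibility preset for a mostly healthy
screening population — prevalence `(0.78, 0.12, 0.07, 0.02, 0.01)`, grader
accuracies 0.75/0.92/0.82 with geometrically decaying adjacent-grade errors,
~3% quality failures per grader-eye, 10% AI failures, 2–3 images per eye. It
is labelled what it is: plausible, not fitted. Grader error structure is an
*output* of concordance studies, not an input anyone publishes.

## Problem sizes and numerical choices

Parameter-recovery tests simulate 20,000 patients (40,000 eyes), which puts
Monte-Carlo standard errors for kappa around 0.004 and makes a
3-standard-error band a sharp test; the remaining unit tests use 50–300
patients and run in seconds. Exhaustive enumerations (grade-pair
commutation, 3-rater permutation invariance over `5^3` triples, the 4-rater
oracle over `4^4` combinations × 4 AI positions) are preferred over sampled
property tests wherever the state space is this small.

Ties in the modal grade cannot occur for three graders (a `2:1` majority is
unique); the generic `G`-grader consensus path requires a strict majority
and sends everything else to adjudication. The grader-median adjudication
policy rounds half-grades half-up to stay on the integer scale.

## Known limitations

* Correlated grader errors (shared-image effects) are not modelled; see
  above.
* No confidence intervals or significance tests for kappa, and no
  multi-rater Fleiss kappa — the report mirrors a pairwise/vs-final design.
* The 3-rater taxonomy, 4-rater taxonomy and referable-DR analysis require
  exactly three human graders; with other panel sizes the pipeline still
  produces consensus, kappa and distribution tables.
* Intra-grader (test–retest) variability and image-level grading are out of
  scope; the unit of grading is the eye, aggregated to the patient.
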