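# drconcord

Concordance analysis for multi-grader diabetic retinopathy (DR) screening.

## What it is for

In fundus-photography DR screening, several ophthalmologists grade each eye
on the 5-level ICDR severity scale (0 = no DR … 4 = proliferative DR), and
an automated grader adds one 4-level grade per patient (the top level,
"sight-threatening DR", merges severe non-proliferative and proliferative
disease). The scientific questions are: how often do the raters agree, how
far beyond chance is their agreement, where does an AI grader sit relative
to a human panel, and what does disagreement look like at the decision that
matters for screening — referable DR (moderate or worse) versus not.

`drconcord` is a tested pipeline for exactly this analysis, aimed at
screening-program evaluators and grader-variability researchers:

* **Scales and transforms** — 5-to-4-point compression, worse-eye
  patient-level aggregation, referable-DR binarization; all monotone, all
  proven commuting by exhaustive test.
* **Quality exclusion** — patients with any human "ungradable" flag or an
  AI failure are excluded, with auditable one-category-per-patient flow
  accounting.
* **Consensus** — unanimous (3:0) and majority (2:1) eyes resolve to the
  modal grade; fully discordant (1:1:1) eyes go to an explicit adjudication
  worklist, and adjudication entries always override the arithmetic.
* **Agreement statistics** — 3-rater and 4-rater (humans + AI) agreement
  taxonomies; Cohen's kappa `κ = (p_o − p_e)/(1 − p_e)`, unweighted by
  default, linear/quadratic weights available; per-grader kappa against the
  adjudicated finals and pairwise kappas with per-grader means;
  grade-distribution tables; a post hoc referable-DR analysis on the
  original grades.
* **Synthetic data** — a generator with per-grader 5×5 confusion matrices,
  inter-eye severity correlation, quality-failure and AI models, plus exact
  analytic oracles (`analytic_kappa()`, `expected_agreement_frequencies()`)
  for parameter-recovery testing.

## Worked example

Simulate a 335-patient screening cohort under the default plausibility
preset and analyze it:

```r
library(drconcord)

cfg    <- sim_config(n_patients = 335, seed = 20)
sim    <- simulate_dataset(cfg)
report <- run_analysis(sim$grades, sim$ai, sim$adjudications)
report
```

```
Multi-grader DR concordance report
==================================
Patient selection flow
  total:                 335
  ungradable by all:     0
  human quality flag:    54
  AI-only ungradable:    30
  incomplete records:    0
  analyzed:              251
Eyes analyzed: 502 (1254 images)
Eye-level agreement: 3:0 300 (60%), 2:1 177 (35%), 1:1:1 25 (5%)
Final patient grades (4-point): 0: 183 (72.91%), 1: 37 (14.74%), 2: 25 (9.96%), 3: 6 (2.39%)
Four-rater patient patterns: 4:0 94, 3:1_ai_majority 82, 3:1_ai_odd 17, 2:2 15, 2:1:1_ai_pair 20, 2:1:1_ai_odd 19, 1:1:1:1 4
Cohen's kappa (none weighting)
  vs final grades: grader1 0.55, grader2 0.81, grader3 0.64
  pairwise:        grader1-grader2 0.48, grader1-grader3 0.36, grader2-grader3 0.55
  mean pairwise:   grader1 0.42, grader2 0.51, grader3 0.46
Referable-DR analysis (cutoff: grade >= 2)
  eyes:     502 analyzed, 386 full agreement, 116 majority (2:1)
  patients: 251 analyzed, 163 full agreement, 88 majority (2:1)
  AI on 2:1 patients: with majority 63, against 25
  AI vs unanimous patients: 16 disagreements (11 AI-referable, 5 AI-non-referable)
```

Reading this: 84 of 335 simulated patients were excluded for quality
reasons; of the 502 analyzable eyes, 60% were graded identically by all
three graders and 25 eyes were fully discordant (resolved here by the
simulated adjudication entries). Grader 2 — the most accurate grader in the
preset — tracks the final grades best (κ = 0.81). Collapsed to the
referable/non-referable decision, the AI sides with the human 2:1 majority
in 63 of 88 split patients.

`render_report(report, "out/")` writes one CSV per table, a `bundle.json`
with the whole report and a text summary; re-rendering is byte-identical.
On real data, start from the three CSVs instead:

```r
report <- run_analysis(load_grades("grades.csv"), load_ai("ai.csv"),
                       load_adjudications("adjudications.csv"))
```

If any fully discordant eye lacks an adjudication entry, `run_analysis()`
raises a `drc_adjudication_required` error carrying the worklist; the CLI
(`inst/cli/drconcord.R`, subcommands `simulate`/`analyze`/`report`) writes
it to `worklist.csv` and exits with status 3.

## Documentation

The methods vignette (`vignettes/grading-concordance.Rmd`) describes the
scales and encodings, the consensus and adjudication rules, kappa
conventions, the synthetic generator's model and its deliberate
simplifications, and known limitations.
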