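---
title: "Methods: the composite satisfaction index and its survey pipeline"
author: "postopsat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the composite satisfaction index and its survey pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postopsat)
```

## The problem and the model

Hospitals that survey postoperative patients face two recurring tasks:
condensing heterogeneous patient characteristics into a single comparable
satisfaction measure, and testing whether satisfaction genuinely moved over
years of infrastructure and protocol investment. `postopsat` implements one
concrete answer used in a five-year, eight-surgical-ward hospital programme:
a multiplicative composite index plus a fixed analysis pipeline over the
questionnaire stream.

The index multiplies eight factors — gender, age, environment (urban/rural
residence), postoperative infection, complication, care protocol
(standard vs. personalized/innovative), use of innovative products, and pain
on the 0–10 numeric rating scale:

$$T = f_\text{gender} \cdot f_\text{age} \cdot f_\text{env} \cdot
      f_\text{inf} \cdot f_\text{comp} \cdot f_\text{prot} \cdot
      f_\text{innov} \cdot f_\text{pain}$$

with $f_\text{age} = 1 + 0.1\,(\text{age}/10)$ and
$f_\text{pain} = 1 + 0.1\,\text{pain}$, and the categorical constants listed
in `?factor_weights`. Every factor is a risk-style multiplier on expected
recovery burden, so the scale is *inverse* to satisfaction; the bands are
high ($T \le 1.5$), moderate ($1.5 < T \le 3.0$) and low ($T > 3.0$), with
both boundaries inclusive on the more-satisfied side. The constants came from
internal hospital calibration rather than a fitted model, which is why they
are configuration, not estimates: other sites are expected to retune
`factor_weights()` and keep the machinery.

Two modelling choices in the index deserve flagging. Age enters continuously
(the formula divides age by 10 without truncation, so fractional decades are
honoured). Pain is accepted on 0–10 even though the accompanying text
describes the scale as "1 to 10": the international numeric rating scale
includes 0, the formula is well defined there, and excluding pain-free
patients would be hard to defend.

### Missing algorithm inputs

The source material never states how records with missing inputs were
scored. `score_dataset()` therefore ships two policies: **strict** (default)
skips the record and reports the missing fields, and **neutral** substitutes
the unit factor 1.0 for the missing input. Strict preserves the published
constants exactly; neutral is a transparent, logged fallback for sites with
patchy clinical capture. No model-based imputation is attempted.

## Quality control

Questionnaires with **over 20%** missing in-scope responses are discarded
(`apply_exclusion()`, strict inequality — a record at exactly the threshold
survives). The in-scope fields default to everything except the
administrative `year` and `ward`, and the set is configurable.

One extension to that rule proved unavoidable: for respondents who answered
"no" to the surgery item, the postoperative-care rating and the five clinical
fields are *structurally* blank, not non-response. If they counted as
missing, every non-operated respondent would carry at least 6/12 = 50%
missingness and be discarded — yet roughly a quarter of the published
analysable questionnaires come from non-operated respondents. The default
(`conditional = TRUE`) therefore removes the surgical fields from a
non-operated record's scope; `conditional = FALSE` restores the naive rule.

Logical-inconsistency checking (`consistency_check()`) ships two rules: a
postoperative-care answer without surgery, and clinical surgical fields
answered without surgery. The analysis command drops flagged records by
default (`cmd_analyze(exclude_inconsistent = TRUE)`); range violations are
nulled at parse time with a counted warning.

## The statistical pipeline

`run_pipeline()` reproduces the full published analysis sequence: yearly and
ward-by-year counts; ward mean ages with an across-ward one-way ANOVA;
surgery percentages with a surgery-by-year chi-square; ward-by-year Likert
means for both items with per-ward across-year ANOVAs and a cumulative row;
algorithm scoring; yearly score summaries (mean, SD, median, quartiles);
paired t tests for all $\binom{5}{2} = 10$ year pairs; a Shapiro–Wilk
normality gate followed by Spearman (or Pearson, if both items pass the
gate) correlation between the two items; Cronbach's alpha; and
postoperative-care comparisons by gender, residence and education.

Fixed numerical conventions, chosen once:

* **Paired units.** The published paired-samples table is arithmetically
  consistent only with $n = 6$ paired units per year pair ($df = 5$), but the
  six units are never identified. The pipeline aggregates scores to
  group-by-year means with six groups; the default grouping collapses ward
  labels differing only in a trailing number, which maps the eight wards onto
  exactly six clinical specialties (plastic surgery, general surgery,
  neurosurgery, ENT, orthopedics, urology). Both the group count and the
  rule are configurable, and `paired_t_from_summary()` exists precisely so
  printed rows can be verified independently of this choice. The group-mean
  differences land close to the printed mean differences, but their SDs are
  smaller than the printed ones — whatever the original six units were, they
  were noisier than specialty means; the reconstruction of the printed rows
  from their own summary statistics is exact either way.
* Two-sided p values everywhere; 95% confidence intervals.
* Pearson chi-square without Yates continuity correction by default
  (`correct = TRUE` available); `method = "auto"` in `contingency_test()`
  switches to Fisher's exact test for 2×2 tables with any expected count
  below 5.
* No multiple-testing correction across the ten year pairs by default,
  mirroring the usual presentation of such tables; any `stats::p.adjust()`
  method can be switched on via `pipeline_config(p_adjust = )`.
* Likert items are treated as numeric for means and ANOVA (that is how the
  published tables are built); no ordinal model is offered.
* Quartiles use linear interpolation (quantile type 7). Report rounding:
  means 2 dp, test statistics 3 dp.
* The Spearman p value uses the large-sample t approximation on mid-ranks,
  and the result records that method. Shapiro–Wilk is used solely as the
  Spearman-vs-Pearson gate; above its n = 5000 implementation limit a
  deterministic evenly spaced subsample is tested.
* Degenerate inputs (zero variance of paired differences, zero table
  margins, constant Shapiro input, all-identical ANOVA values) raise typed
  conditions (`postopsat_degenerate`) rather than returning NaN; the
  pipeline catches them and records a skip reason.

## The synthetic cohort generator

No public patient-level data exist for this design, so `default_config()` +
`generate_cohort()` build cohorts whose *marginal* structure matches every
published summary: ward-by-year questionnaire counts (3985 in total),
ward-by-year surgery probabilities, ward-level age means with SD 15.8
truncated to the printed 12–96 range, the gender/residence/education margins,
ward-by-year target means for both Likert items, a pooled rank correlation of
0.51 between the items, and the yearly algorithm-score trajectory
(2.09, 2.16, 1.70, 1.78, 1.50). On top of the 3985 well-formed records, 33
grossly incomplete records are appended (4018 collected), reproducing the
published quality-control arithmetic.

How the targets are reached:

* **Likert items.** Each ward-year cell gets four latent-normal cutpoints
  solved by `calibrate_cutpoints()` so the implied five-category mean equals
  the cell target (root tolerance far below the 0.01 contract). Cell targets
  at or beyond the scale ends (one cell prints a mean of 5.00) are clamped
  into (1, 5) with a warning — a mean of exactly 5 with any response
  variability is infeasible. The two items are thresholded from one bivariate
  normal pair; the latent correlation is calibrated by root-finding on the
  *population* mid-rank Spearman of the pooled ward-year mixture (bivariate
  rectangle probabilities by numerical integration), so the pooled sample
  Spearman is an unbiased estimate of the 0.51 target.
* **Clinical rates.** Infection, complication, pain and protocol/innovation
  adoption are unreported in the source; they are *calibrated, not
  observed*. Infection/complication/pain follow fixed trajectories (slight
  2020 worsening, improvement afterwards), and the per-year adoption
  probability of personalized protocols and innovative products is solved in
  closed form (a quadratic) so that the expected mean score of the scored
  population equals the yearly target, using the exact truncated-normal age
  expectation and the surgery-weighted ward mixture. A consequence worth
  knowing: with the published factor constants, hitting a yearly mean of
  1.50 forces near-universal adoption (≈ 0.94) and low average pain — the
  published trajectory is only reachable in the corner of the parameter
  space where the improvement levers are fully pulled.
* **Missingness.** Field non-response is injected independently per field
  (the Q2 non-response rate is the published 904/2994 ≈ 30.2%; residence and
  education non-response live in their categorical margins). A repair pass
  then guarantees that no *well-formed* record exceeds the 20% exclusion
  threshold: offending records get fields restored in a fixed priority order
  that never touches Q2 (whose non-response rate is a published quantity)
  and only draws values for structurally blank residence/education as a last
  resort. The 33 gross records blank five demographic fields, which exceeds
  the threshold under either missingness scope. Exclusion therefore removes
  *exactly* the gross block — deliberate, since the published counts
  (4018 collected, 3985 analysed) are stated as exact.
* Everything is conditionally independent given ward and year — the simplest
  joint structure consistent with every printed margin. Ages are truncated,
  not re-sampled, and rounded to whole years.

What the generator does **not** emulate, hence what a green test does not
establish: any real joint dependence (age×surgery, ward-specific clinical
rates, informative non-response), the published per-year score *SDs* (the
printed 0.14–0.55 values are not per-patient dispersions under this model;
only the means are calibrated), per-cell ANOVA p-value patterns, and any
causal link between investments and satisfaction. Recovering the configured
parameters shows the pipeline is arithmetically faithful, not that the model
is the true data-generating process.

### Parameter recovery and its tolerances

`recovery_report()` checks each headline parameter against its target within
**three standard errors at the realized n** (floored at 0.01 absolute; the
rank correlation is compared on the Fisher-z scale). The rows are
deliberately coarse — male share, urban share, 8 ward age means, 5 yearly
surgery rates, 10 question-by-year Likert means, the rank correlation, 5
yearly score means (~31 rows): at ward-by-year-cell granularity (~200 rows) a
3-SE-per-row rule would fail somewhere by chance alone in roughly 40% of
runs, which would make the check meaningless. Comparison targets are the
*achievable* values (post-clamp implied cell means, truncated-normal age
means), so every discrepancy is pure sampling error. The default seed
(20240912) was fixed before any output was inspected.

One published pattern is worth a note: the yearly score targets are not
monotone (1.70 in 2021, 1.78 in 2022). The trend test asserts what the
trajectory actually satisfies — the post-2020 years all lie below the
2019–2020 baseline, and 2023 is the minimum, at the high-satisfaction
boundary.

## Configuration and reproducibility

All configuration is JSON (`read_weights()`, `read_synthetic_config()`);
every run of the CLI writes a manifest with the config snapshot, seed,
package version and warning count, and re-running from the manifest
reproduces all non-timestamp outputs. All randomness flows from the single
config seed; the calibration steps are deterministic numerics and consume no
randomness.

## Limitations

* The index is a fixed expert-weighted product; the package deliberately
  offers no alternative (additive, logistic, fitted) forms and no validation
  of the weights against recovery-time outcomes.
* The identity of the six paired units behind the year-pair tests is an
  assumption (specialty grouping), flagged above.
* No survey weighting, mixed-effects or longitudinal modelling; inference is
  the classical test battery the published analysis used.
* The generator's clinical rates are calibration devices; do not read them
  as epidemiology.
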