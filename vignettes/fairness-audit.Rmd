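---
title: "Auditing fairness and generalizability of ICU mortality risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing fairness and generalizability of ICU mortality risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairicu)
```

## The problem

Binary risk-prediction models trained on critical-care EHR data — here, the
canonical task of predicting in-hospital mortality (IHM) from the first 48
hours of an ICU stay — are routinely reported with one or two pooled
discrimination numbers. That practice hides two failure modes that matter
for deployment: a model can transport poorly to a hospital whose population
differs from the development cohort, and it can behave differently for
demographic groups within one cohort. Both problems interact with class
imbalance (IHM rates near 10%), which by itself moves ranking metrics and
cripples minority-class recall.

`fairicu` implements a three-stage audit for such models:

1. **Internal validation** on a held-out partition of the development
   cohort.
2. **External validation** of the same fitted model on an independent
   cohort.
3. **Internal validation after retraining** on the external cohort.

At each stage the same three tasks run: (A) descriptive cohort screening —
demographics, outcome distribution and per-variable missingness; (B)
performance and fairness evaluation — bootstrap discrimination metrics,
calibration assessment, classification parity and per-group
calibration-in-the-large; and (C) assembly into a structured, serializable
report. The predictor is pluggable: any object with a
`predict(object, cohort)` method returning scores in $[0,1]$ can be
audited; the package bundles a transparent logistic baseline and a
synthetic "oracle" predictor for simulation studies.

The clinical datasets this kind of audit targets are access-restricted, so
the package ships a synthetic cohort generator that reproduces the
statistical structure the audit depends on. Every audit component is
therefore exercisable — and tested — at desk scale.

## The synthetic cohort generator

A cohort of $n$ ICU stays is drawn as follows.

**Demographics.** Gender, ethnicity (Asian, Black, Hispanic, White, Other),
insurance (Medicare, Medicaid, Private, Other) and age band (18–29, …, 90+)
are sampled independently at the patient level from configurable marginals.
The shipped `mimic_generator_config()` and `starr_generator_config()` carry
the published patient shares of a large single-center ICU database and a
smaller, more diverse full-EHR cohort, respectively. Independence across
attributes is a deliberate simplification: only marginals are published for
the emulated cohorts, and any correlation structure would be our invention.
A fraction of patients (default 0.15) contributes two stays with shared
demographics but separate admissions, mirroring that several ICU stays may
be collected for one patient.

**Outcome.** The mortality label is Bernoulli with
$\mathrm{logit}\,p_i = \beta_0 + \sum_a \delta_{a}(g_{ia}) + z_i$, where
$\delta_a(\cdot)$ are additive log-odds offsets per demographic level
(shipped values reproduce the published per-group IHM rates) and
$z_i \sim N(0, \sigma^2)$ is a per-stay latent acuity term. The offsets
alone would make risk constant within demographic cells, which is both
unrealistic and useless for studying discrimination; $\sigma$ controls how
much individual-level signal a well-informed model could exploit. The
default $\sigma = 1.8$ was chosen once, by a design calculation, so that
the AUROC of the true risk is ≈ 0.86 — the discrimination level reported
for the strong benchmark LSTM this generator stands in for. The intercept
$\beta_0$ is not set directly in the shipped configs: it is root-found
(enumerating the 200 demographic cells and integrating the acuity term on a
Gaussian grid) so the pooled event rate equals the published totals
(13.23% for the development-like cohort, 10.18% for the external-like one)
in expectation.

**Emitted risk scores.** `emit_predictions()` produces the scores of the
audited "model": the latent true risk perturbed on the log-odds scale by
per-group miscalibration shifts and per-group Gaussian score noise (SDs
from several attributes combine in quadrature), clipped to the open unit
interval. With all shifts and SDs zero the score equals the true risk —
a calibrated-by-construction oracle. This is the package's bias-injection
mechanism: a $-0.5$ log-odds shift for one group creates a known
calibration-fairness defect, and score noise for one group creates a known
classification-parity defect, both of which the audit must recover.

**Observations.** Each of the 17 physiological variables (vital signs, GCS
components, labs, anthropometrics) is completely absent from a stay with
probability $p_{\text{none}}$ and otherwise observed in each of the 48
hour buckets with probability $p_{\text{hour}}$; a present variable always
carries at least one observation, so the share of stays with no data
converges exactly to $p_{\text{none}}$. The shipped values are derived from
the published coverage tables ($p_{\text{hour}}$ chosen to match the mean
covered hours). Values are drawn from fixed plausible per-variable
Gaussians; they exist for missingness accounting and predictor features,
and none of the audit statistics uses them. This two-parameter model
reproduces the "None" and "Average" columns of the published coverage
tables but not their "Full" column — hour-to-hour observation clustering
in real monitoring data is not emulated, and passing tests say nothing
about such autocorrelation.

**Diagnoses.** When enabled, twelve synthetic comorbidity factors
(`F01`–`F12`, weights 1,1,1,1,1,1,2,2,2,3,6,6, two codes each) are drawn
per stay with prevalence tilted by the latent acuity, so comorbidity burden
correlates with outcome risk; diagnosis dates are uniform over the three
years before admission, placing some outside the two-year lookback on
purpose. The code table is synthetic — real ICD mappings are user-supplied
through `charlson_config()`.

**Reproducibility.** One master seed governs a generation; components
(demographics, outcomes, observations, diagnoses, score emission) consume
fixed-offset child seeds, so identical configurations give byte-identical
cohorts and any component can be regenerated independently. Cohorts are
written as three TSV files (stays, observations, diagnoses); the latent
true risk is deliberately excluded from the export schema so file
round-trips cannot leak it.

## Cohort screening

`apply_exclusions()` applies the benchmark eligibility rules: adults only,
a single ICU stay per hospital admission, length of stay strictly greater
than 48 h ("more than 48 hours" is read as a strict inequality, so a stay
at exactly 48.0 h is excluded), and at least one observation inside the
window. Each excluded stay is attributed to the first rule it violates in
the fixed order age → multi-stay → LOS → observations, making the reported
counts unambiguous; predicates are evaluated on the input cohort, so both
stays of a shared admission count under the multi-stay rule. The operation
is idempotent. Because the published exclusion criterion is per admission
while multi-stay *patients* are retained in the published cohort tables,
the stays schema carries an explicit `admission_id`.

`demographics_table()` deduplicates patients by identifier within each
level — a patient whose insurance differs across stays is counted under
each level, since the emulated cohort tables do not resolve this case.
`missingness_profile()` counts, per stay and variable, hour buckets with at
least one observation; `avg_points = 0` exactly when `pct_none = 100`.

## Discrimination metrics and the bootstrap

AUROC uses the Mann–Whitney formulation with ties counted ½. AUPRC is
step-wise average precision (no trapezoidal interpolation): tied scores
form one rank block and every event in the block receives the block-level
precision, which reduces to the textbook estimator on tie-free data. The
baseline AUPRC of an uninformative classifier equals the event rate, which
is what makes the metric informative under imbalance. Threshold metrics
(accuracy, per-class precision and recall at a default threshold of 0.5,
with `score >= threshold` predicting the event) return ratios with empty
denominators as flagged-undefined values, never as silent zeros — the
accuracy-paradox regime, where a model that never predicts the event still
attains accuracy $1-r$, must stay visible.

Confidence intervals are percentile bootstrap: (score, label) pairs are
resampled jointly, $n$-out-of-$n$, $K$ times (default $K = 10{,}000$), and
the $\alpha/2$ and $1-\alpha/2$ empirical quantiles (type-7) are reported.
The resampling unit is the ICU stay, not the patient. Resamples on which a
metric is undefined (single-class draws) are redrawn and the redraw count
is logged; for very small samples an exhaustive mode enumerates all $n^n$
ordered resamples instead. Percentile intervals can in pathological cases
fail to contain the point estimate; the estimate object carries a
`degenerate` flag for that.

## Calibration

Standard decile-based risk grouping collapses under the skew of mortality
scores, so the risk groups come from *exponential quantiles*: interior cut
points are empirical quantiles at the transformed levels
$f(i/10) = (i/10)^{1/5}$, concentrating resolution in the sparse
high-risk tail. The exponent is configurable and should be adapted to the
skew at hand; exponent 1 recovers equal-count groups. Quantiles use the
type-7 convention (the default linear interpolation rule), bins are
half-open with the last bin closed, and duplicate cut points on heavily
tied scores merge bins leftward rather than erroring, preserving the
partition of the sample (merge counts are logged).

Each group is summarized by its mean predicted risk, observed event
proportion, and a 95% Wilson score interval — chosen for its closed form
and small-count behavior near the boundaries. A LOWESS smooth (tricube
kernel, local linear fit over the `span * n` nearest neighbors, span 0.5,
zero robustness iterations) of the raw (score, label) pairs provides
calibration information independent of any grouping; robustness iterations
are disabled because Bernoulli residuals are not outlier-prone in the
robust-regression sense, and the smooth is fitted to raw pairs rather than
bin summaries. For inputs with more than 1000 distinct scores the local
fits are evaluated at 1000 quantile-spaced anchors and linearly
interpolated, which is exact for locally linear signals. Per-class score
histograms (intended for log-scale display) complete the validation-curve
data; everything is exportable as delimited text without a graphics
backend.

The Hosmer–Lemeshow chi-square statistic is deliberately not computed: its
verdict is too sensitive to the grouping choice, and the graphical
machinery above is the intended instrument.

## Fairness assessments

**Classification parity.** Per-group AUROC and AUPRC with within-group
bootstrap intervals are only half the story: group event rates move both
metrics, so raw differences confound model unfairness with class
imbalance. A performance difference is attributed to the model only in two
scenarios: (1) the groups have materially similar event rates (default
tolerance 1.0 percentage point, mirroring how a one-point gap is read as
materially similar in the emulated study), or (2) the event-rate ordering
is the *converse* of the performance ordering — the better-performing
group is the one its event rate should disadvantage. In either scenario a
`parity_violation` verdict additionally requires disjoint 95% intervals
(interval disjointness, not a formal two-sample test, operationalizes
"distinctively worse" since the audit reports interval plots). Otherwise
the finding is `imbalance_confounded` (disjoint intervals, but the rate
gap explains the direction) or `no_material_difference` (overlapping
intervals). Verdicts are invariant under relabeling the pair, and levels
with fewer than two stays or one outcome class are reported as
not-assessable instead of generating spurious numbers.

**Calibration-in-the-large.** Per level, the relative difference
$(\bar{s} - \bar{y})/\bar{y}$ between mean predicted and observed risk is
reported with a percentile bootstrap interval of per-resample relative
differences (within-level resampling; zero-event resamples redrawn). The
sign convention — predicted minus observed over observed — means risk
underestimation is negative. An interval containing zero is reported as
consistent with calibration; levels with no observed events are flagged
rather than divided. The $n$-weighted pooling of group numerators and
denominators reproduces the whole-cohort relative difference exactly.

**Comorbidity–risk curves.** The Charlson comorbidity index here is a
weighted sum over twelve distinct factors observed within a two-year
(730-day) lookback before admission; a factor counts once regardless of
how many codes or dates support it, and unmapped codes are counted and
ignored. Risk-score percentiles are computed on the pooled test cohort —
not within group — so all group curves share an x-axis; per level, the
mean Charlson score in a sliding ±5-percentile window is evaluated on the
grid 1..100, with windows under 10 stays flagged sparse. Higher comorbidity
should accompany higher algorithmic risk independently of demographics;
group-divergent curves indicate risk scores that mean different things for
different groups. The curves are only computed for cohorts carrying
diagnosis data, since an ICU-only database cannot support the lookback.

## The three-stage orchestration

`run_framework()` splits the development cohort 85/15 (seeded), fits the
predictor on the training partition and audits the held-out partition
(stage 1). The external cohort is split 80/20; stage 2 audits the stage-1
model and stage 3 the retrained model on the *same* held-out external
partition, so stage-2 vs stage-3 deltas are free of test-set variation —
a deliberate divergence from the emulated protocol, which scored the whole
external cohort at stage 2; `paper_mode = TRUE` restores that behavior.
Stage reports serialize losslessly (write → read → write is
byte-identical) and export all plot data as TSV; cross-stage deltas carry
CI-overlap indicators. Report payloads are deterministic given seeds,
excluding only the timestamp metadata.

The bundled baseline predictor is a logistic regression on demographics
plus per-variable observation counts. On synthetic cohorts its
discrimination is modest by construction — most outcome signal lives in
the latent acuity term that no feature observes — which is itself a
faithful stand-in for auditing a model whose inputs the auditor does not
control. Simulation studies that need a strong, well-calibrated model
should audit the oracle predictor instead.

## Problem sizes and numerical choices

The shipped defaults are the study conditions: cohort sizes 20,000 and
6,400 stays for the two default configs, $K = 10{,}000$ bootstrap
resamples, 10 risk groups with exponent 1/5, LOWESS span 0.5, threshold
0.5, parity tolerance 1.0 pp, Charlson lookback 730 days. The package's
own test suite and analysis scripts run the same machinery at smaller
sizes chosen as the smallest scales at which the statistical properties
under test are comfortably resolvable: cohorts of 12,000/5,000 stays and
$K = 1{,}000$ in the analysis scripts; recovery experiments with 100
replicates at 20,000–40,000 stays and $K$ = 300–1,000; marginal-recovery
checks at 50,000–100,000 stays. Seeds are fixed throughout; all reported
numbers are recomputed at run time.

## Limitations

Beyond the simplifications already noted (independent demographic
attributes, no inter-variable or temporal correlation of observations,
synthetic Charlson code table), the generator draws labels from the same
logistic family the audit's recovery tests estimate, so those tests
demonstrate internal consistency of the machinery, not robustness to
misspecified real-world risk surfaces. The parity verdict rule inherits
the coarseness of its two scenarios: a true violation accompanied by a
large event-rate gap in the "explaining" direction is deliberately labeled
`imbalance_confounded`, trading sensitivity for attribution validity.
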