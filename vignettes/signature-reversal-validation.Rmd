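---
title: "Signature reversal screening and SCCS validation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature reversal screening and SCCS validation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repscreen)
```

This vignette documents the statistical machinery in `repscreen`, the
choices made where the design was genuinely open, and what the bundled
synthetic data can and cannot tell you about behaviour on real
clinical data.

## The two-stage model

### Stage 1: disease signatures and reversal scoring

A disease is summarised by a gene-expression signature derived from a
table of genetically imputed per-gene differential-expression records
(symbol, association Z-score, two-tailed p). Two selection rules are
implemented:

* **Top-K** (`select_topk()`): the K genes with the largest positive Z
  and the K with the most negative Z, K = 50 by default, giving a
  100-gene signature when both tails are full. Only strictly signed
  genes qualify for a side; if a tail is shallower than K the rule
  takes what is there and warns.
* **FDR** (`select_fdr()`): Benjamini–Hochberg q-values over the whole
  table, retaining genes with q < 0.05 by default.

Genes with Z = 0 are excluded by both rules: the downstream reversal
score needs a direction, and a zero score carries none.

A drug perturbation signature is a gene → differential-expression
mapping. `pearson_match()` scores a drug against a disease signature
with the Pearson correlation over the gene intersection (exact symbol
match after uppercase normalisation; no alias resolution, which keeps
matching deterministic at the cost of dropping renamed genes). The
two-tailed p-value uses the classical t-transform
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom and is only
defined for three or more shared genes; smaller intersections are
flagged rather than scored. A *reverser* satisfies r < 0 with p below
the screening threshold (0.05 by default; the shipped configurations
also support a stricter 0.001 screen for a second disease). Candidate
lists from the two signature rules are merged by union, keeping the
most negative r as representative and recording per-drug provenance.

Weighted correlation is supported through a non-negative per-gene
weight vector (for instance |Z|), normalised internally. The default
is unit weights: the upstream platforms' internal weighting and
moderated-Z concordance statistics are not publicly specified, so the
package ships the plain correlation as its scorer and leaves the
weight hook for sensitivity analysis rather than claiming equivalence
to any particular service.

### Stage 2: the paired mixed model

Validation uses a two-period self-controlled design: each exposed
person is their own control. With per-person baseline and treatment
median biomarker values, the model is

$$\mathrm{biomarkerVal} \sim \beta_0 + \beta_1\,\mathrm{drugExposure}
 + \beta_2\,\mathrm{Age} + \beta_3\,\mathrm{Gender}
 + \beta_4\,\mathrm{Ethnicity} + \beta_5\,\mathrm{Comorbidity}
 + (1 \mid \mathrm{Individual})$$

fitted by REML via `lme4::lmer()`. Gender is coded 1 for female,
Ethnicity 1 for not white; Age and the Elixhauser comorbidity index
are measured at the end of each period and z-normalised across all
rows of the per-drug table (the "normalised" covariates are therefore
within-cohort, which makes coefficients comparable across drugs with
different cohort compositions). Inference on $\beta_1$ is Wald with
normal quantiles: with exactly two observations per cluster,
degrees-of-freedom corrections (Kenward–Roger, Satterthwaite) are out
of scope, and at the cohort sizes the pipeline enforces (n ≥ 20, and
typically hundreds) the normal approximation is adequate — the
acceptance suite checks 95% CI coverage empirically. Reported
p-values are floored at 2.2 × 10⁻¹⁶. If the mixed-model fit fails
outright, the paired-difference estimate (paired t-test) is
substituted and flagged `converged = FALSE` so batch screens stay
total; on balanced tables the covariate-free mixed model and the
paired mean difference agree algebraically, which the test suite
exploits as an independent oracle.

## Cohort construction conventions

All interval arithmetic is in whole days, with a 365-day year — no
calendar-month arithmetic, so results are locale-independent.

* **Index date**: first outpatient exposure to the tested drug.
* **Baseline**: `[index − 365 d, index]`, closed on both ends. A
  measurement on the index date itself is baseline (the period "ends
  on" the index date; the boundary assignment is this package's
  convention).
* **Treatment**: `(index, min(last exposure end, index + 365 d)]`,
  with the first 30 days (induction) excluded from the effective
  period so the drug can reach steady state. Persons whose exposure
  ends within 30 days of the index are ineligible.
* **Missing exposure end dates** are imputed as start + 90 days, a
  conventional days-supply default; it is configurable
  (`end_impute_days`).
* Baselines shorter than 365 days are allowed, down to a single
  pre-index measurement; requiring a minimum baseline length is left
  to the caller.

The exclusion cascade runs in a fixed order — adult age (≥ 18 and
< 90 at index), at least one outpatient biomarker in each period, no
overlapping exposure to a drug approved for the disease (the tested
drug itself never triggers this, so approved drugs can be re-derived
as positive controls), at least two distinct outpatient measurement
dates within a 730-day span (a guard against fragmented records), and
an optional systemic-route-only filter for drugs commonly dispensed
topically. Attrition is recorded after every step; drugs ending below
20 persons are marked untestable rather than fitted, both for privacy
reporting and power.

**Outlier removal** applies the 1.5 × IQR Tukey fences to the
per-person medians, computed separately for the baseline and the
treatment distributions across the cohort, and removes the whole
person when either median falls outside its period's fences. Whether
such trimming should be joint on the pairs or per period, and per
person or per value, is under-determined in the designs this package
follows; per-period fences with person-level removal were chosen as
the strictest variant that keeps the table balanced, and documented
as a package convention rather than a claim of fidelity. Quartiles
use linear interpolation (R's type 7), fixed for determinism;
cohorts below four persons are left untouched. The **Elixhauser
index** defaults to an unweighted category count over an ICD-prefix
map (a weight table, e.g. van Walraven, can be supplied); codes count
from the start of the observation window to the end of the respective
period, so the treatment-period index is never smaller than the
baseline one.

## What the synthetic generator emulates

`gen_ehr()` simulates the statistical structure the validation stage
assumes: per-person random intercepts (SD 10) around a concept mean
(130 mg/dL LDL-C or 130 mmHg SBP), covariate effects entering at the
person-period level, measurement noise (SD 5) around outpatient
visits from a Poisson process, inpatient measurements shifted upward
(which the pipeline must filter), exposure durations of 90–365 days
with 10% missing end dates, and an injected effect δ that switches on
only after the 30-day induction — matching the estimand the model
targets (a `ramp_in` switch stresses induction handling instead).
Planted protocol violations (under-age persons, approved-drug
co-exposure, missing-period measurements) are recorded in a truth
manifest so the attrition cascade can be checked by exact set
equality. The confounding-by-indication stressor co-exposes 30% of a
cohort to an approved drug whose own −20 mg/dL effect contaminates
their treatment measurements; with the approved-drug exclusion
disabled this biases a null drug decisively, and enabling the
exclusion restores nominal coverage — the mechanism the design's
step-3 filter exists to break.

Default scales: 5000-gene DEG tables with 100 causal genes at |Z| ~
N(6, 1) (chosen so FDR selection at q < 0.05 recovers essentially all
of them); libraries of 5 reversers at fidelity 0.9 (noise calibrated
as $\sigma_s\sqrt{1/\rho^2 - 1}$ so the expected correlation with the
signature is −ρ) among 500 decoys; 300 persons per drug cohort. The
bundled scenario injects clinically realistic magnitudes: one strong
effect at
−30 (a potent approved-drug scale), one weak at −5 (the scale of
incidental repurposing signals), nulls at 0, plus a 19-person cohort
to exercise the minimum-cohort rule.

What passing tests on this generator do **not** show: robustness to
real EHR messiness — irregular visit intensity correlated with health
state, measurement error that depends on care setting beyond a mean
shift, exposure misclassification and non-adherence (a simple
attenuation switch exists but defaults off), time-varying confounding
within the observation window, and coding practice drift. The
generator validates the machinery, not the epidemiology.

## Numerical and degenerate-input choices

* Ties in Z during top-K selection break by ascending p-value, then
  gene symbol — deterministic across platforms.
* Duplicate genes in a DEG table collapse to the record with the
  smallest p (most significant measurement wins), with the collapse
  count logged for auditability.
* |r| = 1 correlations report p at machine epsilon with a
  `degenerate` flag instead of 0, keeping −log₁₀(p) displays finite.
* All-zero paired differences return estimate 0 with p = 1; constant
  non-zero differences return the floored minimum p.
* Constant or aliased covariate columns (e.g. an all-female cohort)
  are dropped with a message and the model refitted on the reduced
  design.
* McNemar tests in the demographics report use the continuity
  correction by default, with an exact binomial variant for tiny
  discordant counts; paired Wilcoxon tests on identical vectors
  return a not-applicable marker rather than an error. Subgroup
  counts below 20 are suppressed in reports.

## Interface notes

The pipeline's four steps are exported as plain functions —
`simulate_inputs()`, `screen_candidates()`, `validate_candidates()`,
`compare_summaries()` — over a YAML-backed `run_config()`. They are
deterministic given config + seed (identical summary files byte for
byte), write all tabular outputs as TSV, and log attrition at every
step. The package deliberately ships no shell executable: its users
drive analyses from R or Rmd, and the functions compose directly.

## Problem sizes used by the shipped tests

The test suite runs the generators at the default study conditions
where the property under test depends on them (300-person cohorts for
recovery, coverage and type-I error, with 100 replicates per effect
size and 200 null drugs; 500-decoy screens) and at reduced scales for
structural unit tests where only correctness of bookkeeping is at
stake (25–60-person cohorts, 10–40-drug libraries). The
brute-force Benjamini–Hochberg oracle is compared on 1000 random
tables; mixed-model/paired-difference equivalence on 50 random
balanced tables at 10⁻⁶ tolerance.

## Known limitations

* The two-period paired design is not the classical Poisson-process
  SCCS likelihood; it targets sustained biomarker shifts, not event
  rates, and is inappropriate for delayed endpoints.
* Wald-z inference is mildly anticonservative in small cohorts; the
  minimum-cohort rule bounds this, but users fitting 20-person
  cohorts should expect coverage nearer 0.93 than 0.95.
* Gene matching is symbol-exact; libraries using probe ids or aliases
  must be mapped upstream.
* The approved-drug exclusion removes confounding by co-medication
  for the *listed* drugs only; an incomplete approved list leaves
  residual confounding by indication.
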