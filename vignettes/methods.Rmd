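---
title: "Methods: case-control genetic association meta-analysis with genemeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control genetic association meta-analysis with genemeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genemeta)
```

## The problem

A candidate-gene association meta-analysis starts from per-study 3x2
genotype tables: counts of wt-wt, var-wt and var-var subjects among cases
and controls, where "wt" and "var" denote the major and minor allele of a
single nucleotide polymorphism (markers in complete linkage
disequilibrium may be pooled under this generic notation, since they carry
the same association signal). The question is whether carrying the
variant changes the odds of disease, and whether that conclusion is
stable across genetic models, populations, outlying studies and possible
publication bias. `genemeta` implements that whole workflow as composable
functions plus a single `run_pipeline()` driver, with a bundled 20-study
BDNF / alcohol-use-disorder dataset (`bdnf_aud_studies()`) as the worked
example.

## Data model and zero cells

Studies are rows of a validated data frame (`gene_dataset`) with genotype
counts, ethnicity, marker label and optional covariates. Two conventions
matter downstream:

* **Laplace correction** (`laplace_correct()`): when any genotype cell is
  zero, one pseudocount is added to *all six* cells of that study and the
  row is flagged. This is the primary zero-cell policy; it acts once, at
  the genotype level, before any contrast is built. The bundled dataset
  ships four rows already corrected (their sources printed them that
  way), which is why those rows' cells sum to slightly more than the
  enrolled subject counts; `total_counts()` therefore prefers the
  explicit per-study totals, reproducing the enrolled 4095 cases and
  4727 controls.
* A **0.5 continuity fallback** (`zero_cell = "add_half"` in
  `study_effects()`) exists for data that reach the 2x2 stage with zeros
  (as happens with simulated small studies). It is off by default so that
  an unnoticed zero is an error, not a silent adjustment.

## Descriptive gates

Per study we compute the control minor-allele frequency, a Pearson 1-df
chi-square test against Hardy-Weinberg proportions (asymptotic, no
continuity correction; monomorphic samples are reported as degenerate
rather than tested), and an approximate power to detect an odds ratio of
1.5 at alpha = 0.05. Power uses a two-proportion normal comparison of
case and control allele frequencies with the *subject* counts as group
sizes; the `method` string records this. It is an approximation — the
power figures printed by dedicated calculators under genotypic-risk
models follow conventions that cannot generally be recovered — but it
reproduces the dichotomous "powered (>= 75%)" classification of the
bundled studies exactly, which is what the pipeline consumes.

## Genetic models and per-study effects

Four contrasts per study (`build_contrast()`): homozygous (var-var vs
wt-wt, heterozygotes dropped), recessive (var-var vs the rest), dominant
(any var vs wt-wt), and codominant/allelic (variant vs wild-type allele
counts, two alleles per subject). The codominant contrast ignores
within-subject allele dependence, the conventional approximation for the
multiplicative model. Effects are cross-product odds ratios with Woolf
standard errors and Wald 95% intervals (z = 1.959964).

## Pooling and model selection

Fixed-effects pooling is Mantel-Haenszel with the
Robins-Breslow-Greenland variance, which stays consistent both with many
sparse strata and few large ones. Random-effects pooling is
DerSimonian-Laird: the method-of-moments between-study variance from
Cochran's Q inflates each study's variance before inverse-variance
weighting. Q, I^2 = max(0, (Q - df)/Q) and tau^2 are computed from
inverse-variance weights around the fixed inverse-variance mean — the
mainstream software convention. The choice between models is a gate, not
a judgment call: random effects iff the Q test has p < 0.10. The same
gate decides whether outlier treatment runs at all (below), because
outliers are interesting here only as *sources of heterogeneity*.

## Outlier treatment, subgroups, multiplicity

The Galbraith (radial) plot places each study at x = 1/se, y =
log(OR)/se; the fixed-effects pooled log odds ratio is the reference
slope (it equals the least-squares slope through the origin), and studies
with |y - slope x| strictly above 2 — the approximate 95% band of a
unit-variance residual — are flagged in a single pass, without re-fitting
after removal. Heterogeneous analyses are then re-pooled without the
flagged studies, re-applying the heterogeneity gate on the reduced set.
Analyses the gate already called homogeneous keep no post-outlier arm.

Subgrouping repeats every analysis within ethnicity strata. All
association p-values of a run form one Bonferroni family; the multiplier
defaults to the number of association tests actually executed (19 on the
bundled data: 12 pre-outlier analyses plus 7 post-outlier re-poolings)
and can be pinned in `run_config()`.

## Sensitivity, publication bias, meta-regression

Leave-one-out sensitivity re-pools n times, re-gating each time; a result
is *robust* when every reduced set preserves the full set's significance
status (95% CI excluding OR = 1; no re-correction inside the loop) and
effect direction. Publication-bias testing is gated on a Shapiro-Wilk
test of the study odds ratios (on the OR scale): normal sets get Egger's
regression of standardized effect on precision, non-normal sets the
Begg-Mazumdar rank correlation between variance-standardized deviations
from the fixed pooled effect and the variances (tau-b, normal
approximation, two-sided). Both follow-ups run only for
Bonferroni-significant results with more than 10 studies, mirroring the
design the bundled analysis reproduces. Meta-regression fits one
covariate at a time by weighted least squares with a method-of-moments
residual tau^2 (the DerSimonian-Laird idea applied to a regression
residual), one-hot encoding categorical covariates and dropping — never
imputing — missing rows.

## The synthetic-data generator

`simulate_dataset()` draws control genotypes from Hardy-Weinberg
proportions at a minor-allele frequency uniform on a configured range,
tilts them multiplicatively per variant allele (or by dominant/recessive
genotype odds ratios) to obtain case probabilities, adds Normal(0, tau)
between-study noise on the log-OR scale, and optionally distorts
designated studies' control genotypes with an inbreeding coefficient or
filters candidate studies through a directional publication gate
(acceptance probability decreasing in the product of the one-sided
allelic p-value and the standard error). Defaults — 20 studies, control
MAF 0.14-0.52, per-arm sizes 30-700 cases and 40-920 controls, no true
effect, no heterogeneity, no selection — emulate the scale and frequency
range of the bundled dataset. All randomness flows from the
configuration seed; the caller's random stream is untouched.

What the generator does *not* emulate: genotyping error, population
stratification, linked multi-marker structure, covariate-outcome
confounding. Passing the property suite therefore validates the
statistical machinery (coverage, tau^2 recovery, test calibration,
outlier detection), not robustness to those real-data pathologies.

## Numerical and design choices

* Wald intervals with z = 1.959964 everywhere; two-sided p from the
  normal (t for the Egger intercept, as its originators specified).
* `heterogeneity()` returns I^2 = 0 when Q = 0 and tau^2 = 0 whenever
  Q <= df.
* The Galbraith threshold is strict (`> 2`, not `>=`), so a residual
  exactly on the band is kept.
* Begg-Mazumdar on equal-variance sets is degenerate (the variance
  ranking carries no information); it warns and reports tau = 0, p = 1.
* The rank test is conservative below about 25 studies; at the default
  simulation size (20 studies) its empirical size runs near 2-3% against
  the nominal 5%, a known property of the test rather than an
  implementation artifact, and the calibration suite reports it as
  measured.
* Problem sizes in the validation suite: 1000 replicates for CI coverage
  and test size, 200 for tau^2 recovery (50 studies each), 400 studies
  for Hardy-Weinberg calibration. These give Monte-Carlo standard errors
  comfortably inside the asserted bands.

## Reproduction limits of the bundled analysis

The bundled dataset is a faithful transcription of its source's printed
counts, and the pipeline reproduces the published pre-outlier pooled
estimates of the genotype-level models to ~0.01, the published
post-outlier study counts for the dominant and subgroup analyses, the
Bonferroni family size (19), and the Hardy-Weinberg/frequency columns.
Four kinds of published values are *not* derivable from the printed
counts, and the acceptance tests assert them at face value so the gaps
stay visible rather than being absorbed into tolerances: (1) the
codominant (allelic) rows, whose printed heterogeneity exceeds anything
any contrast construction yields even in subgroups with unambiguous
data entry; (2) a handful of I^2 values that match only if the
Laplace-corrected rows are de-corrected and a 0.5 continuity rule is
applied instead — evidence that the source mixed conventions between its
printed table and its analysis runs; (3) the post-outlier homozygous and
codominant rosters, which were never printed and which the stated
|residual| > 2 rule does not reproduce from the printed counts; (4) two
publication-bias statistics whose underlying analysis sets are likewise
unrecoverable. The package follows the stated method uniformly — printed
(Laplace-corrected) counts, one convention end to end — and documents
the residual disagreement instead of fitting to it.
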