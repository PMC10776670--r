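---
title: "Expression-cutoff survival stratification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-cutoff survival stratification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprsurv)
```

## The problem

A continuous biomarker — here the qRT-PCR mRNA expression of a candidate
prognostic gene in an acute myeloid leukemia (AML) cohort, measured relative
to a housekeeping gene — is to be turned into a two-group risk
stratification: "low expressors" versus "high expressors", compared by
survival. The scientifically honest difficulty is that the dichotomising
threshold is not known in advance. Trying every threshold and reporting the
best p-value is a classic multiple-testing trap: the minimum p over many
correlated cutoff tests is strongly anti-conservative. `exprsurv`
implements the full procedure — exhaustive cutoff evaluation restricted to
the interquartile range, per-cutoff Cox modelling, Benjamini–Hochberg (BH)
adjustment across the scan, and minimum-FDR selection with highest-HR
tie-breaking — together with the surrounding analyses such a study needs:
delta-Ct quantification, nonparametric group comparisons, Kaplan–Meier
estimation, subgroup (mutation-status) scans, growth-kinetics doubling
times and 4PL IC50 fits, and a synthetic-cohort generator that makes every
stage testable against known ground truth.

## The cutoff scan

For a cohort of `n` patients with expression values `x_i`, right-censored
survival times `t_i` and event indicators `d_i`:

1. **Candidates.** The candidate set is every *observed unique* expression
   value `v` with `Q1 <= v <= Q3`, where the quartiles use linear
   interpolation between order statistics (R's type-7 convention, recorded
   in the configuration because conventions move the candidate set).
   Observed values are the only points at which the stratification
   `low = {x <= v}` changes, so scanning them is exhaustive. Candidates
   whose strata would fall below `min_group_size` (default 10) are dropped:
   near-empty tail strata produce unstable hazard estimates.
2. **Per-cutoff test.** For each candidate the binary indicator
   `1[x <= v]` enters a single-covariate Cox proportional-hazards model,
   fitted by Newton–Raphson on the partial likelihood with the Efron tie
   correction. The low stratum is coded 1, so HR > 1 reads "low expression
   is adverse". The default p-value is the two-sided Wald test; the score
   test (with Breslow ties and untied event times exactly the log-rank
   statistic) is available via
   `p_source = "logrank"`.
3. **FDR across the scan.** The per-cutoff p-values are adjusted with the
   BH step-up rule `q_(i) = min_{j>=i} p_(j) m / j`. The FDR family is the
   candidate set of one scan — one marker, one cohort, one endpoint. Wider
   families (several endpoints, several subgroups) can be formed by
   applying `bh_fdr()` to pooled p-vectors, but the default matches the
   scan-wise correction.
4. **Selection.** The minimum-q cutoff wins. Cutoffs tied on FDR —
   frequent, because the step-up adjustment flattens runs of order
   statistics — are broken by the highest hazard ratio; residual ties by
   lower raw p, then by the smaller cutoff, making selection fully
   deterministic. Kaplan–Meier curves of the selected strata, with median
   survival under the `S(t) <= 0.5` convention, are attached to the
   outcome.

Non-convergent fits (monotone partial likelihood from perfect separation)
are kept in the scan table but excluded from the family and from selection,
with a warning.

### What the calibration experiments show — and one honest caveat

Under a null cohort (expression independent of survival), the uncorrected
minimum p across a scan of a 200-patient cohort falls below 0.05 in roughly
a quarter of cohorts — the inflation the correction exists to remove. The
BH-adjusted selected q-value falls below 0.05 in about 2% of null cohorts.
Note that this is *below* the nominal 5%: under the global null the
"selected q < alpha" event is exactly the event that BH rejects anything,
and its probability equals alpha only for independent (or perfectly
dependent) p-values. Adjacent cutoffs differ by a single patient, so the
scan's tests are in between — very strongly, but not perfectly, positively
dependent — and the procedure is conservative there. We report this as a
property of the published procedure itself, faithfully implemented: type-I
error is controlled, not exhausted. A maximally-selected-rank-statistics
correction (Lausen–Schumacher) would be the exact alternative and is a
stated non-goal.

With a true step effect (HR 2 below an expression ratio of 0.33), the
selected cutoff concentrates around the truth as `n` grows over
{200, 500, 2000}, and the mean selected-cutoff HR at `n = 2000` is within
10% of 2. At small `n` the selected HR is biased upward — the familiar
winner's curse of optimal-cutpoint methods; we deliberately do not shrink
it, since the published procedure does not.

## The synthetic cohort generator

`cohort_spec()` fixes the study conditions; its defaults are chosen once to
mirror the cohort structure the analyses assume and are not tuned
afterwards:

* **Expression**: log-normal, `meanlog = log(0.33)`, `sdlog = 0.8`,
  truncated below at 0.01 — a strictly positive, right-skewed, widely
  dispersed ratio distribution whose median (0.33) and typical range
  (~0.05–1.5 at cohort sizes of a few dozen) match attenuated expression in
  AML blasts relative to donors; donor-like cohorts are generated by
  raising `expr_log_mean` (e.g. `log(0.95)`).
* **Survival**: exponential event times with hazard
  `0.035/month × exp(log-HR × 1[x <= 0.33])` — baseline median OS near 20
  months, the planted effect a step at the latent cutoff because that is
  exactly the structure the scan searches for (a linear-in-log-expression
  alternative, `effect = "linear"`, exists for robustness checks).
* **Censoring**: independent exponential (0.0175/month) plus a 120-month
  administrative cap, giving roughly two-thirds observed events over ~50
  months of average follow-up, the simplest mechanism satisfying the
  non-informative censoring that KM and Cox assume. The censoring
  distribution of real registry cohorts is unknown; this is a stand-in, not
  an inference.
* **Mutations**: independent Bernoulli flags at adult-AML-typical
  frequencies (FLT3-ITD 0.25, NPM1 0.30, CEBPA 0.08), with optional
  subgroup-specific log-HRs so that a single stratum can carry the effect.
  Real mutation flags co-occur non-independently; tests that rely on that
  structure would need a richer generator.
* **Complete remission**: logistic in log expression
  (`plogis(2.3 + 1.5 log x)`, ~65% CR at the median), reproducing a
  monotone CR/non-CR separation without asserting any particular published
  model — none is given for this outcome.
* **EFS**: the event-free endpoint adds an independent relapse process
  (0.0175/month, sharing the expression effect); EFS time is the earlier of
  relapse and death under the same censoring.

Ground truth (the spec) always travels beside the generated table, never
inside it, and a fixed seed reproduces a cohort byte for byte without
disturbing the caller's RNG stream. Because the generator draws exponential
survival with a clean step effect and independent flags, passing recovery
tests demonstrate correctness of the *procedure*, not robustness to
non-proportional hazards, informative censoring or correlated genotypes.

## Supporting statistics

* **Delta-Ct**: `relative_expression()` implements `2^-(Ct_target -
  Ct_ref)` — single-reference relative quantification without a calibrator
  sample; `rescale_expression()` optionally re-expresses ratios on a
  donor-median scale. No amplification-efficiency correction is attempted.
* **Mann–Whitney U**: exact p by full enumeration of all `C(n+m, n)` rank
  assignments when both `n, m <= 10` and no ties (forced via
  `mode = "exact"`, which then uses midranks), otherwise the normal
  approximation with midrank tie correction and continuity correction. The
  two agree within 0.01 by `n = m = 10`. Two-sided throughout.
* **t and Spearman**: Welch by default (pooled available); Spearman rho as
  the Pearson correlation of midranks with the t-approximation p. These
  textbook statistics are implemented directly and cross-checked in the
  test suite against `t.test()`, `wilcox.test()` and `cor.test()`.
* **Cox numerics**: gradient tolerance `1e-10` (relative to the log partial
  likelihood), at most 50 Newton iterations with step-halving so the
  partial likelihood never decreases; standard errors from the observed
  information. Monotone likelihood is flagged (`diverged`), detected as a
  vanishing gradient at `|beta| * sd(x) > 10`, and never raised as an
  error. Efron is the default tie method (more accurate with tied event
  times); Breslow is retained because it makes the score test identical to
  the log-rank statistic for untied data, which the suite exploits as an
  oracle identity (with tied event times the log-rank hypergeometric
  variance carries a `(n_j - d_j)/(n_j - 1)` factor the Breslow score
  information does not, and the two statistics part ways — the tied case
  is cross-checked against `survival::survdiff` instead).

## Kinetics

Growth: `lambda = (ln N_t - ln N_0)/(t - t_0)` and `t_d = ln 2 / lambda`,
exact by construction. Two extensions to a multi-timepoint series are
offered: averaging interval-wise `lambda` (`pairwise_mean`) and regressing
`ln(count)` on time (`log_linear_regression`, the default — it pools
information and has visibly lower variance under multiplicative noise; the
two coincide exactly on noiseless data). A non-growing culture
(`lambda <= 0`) has no doubling time and is an explicit error, never a
sentinel value.

Dose–response: the four-parameter logistic
`y = bottom + (top - bottom)/(1 + (ic50/dose)^hill)` — the conventional
model behind commercial IC50 software — fitted by Levenberg–Marquardt
(`minpack.lm`) with the IC50 parameterised on the log scale and a
multi-start grid (five IC50 starts spanning the dose range × four Hill
slopes including a negative one). An inverted solution (`bottom > top`) is
mapped to the equivalent ordered one by negating the Hill slope. Failure of
all starts returns a diagnosable unconverged result. `fitted(ic50) =
(bottom+top)/2` holds by construction, and the fit is equivariant under
dose-unit rescaling. Curve comparisons report the IC50 ratio and per-dose
differences with residual-resampling bootstrap intervals; whether responses
are normalised to percent-of-maximum first is a switch
(`normalize`), as published IC50s do not always state it.

## Pipeline and IO

`load_cohort()` reads delimited text with a header, applies a column
mapping, derives expression from Ct pairs when needed, and rejects rows
violating hard invariants (non-positive times or ratios) with their line
numbers; remaining missingness is handled per analysis by complete-case
deletion with logged counts — matching the per-analysis `n` reporting style
of clinical cohort papers. `run_pipeline()` executes a JSON-serialisable
configuration (simulate or load, optional FAB-M3 row filter, then any of
compare / cutscan / subgroup_scan / growth / ic50) into one report
directory; every artifact carries a deterministic configuration hash and
the seed, and identical config + seed reproduces the report byte for byte
(timestamps live only in the log). The exported functions are the
interface; the package ships no shell wrapper.

## Worked example

```{r example}
co <- generate_cohort(cohort_spec(n_patients = 400, seed = 7))
sc <- cutoff_scan(co$data)
sc
head(sc$results)
```

```{r km, fig.width = 6, fig.height = 4.5}
plot(sc$km_high, col = "steelblue")
plot(sc$km_low, add = TRUE, col = "firebrick")
legend("topright", c("high expression", "low expression"),
       col = c("steelblue", "firebrick"), lty = 1, bty = "n")
```

Subgroup scans follow the same contract:

```{r subgroups}
scs <- subgroup_scan(co$data, c("flt3_itd", "npm1"))
for (s in scs) print(s)
```

## Problem sizes used in the test suite

The calibration and recovery experiments in the shipped tests use 1000
null cohorts of `n = 200` for the type-I study, 100 seeds at each of
`n` in {200, 500, 2000} for cutoff/HR recovery, 100 replicates for IC50
recovery and oracle comparisons over a few hundred random small datasets —
sizes at which the Monte-Carlo error of every checked proportion is well
below the asserted margins.

## Known limitations

* Single-covariate Cox only; "multivariate" questions are answered by
  subgroup-restricted scans (the interpretation of mutation-stratified
  survival figures in this literature), not by a joint model.
* No Lausen–Schumacher exact cutpoint p-values; the BH route is the
  implemented (and published) procedure, with its conservatism under the
  scan's dependence quantified above.
* The generator does not imitate microarray/RNA-seq measurement error,
  probe effects, or correlated mutation genotypes.
* No qPCR efficiency correction or multi-reference normalisation.
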