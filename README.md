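# exprsurv

Expression-cutoff survival stratification for biomarker cohorts.

## The problem

Clinical cohort studies often need to turn a continuous biomarker — for
example the qRT-PCR mRNA expression of a candidate prognostic gene in acute
myeloid leukemia (AML), measured relative to a housekeeping gene as
`2^-(Ct_target - Ct_reference)` — into a two-group survival stratification
("low" vs "high" expressors). Because the dichotomising threshold is not
known in advance, the honest procedure evaluates *every* observed cutoff
within the interquartile range of expression and corrects for having looked
many times: the minimum p-value over a scan of correlated cutoff tests is
badly anti-conservative.

`exprsurv` implements that procedure end to end, for biostatisticians and
translational researchers:

* **Cutoff scan** (`cutoff_scan()`): for each observed expression value
  `v` with `Q1 <= v <= Q3`, fit a single-covariate Cox proportional-hazards
  model on `1[x <= v]` (Efron ties; HR > 1 = "low expression is adverse"),
  adjust the per-cutoff p-values across the scan with the
  Benjamini–Hochberg step-up rule `q_(i) = min_{j>=i} p_(j) m / j`, select
  the minimum-FDR cutoff, break FDR ties by the highest hazard ratio, and
  attach Kaplan–Meier curves of the selected strata. Subgroup
  (mutation-status) scans and an event-free-survival endpoint are one
  argument away (`subgroup_scan()`).
* **Survival machinery written from scratch**: Kaplan–Meier product-limit
  estimation with `S(t) <= 0.5` median convention (`km_estimate()`),
  two-group log-rank test (`logrank_test()`), Newton–Raphson Cox partial
  likelihood with Efron/Breslow ties (`cox_fit()`), BH FDR (`bh_fdr()`).
* **Group statistics**: exact-enumeration Mann–Whitney U, Welch/pooled t,
  Spearman rank correlation, pairwise cohort comparisons with medians,
  means and significance stars (`compare_groups()`).
* **Assay kinetics**: exponential growth constant
  `lambda = (ln Nt - ln N0)/(t - t0)` and doubling time `td = ln 2/lambda`
  (`growth_constant()`, `doubling_time()`, `fit_doubling_time()`);
  four-parameter logistic dose–response fitting with IC50
  (`fit_4pl()`, `compare_dose_response()`).
* **Synthetic cohort generator** (`generate_cohort()`): log-normal
  expression, proportional-hazards survival with a step effect at a latent
  cutoff, independent censoring, mutation flags, logistic
  complete-remission outcome — with ground truth kept beside the data, so
  calibration and recovery are testable without any external download.
* **Pipeline** (`run_pipeline()`): JSON-configurable orchestration of the
  whole sequence into a deterministic, seed-stamped report directory.

## Worked example

```r
library(exprsurv)

co <- generate_cohort(cohort_spec(n_patients = 400, seed = 7))
sc <- cutoff_scan(co$data)
sc
#> Cutoff scan [all], endpoint os_time: 200 candidates, n = 400 (280 events)
#>   selected cutoff 0.3349 (hr_tiebreak): HR = 2.217, p = 9.94e-11, FDR q = 1.36e-08
#>   median survival: low 8.818542 vs high 21.4011
```

The cohort was simulated with a true step effect of hazard ratio 2 below an
expression ratio of 0.33; the scan recovers the cutoff (0.335), its effect
(HR 2.22, the slight excess being the winner's curse of optimal-cutpoint
selection at this n), and the corrected significance of the selected split
(q = 1.4e-8). Low expressors have a median overall survival of 8.8 months
against 21.4 months for high expressors.

```r
compare_groups(co$data, "cr_achieved", "relative_expression")
#>   group_a group_b n_a n_b  median_a  median_b            p stars
#> 1   FALSE    TRUE 157 243 0.2058837 0.4340505 5.685791e-18  ****
```

Patients failing complete remission carry a lower median expression (0.21
vs 0.43; Mann–Whitney).

```r
gs <- generate_growth_series(1e5, 19, seq(0, 96, 24), noise_cv = 0.05,
                             n_replicates = 3, seed = 2)
fit_doubling_time(gs)$doubling_time
#> [1] 18.92477   # hours, log-linear regression over 3 replicates
```

See `vignettes/exprsurv-methods.Rmd` for the models, parameter choices,
numerical conventions and known limitations.

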