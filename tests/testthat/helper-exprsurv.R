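# Shared fixtures, built in code.

# Small random right-censored dataset for property tests.
random_surv <- function(n, event_p = 0.7, tie_prob = 0) {
  tm <- rexp(n)
  if (tie_prob > 0) tm <- round(tm * 4) / 4 + 0.25  # induces ties
  list(time = tm,
       event = stats::rbinom(n, 1L, event_p) == 1L,
       group = stats::rbinom(n, 1L, 0.5))
}

# A quick, small effect cohort for scan tests.
quick_cohort <- function(n = 150, seed = 1, hr = 2) {
  generate_cohort(cohort_spec(n_patients = n, seed = seed,
                              true_log_hr_low = log(hr)))
}
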