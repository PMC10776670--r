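# Synthetic cohorts, growth series and dose-response data with known ground
# truth. The generator emulates the statistical structure the downstream
# analyses assume -- right-skewed log-normal expression, proportional-hazards
# survival with a step effect at a latent expression cutoff, independent
# exponential censoring plus an administrative cap, mutation flags with
# optional subgroup-specific effects, and a logistic complete-remission
# model -- so calibration and recovery can be tested without external data.

#' Specification of a synthetic patient cohort
#'
#' Bundles and validates all generator parameters. Defaults describe an
#' AML-like cohort: relative expression log-normal with median ~0.33 and
#' wide dispersion; overall-survival hazard of 0.035/month (median OS near
#' 20 months) doubled below the latent expression cutoff; independent
#' exponential censoring yielding roughly two-thirds observed events over a
#' 120-month administrative window; mutation flag frequencies typical of
#' adult AML; and a complete-remission probability increasing in log
#' expression.
#'
#' @param n_patients number of patients (>= 2).
#' @param expr_log_mean,expr_log_sd log-scale mean and sd of the log-normal
#'   relative-expression distribution.
#' @param expr_min truncation floor for expression ratios.
#' @param subgroup_fractions named proportions of mutation-positive patients
#'   per flag (independent Bernoulli draws).
#' @param true_cutoff latent expression cutoff at which the hazard effect
#'   switches on.
#' @param true_log_hr_low log hazard ratio applied to patients with
#'   expression `<= true_cutoff` (step effect; 0 = null cohort).
#' @param subgroup_log_hr named list/vector of additional log hazard ratios
#'   applied to low-expression patients positive for the named flag; lets a
#'   single subgroup carry the effect.
#' @param effect `"step"` (default; the hazard acts through the cutoff) or
#'   `"linear"` (log hazard declines linearly in standardised log
#'   expression with slope `true_log_hr_low`; robustness alternative).
#' @param baseline_hazard events per month in the high-expression stratum.
#' @param censor_rate independent exponential censoring rate per month
#'   (0 = no random censoring).
#' @param followup_cap administrative censoring time in months (`Inf` to
#'   disable).
#' @param efs_relapse_hazard extra hazard for the event-free-survival
#'   endpoint (relapse), sharing the expression effect; EFS time is the
#'   earlier of relapse and death.
#' @param cr_intercept,cr_slope logistic model of complete remission on log
#'   expression: `P(CR) = plogis(cr_intercept + cr_slope * log(expr))`.
#' @param cohort_label label stored with each record.
#' @param seed integer RNG seed; identical spec + seed reproduces the cohort
#'   exactly.
#' @return a validated object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_patients = 830,
                        expr_log_mean = log(0.33),
                        expr_log_sd = 0.8,
                        expr_min = 0.01,
                        subgroup_fractions = c(flt3_itd = 0.25,
                                               npm1 = 0.30,
                                               cebpa = 0.08),
                        true_cutoff = 0.33,
                        true_log_hr_low = log(2),
                        subgroup_log_hr = NULL,
                        effect = c("step", "linear"),
                        baseline_hazard = 0.035,
                        censor_rate = 0.0175,
                        followup_cap = 120,
                        efs_relapse_hazard = 0.0175,
                        cr_intercept = 2.3,
                        cr_slope = 1.5,
                        cohort_label = "AML",
                        seed = 1L) {
  effect <- match.arg(effect)
  check_number(n_patients, "n_patients", lower = 2)
  check_number(expr_log_mean, "expr_log_mean")
  check_that(is.numeric(expr_log_sd) && expr_log_sd > 0, "expr_log_sd",
             "must be > 0")
  check_number(expr_min, "expr_min", lower = 0)
  if (length(subgroup_fractions)) {
    check_that(!is.null(names(subgroup_fractions)) &&
                 all(nzchar(names(subgroup_fractions))),
               "subgroup_fractions", "must be named")
    check_that(all(subgroup_fractions >= 0 & subgroup_fractions <= 1),
               "subgroup_fractions", "proportions must lie in [0, 1]")
  }
  check_number(true_cutoff, "true_cutoff", lower = 0)
  check_number(true_log_hr_low, "true_log_hr_low")
  if (!is.null(subgroup_log_hr)) {
    check_that(all(names(subgroup_log_hr) %in% names(subgroup_fractions)),
               "subgroup_log_hr", "names must match subgroup_fractions")
  }
  check_that(is.numeric(baseline_hazard) && baseline_hazard > 0,
             "baseline_hazard", "must be > 0")
  check_number(censor_rate, "censor_rate", lower = 0)
  check_number(followup_cap, "followup_cap", lower = 0, finite = FALSE)
  check_that(followup_cap > 0, "followup_cap", "must be > 0")
  check_number(efs_relapse_hazard, "efs_relapse_hazard", lower = 0)
  check_number(cr_intercept, "cr_intercept")
  check_number(cr_slope, "cr_slope")
  check_number(seed, "seed")
  out <- list(n_patients = as.integer(n_patients),
              expr_log_mean = expr_log_mean, expr_log_sd = expr_log_sd,
              expr_min = expr_min,
              subgroup_fractions = subgroup_fractions,
              true_cutoff = true_cutoff,
              true_log_hr_low = true_log_hr_low,
              subgroup_log_hr = subgroup_log_hr,
              effect = effect,
              baseline_hazard = baseline_hazard,
              censor_rate = censor_rate,
              followup_cap = followup_cap,
              efs_relapse_hazard = efs_relapse_hazard,
              cr_intercept = cr_intercept, cr_slope = cr_slope,
              cohort_label = cohort_label,
              seed = as.integer(seed))
  class(out) <- "cohort_spec"
  out
}

# Per-patient log hazard shift attributable to expression (and subgroups).
expression_log_hazard <- function(spec, expr, flags) {
  low <- expr <= spec$true_cutoff
  shift <- if (spec$effect == "step") {
    spec$true_log_hr_low * low
  } else {
    -spec$true_log_hr_low *
      (log(expr) - spec$expr_log_mean) / spec$expr_log_sd
  }
  if (!is.null(spec$subgroup_log_hr)) {
    for (fl in names(spec$subgroup_log_hr)) {
      shift <- shift + spec$subgroup_log_hr[[fl]] * low * flags[[fl]]
    }
  }
  shift
}

#' Generate a synthetic patient cohort
#'
#' Draws expression log-normally, mutation flags independently, survival
#' times from an exponential proportional-hazards model whose hazard is
#' `baseline_hazard * exp(shift)` with the shift determined by the latent
#' expression cutoff (see [cohort_spec()]), censoring independently, and
#' complete remission from the logistic model. The observed time is the
#' minimum of event, censoring and the administrative cap.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `"synthetic_cohort"`: `$data`, a data frame with
#'   `sample_id`, `relative_expression`, one logical column per mutation
#'   flag, `os_time`/`os_event`, `efs_time`/`efs_event`, `cr_achieved` and
#'   `cohort_label`; and `$spec`, the generating ground truth kept alongside
#'   (never embedded in) the table.
#' @examples
#' co <- generate_cohort(cohort_spec(n_patients = 50, seed = 7))
#' head(co$data)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    expr <- pmax(stats::rlnorm(n, spec$expr_log_mean, spec$expr_log_sd),
                 spec$expr_min)
    flags <- lapply(spec$subgroup_fractions, function(p) {
      stats::rbinom(n, 1L, p) == 1L
    })
    shift <- expression_log_hazard(spec, expr, flags)
    hz <- spec$baseline_hazard * exp(shift)
    death_time <- stats::rexp(n, rate = 1) / hz
    censor_time <- if (spec$censor_rate > 0) {
      stats::rexp(n, spec$censor_rate)
    } else {
      rep(Inf, n)
    }
    os_time <- pmin(death_time, censor_time, spec$followup_cap)
    os_event <- death_time <= pmin(censor_time, spec$followup_cap)
    relapse_time <- if (spec$efs_relapse_hazard > 0) {
      stats::rexp(n, rate = 1) / (spec$efs_relapse_hazard * exp(shift))
    } else {
      rep(Inf, n)
    }
    efs_raw <- pmin(death_time, relapse_time)
    efs_time <- pmin(efs_raw, censor_time, spec$followup_cap)
    efs_event <- efs_raw <= pmin(censor_time, spec$followup_cap)
    cr <- stats::rbinom(n, 1L,
                        stats::plogis(spec$cr_intercept +
                                        spec$cr_slope * log(expr))) == 1L
    dat <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                      relative_expression = expr,
                      os_time = os_time, os_event = os_event,
                      efs_time = efs_time, efs_event = efs_event,
                      cr_achieved = cr,
                      cohort_label = spec$cohort_label,
                      stringsAsFactors = FALSE)
    for (fl in names(flags)) dat[[fl]] <- flags[[fl]]
    out <- list(data = dat, spec = spec)
    class(out) <- "synthetic_cohort"
    out
  })
}

#' Generate a null cohort (expression independent of survival)
#'
#' Identical pipeline to [generate_cohort()] with the expression effect
#' forced to zero (`true_log_hr_low = 0`, subgroup effects dropped), so
#' expression and survival are independent. Used to calibrate the cutoff
#' scan's false-positive behaviour.
#'
#' @param spec a [cohort_spec()]; its effect fields are overridden.
#' @return a `synthetic_cohort`.
#' @export
generate_null_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  spec$true_log_hr_low <- 0
  spec$subgroup_log_hr <- NULL
  spec$effect <- "step"
  generate_cohort(spec)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort '%s': n = %d, events = %d (%.1f%%), seed = %d\n",
    x$spec$cohort_label, nrow(x$data), sum(x$data$os_event),
    100 * mean(x$data$os_event), x$spec$seed))
  invisible(x)
}

#' @export
as.data.frame.synthetic_cohort <- function(x, ...) x$data

#' Generate an exponential growth series
#'
#' Cell counts `n0 * 2^(t / doubling_time)` at the given timepoints, with
#' multiplicative log-normal noise of the stated coefficient of variation
#' (mean 1, so the noise is unbiased on the count scale).
#'
#' @param n0 initial cell count (> 0).
#' @param doubling_time true doubling time in hours (> 0).
#' @param timepoints strictly increasing observation times in hours.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 = deterministic counts).
#' @param n_replicates independent replicate series.
#' @param seed optional RNG seed.
#' @return data frame of class `"growth_series"` with columns `time_h`,
#'   `count`, `replicate`; the generating parameters are stored in
#'   attribute `"params"`.
#' @examples
#' generate_growth_series(1e5, 24, c(0, 24, 48))  # exact doublings
#' @export
generate_growth_series <- function(n0, doubling_time, timepoints,
                                   noise_cv = 0, n_replicates = 1L,
                                   seed = NULL) {
  check_that(is.numeric(n0) && n0 > 0, "n0", "must be > 0")
  check_that(is.numeric(doubling_time) && doubling_time > 0,
             "doubling_time", "must be > 0")
  check_numeric_vec(timepoints, "timepoints", min_len = 1L)
  check_that(all(diff(timepoints) > 0) || length(timepoints) == 1L,
             "timepoints", "must be strictly increasing")
  check_number(noise_cv, "noise_cv", lower = 0)
  with_seed(seed, {
    rows <- lapply(seq_len(n_replicates), function(rep_i) {
      mu <- n0 * 2^(timepoints / doubling_time)
      count <- if (noise_cv > 0) {
        sdlog <- sqrt(log(1 + noise_cv^2))
        mu * stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else {
        mu
      }
      data.frame(time_h = timepoints, count = count, replicate = rep_i)
    })
    out <- do.call(rbind, rows)
    attr(out, "params") <- list(n0 = n0, doubling_time = doubling_time,
                                noise_cv = noise_cv, seed = seed)
    class(out) <- c("growth_series", "data.frame")
    out
  })
}

#' Four-parameter logistic dose-response curve
#'
#' `bottom + (top - bottom) / (1 + (ic50 / dose)^hill)`. With `hill > 0`
#' the response increases with dose and equals the midpoint
#' `(bottom + top) / 2` exactly at `dose = ic50`.
#'
#' @param dose doses (> 0).
#' @param bottom,top lower and upper asymptotes (`bottom < top`).
#' @param ic50 half-maximal dose (> 0).
#' @param hill slope parameter.
#' @return response values.
#' @export
fourpl <- function(dose, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + (ic50 / dose)^hill)
}

#' Generate synthetic dose-response data
#'
#' Responses from a 4PL curve plus additive Gaussian noise, clipped to the
#' valid response range (`[0, 1]` for fractions, `[0, 100]` for percent).
#'
#' @param doses dose levels (> 0), e.g. an 8-point serial dilution.
#' @param bottom,top,ic50,hill 4PL parameters; `bottom < top`, `ic50 > 0`.
#' @param noise_sd standard deviation of the additive noise.
#' @param n_replicates replicates per dose.
#' @param response_scale `"fraction"` or `"percent"`.
#' @param seed optional RNG seed.
#' @return data frame of class `"dose_response"` with columns `dose`,
#'   `response`, `replicate`; generating parameters in attribute `"params"`.
#' @export
generate_dose_response <- function(doses, bottom = 0.05, top = 0.85,
                                   ic50 = 100, hill = 1.2, noise_sd = 0,
                                   n_replicates = 1L,
                                   response_scale = c("fraction", "percent"),
                                   seed = NULL) {
  response_scale <- match.arg(response_scale)
  check_numeric_vec(doses, "doses", min_len = 1L, positive = TRUE)
  check_that(is.numeric(bottom) && is.numeric(top) && bottom < top,
             "bottom", "must satisfy bottom < top")
  check_that(is.numeric(ic50) && ic50 > 0, "ic50", "must be > 0")
  check_number(hill, "hill")
  check_number(noise_sd, "noise_sd", lower = 0)
  hi <- if (response_scale == "fraction") 1 else 100
  with_seed(seed, {
    rows <- lapply(seq_len(n_replicates), function(rep_i) {
      mu <- fourpl(doses, bottom, top, ic50, hill)
      y <- mu + stats::rnorm(length(mu), sd = noise_sd)
      data.frame(dose = doses, response = pmin(pmax(y, 0), hi),
                 replicate = rep_i)
    })
    out <- do.call(rbind, rows)
    attr(out, "params") <- list(bottom = bottom, top = top, ic50 = ic50,
                                hill = hill, noise_sd = noise_sd,
                                response_scale = response_scale, seed = seed)
    class(out) <- c("dose_response", "data.frame")
    out
  })
}
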