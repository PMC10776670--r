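# From-scratch survival machinery: Kaplan-Meier product-limit estimation,
# the two-group log-rank test, single-covariate Cox proportional-hazards
# regression (Efron or Breslow tie handling) and Benjamini-Hochberg FDR
# adjustment. These are the building blocks of the cutoff scan.

validate_surv <- function(time, event, n_min = 1L) {
  check_numeric_vec(time, "time", min_len = n_min, positive = TRUE)
  check_that(length(event) == length(time), "event",
             "must have the same length as `time`")
  check_that(is.logical(event) || all(event %in% c(0, 1)), "event",
             "must be logical or 0/1")
  as.logical(event)
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes the nonparametric survival curve for right-censored data.
#' Subjects censored at an event time are still counted as at risk for that
#' event time (the standard convention). The median survival is the smallest
#' event time at which the curve drops to 0.5 or below; if the curve never
#' reaches 0.5 the median is undefined and reported as `NA`.
#'
#' @param time positive follow-up times (months).
#' @param event logical (or 0/1) event indicator; `FALSE` = censored.
#' @return An object of class `"km_curve"`: a list with the distinct event
#'   times, the survival probability after each, at-risk and event counts,
#'   censoring times, the median survival (`NA` if undefined) and `n`.
#' @examples
#' km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
#' km$surv          # 2/3, 1/3, 0
#' median_survival(km)
#' @export
km_estimate <- function(time, event) {
  event <- validate_surv(time, event)
  ord <- order(time)
  t_s <- time[ord]
  e_s <- event[ord]
  ev_times <- unique(t_s[e_s])
  if (length(ev_times) == 0L) {
    out <- list(time = numeric(0), surv = numeric(0),
                n_risk = integer(0), n_event = integer(0),
                censor_times = t_s, median = NA_real_, n = length(time))
    class(out) <- "km_curve"
    return(out)
  }
  # at-risk: all subjects with observed time >= t (censored-at-t included)
  n_risk <- vapply(ev_times, function(tt) sum(t_s >= tt), integer(1))
  n_event <- vapply(ev_times, function(tt) sum(t_s == tt & e_s), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  med <- if (any(surv <= 0.5)) ev_times[which(surv <= 0.5)[1L]] else NA_real_
  out <- list(time = ev_times, surv = surv, n_risk = n_risk,
              n_event = n_event, censor_times = t_s[!e_s],
              median = med, n = length(time))
  class(out) <- "km_curve"
  out
}

#' Median survival of a Kaplan-Meier curve
#'
#' Smallest event time with survival probability `<= 0.5`; `NA` when the
#' curve never reaches 0.5 (the median is then undefined). This `<= 0.5`
#' convention matches common survival software and is stated here explicitly
#' because published reports rarely define it.
#'
#' @param curve a [km_estimate()] result.
#' @return months, or `NA_real_` when undefined.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  curve$median
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s\n",
              x$n, sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$time, surv = x$surv,
             n_risk = x$n_risk, n_event = x$n_event)
}

#' Plot a Kaplan-Meier curve
#'
#' Step curve with censor tick marks, drawn with base graphics.
#'
#' @param x a `km_curve`.
#' @param add overlay on an existing plot.
#' @param col,lty,... passed to [graphics::lines()].
#' @return `x`, invisibly.
#' @export
plot.km_curve <- function(x, add = FALSE, col = 1, lty = 1, ...) {
  tt <- c(0, x$time)
  ss <- c(1, x$surv)
  if (!add) {
    graphics::plot(NA, xlim = c(0, max(c(tt, x$censor_times), 1)),
                   ylim = c(0, 1), xlab = "Time (months)",
                   ylab = "Survival probability")
  }
  graphics::lines(stats::stepfun(x$time, ss), do.points = FALSE,
                  col = col, lty = lty, ...)
  if (length(x$censor_times)) {
    sc <- vapply(x$censor_times,
                 function(tc) c(1, x$surv)[sum(x$time <= tc) + 1L], numeric(1))
    graphics::points(x$censor_times, sc, pch = 3, col = col)
  }
  invisible(x)
}

#' Two-group log-rank test
#'
#' Classic Mantel-Haenszel log-rank chi-square on one degree of freedom,
#' using the hypergeometric variance at each distinct event time. For a
#' binary covariate this statistic equals the Cox score test with Breslow
#' tie handling.
#'
#' @param time,event as in [km_estimate()].
#' @param group two-level grouping (logical, factor, or two unique values).
#' @return list with `chisq`, `df` (always 1), `p`, and the observed and
#'   expected event counts per group.
#' @export
logrank_test <- function(time, event, group) {
  event <- validate_surv(time, event)
  check_that(length(group) == length(time), "group",
             "must have the same length as `time`")
  lev <- unique(group)
  check_that(length(lev) == 2L, "group", "must have exactly 2 levels")
  g1 <- group == lev[[2L]]

  ev_times <- sort(unique(time[event]))
  o1 <- e1 <- v <- 0
  for (tt in ev_times) {
    at_risk <- time >= tt
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & g1)
    d_j <- sum(time == tt & event)
    d1_j <- sum(time == tt & event & g1)
    o1 <- o1 + d1_j
    e1 <- e1 + d_j * n1_j / n_j
    if (n_j > 1) {
      v <- v + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
    }
  }
  chisq <- if (v > 0) (o1 - e1)^2 / v else 0
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
       observed = c(sum(event) - o1, o1),
       expected = c(sum(event) - e1, e1))
}

# Precompute everything about (time, event) that the Cox partial likelihood
# needs and that does not depend on the covariate or on beta: sort order,
# risk-set anchors for each distinct event time, and the Efron expansion
# (one row per tied death, with its within-tie fraction l/d). Reused across
# the cutoff scan so only the covariate changes between fits.
cox_prep <- function(time, event) {
  event <- validate_surv(time, event, n_min = 2L)
  check_that(sum(event) >= 1L, "event", "needs at least one event")
  ord <- order(time)
  t_s <- time[ord]
  e_s <- event[ord]
  ut <- unique(t_s[e_s])
  first_idx <- match(ut, t_s)              # risk set = first_idx..n
  death_rows <- which(e_s)
  death_grp <- match(t_s[death_rows], ut)  # event-time index per death
  d <- tabulate(death_grp, nbins = length(ut))
  exp_grp <- rep(seq_along(ut), d)
  exp_frac <- unlist(lapply(d, function(dd) (seq_len(dd) - 1) / dd),
                     use.names = FALSE)
  list(ord = ord, t_s = t_s, e_s = e_s, n = length(t_s),
       ut = ut, first_idx = first_idx,
       death_rows = death_rows, death_grp = death_grp, d = d,
       exp_grp = exp_grp, exp_frac = exp_frac)
}

# Log partial likelihood, gradient and observed information at beta for a
# single covariate x (already in prep's sort order).
cox_lgh <- function(prep, x, beta, ties) {
  eta <- beta * x
  w <- exp(eta)
  rc0 <- rev(cumsum(rev(w)))
  rc1 <- rev(cumsum(rev(w * x)))
  rc2 <- rev(cumsum(rev(w * x * x)))
  S0 <- rc0[prep$first_idx]
  S1 <- rc1[prep$first_idx]
  S2 <- rc2[prep$first_idx]
  xd <- x[prep$death_rows]
  wd <- w[prep$death_rows]
  sum_eta_d <- sum(eta[prep$death_rows])
  sum_x_d <- sum(xd)
  if (ties == "breslow") {
    lp <- sum_eta_d - sum(prep$d * log(S0))
    m1 <- S1 / S0
    g <- sum_x_d - sum(prep$d * m1)
    h <- sum(prep$d * (S2 / S0 - m1 * m1))
  } else {
    S0d <- as.vector(rowsum(wd, prep$death_grp))
    S1d <- as.vector(rowsum(wd * xd, prep$death_grp))
    S2d <- as.vector(rowsum(wd * xd * xd, prep$death_grp))
    gi <- prep$exp_grp
    fr <- prep$exp_frac
    den <- S0[gi] - fr * S0d[gi]
    n1 <- S1[gi] - fr * S1d[gi]
    n2 <- S2[gi] - fr * S2d[gi]
    m1 <- n1 / den
    lp <- sum_eta_d - sum(log(den))
    g <- sum_x_d - sum(m1)
    h <- sum(n2 / den - m1 * m1)
  }
  list(lp = lp, g = g, h = h)
}

#' Single-covariate Cox proportional-hazards fit
#'
#' Maximises the Cox partial likelihood by Newton-Raphson with step-halving,
#' using the Efron tie correction by default (Breslow available, under which
#' the score test at `beta = 0` for a binary covariate is exactly the
#' log-rank chi-square). The standard error comes from the observed
#' information at the optimum; the default p-value is the two-sided Wald
#' test, with score and likelihood-ratio p-values also reported.
#'
#' Perfect separation (monotone likelihood) is not an error: the fit is
#' returned with `converged = FALSE` and `diverged = TRUE` so that callers
#' such as [cutoff_scan()] can skip the cutoff instead of aborting.
#'
#' @param time,event as in [km_estimate()].
#' @param covariate numeric covariate, one value per subject (a binary 0/1
#'   stratum indicator in the cutoff scan).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param init starting value for the coefficient.
#' @param tol convergence tolerance on the gradient magnitude.
#' @param max_iter Newton-Raphson iteration cap.
#' @return Object of class `"cox_fit"`: coefficient `beta`, `hr = exp(beta)`,
#'   `se`, `z`, `p` (Wald), `score_chisq`/`score_p`, `lr_chisq`/`lr_p`,
#'   log partial likelihoods at 0 and at the optimum, iteration count and
#'   convergence flags.
#' @examples
#' set.seed(1)
#' tm <- rexp(60); gp <- rep(0:1, 30)
#' fit <- cox_fit(tm * ifelse(gp == 1, 2, 1), rep(TRUE, 60), gp)
#' fit$hr
#' @export
cox_fit <- function(time, event, covariate, ties = c("efron", "breslow"),
                    init = 0, tol = 1e-10, max_iter = 50L) {
  ties <- match.arg(ties)
  prep <- cox_prep(time, event)
  check_that(length(covariate) == length(time), "covariate",
             "must have the same length as `time`")
  check_numeric_vec(covariate, "covariate", min_len = 2L)
  x <- covariate[prep$ord]
  cox_fit_prepped(prep, x, ties = ties, init = init, tol = tol,
                  max_iter = max_iter)
}

# Workhorse on presorted data; x in prep order.
cox_fit_prepped <- function(prep, x, ties = "efron", init = 0,
                            tol = 1e-10, max_iter = 50L) {
  # degenerate covariate: no variation within any risk set
  at0 <- cox_lgh(prep, x, 0, ties)
  if (!is.finite(at0$h) || at0$h <= 0) {
    stop("invalid `covariate`: no variation among subjects at risk ",
         "at any event time", call. = FALSE)
  }
  score_chisq <- at0$g^2 / at0$h
  sdx <- stats::sd(x)
  beta <- init
  cur <- if (init == 0) at0 else cox_lgh(prep, x, beta, ties)
  iter <- 0L
  converged <- FALSE
  diverged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    if (abs(cur$g) <= tol * max(1, abs(cur$lp))) {
      converged <- TRUE
      break
    }
    if (!is.finite(cur$h) || cur$h <= 0 || abs(beta) * sdx > 20) {
      diverged <- TRUE
      break
    }
    step <- cur$g / cur$h
    # step-halving: never accept a decrease in the partial likelihood
    for (half in 0:30) {
      cand <- beta + step / 2^half
      nxt <- cox_lgh(prep, x, cand, ties)
      if (is.finite(nxt$lp) && nxt$lp >= cur$lp - 1e-12) break
    }
    beta <- cand
    cur <- nxt
  }
  # monotone likelihood: the gradient flattens as beta runs away, so a
  # vanishing gradient at an extreme (scale-adjusted) beta is divergence,
  # not convergence
  if (abs(beta) * sdx > 10) {
    diverged <- TRUE
    converged <- FALSE
  }
  se <- if (is.finite(cur$h) && cur$h > 0) 1 / sqrt(cur$h) else NA_real_
  z <- beta / se
  lr <- 2 * (cur$lp - at0$lp)
  out <- list(beta = beta, hr = exp(beta), se = se, z = z,
              p = 2 * stats::pnorm(-abs(z)),
              score_chisq = score_chisq,
              score_p = stats::pchisq(score_chisq, 1L, lower.tail = FALSE),
              lr_chisq = lr,
              lr_p = stats::pchisq(max(lr, 0), 1L, lower.tail = FALSE),
              loglik0 = at0$lp, loglik = cur$lp,
              iter = iter, converged = converged, diverged = diverged,
              ties = ties, n = prep$n, n_event = length(prep$death_rows))
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "Cox PH fit (%s ties): HR = %.4f (beta = %.4f, se = %.4f), Wald p = %.3g%s\n",
    x$ties, x$hr, x$beta, x$se, x$p,
    if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values `q_(i) = min_{j >= i} p_(j) * m / j`, clipped to
#' 1 and returned in the input order. Used across the candidate set of one
#' cutoff scan so that the minimum over many correlated cutoff tests is not
#' reported at face value.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p) {
  check_numeric_vec(p, "p", min_len = 1L)
  check_that(all(p >= 0 & p <= 1), "p", "must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
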