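# In-vitro quantitative analyses: exponential growth constants and doubling
# times from timed cell counts, and four-parameter logistic (4PL)
# dose-response fitting with IC50 estimation for apoptosis dose-dilution
# experiments.

#' Exponential growth constant from two counts
#'
#' `lambda = (ln(Nt) - ln(N0)) / (t - t0)`, the per-hour rate of an
#' exponentially growing culture. Negative values (shrinking culture) are
#' allowed.
#'
#' @param n0,nt cell counts at the initial and observation time (> 0).
#' @param t0,t initial and observation times in hours (`t > t0`).
#' @return growth constant per hour.
#' @examples
#' growth_constant(100, 800, 0, 3)  # ln 2: three doublings in three hours
#' @export
growth_constant <- function(n0, nt, t0, t) {
  check_that(is.numeric(n0) && all(n0 > 0), "n0", "must be > 0")
  check_that(is.numeric(nt) && all(nt > 0), "nt", "must be > 0")
  check_that(is.numeric(t0) && is.numeric(t) && all(t > t0), "t",
             "must be > t0")
  (log(nt) - log(n0)) / (t - t0)
}

#' Doubling time from a growth constant
#'
#' `td = ln(2) / lambda`. Defined only for a growing culture.
#'
#' @param lambda growth constant per hour (> 0).
#' @return doubling time in hours.
#' @export
doubling_time <- function(lambda) {
  check_that(is.numeric(lambda) && all(is.finite(lambda)), "lambda",
             "must be finite")
  if (any(lambda <= 0)) {
    stop("undefined doubling time: culture is not growing (lambda <= 0)",
         call. = FALSE)
  }
  log(2) / lambda
}

#' Estimate doubling time from a timed count series
#'
#' Two estimators: `log_linear_regression` (default) fits `ln(count)` on
#' time by least squares and converts the slope; `pairwise_mean` averages
#' the two-point growth constant over consecutive intervals. Both agree
#' exactly on noiseless exponential data; the regression pools information
#' and has lower variance under multiplicative noise. With replicate
#' series, each replicate is estimated separately and the spread is
#' reported.
#'
#' @param series a [generate_growth_series()] data frame, or any data frame
#'   with columns `time_h`, `count` and optionally `replicate`.
#' @param method `"log_linear_regression"` or `"pairwise_mean"`.
#' @return list with `doubling_time` (hours, mean over replicates),
#'   `growth_constant` (per hour), `sd` (between-replicate sd of the
#'   doubling time, `NA` for a single series), `per_replicate`, `method`.
#' @export
fit_doubling_time <- function(series,
                              method = c("log_linear_regression",
                                         "pairwise_mean")) {
  method <- match.arg(method)
  check_that(is.data.frame(series) &&
               all(c("time_h", "count") %in% names(series)),
             "series", "needs columns time_h and count")
  if (is.null(series$replicate)) series$replicate <- 1L
  reps <- split(series, series$replicate)
  lam <- vapply(reps, function(df) {
    df <- df[order(df$time_h), , drop = FALSE]
    check_that(nrow(df) >= 2L, "series",
               "needs at least 2 timepoints per replicate")
    check_numeric_vec(df$count, "count", positive = TRUE)
    if (method == "pairwise_mean") {
      mean(growth_constant(df$count[-nrow(df)], df$count[-1L],
                           df$time_h[-nrow(df)], df$time_h[-1L]))
    } else {
      unname(stats::coef(stats::lm(log(count) ~ time_h, data = df))[2L])
    }
  }, numeric(1))
  td <- doubling_time(lam)  # errors if any replicate is not growing
  list(doubling_time = mean(td),
       growth_constant = mean(lam),
       sd = if (length(td) > 1L) stats::sd(td) else NA_real_,
       per_replicate = td,
       method = method)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `response = bottom + (top - bottom) /
#' (1 + (ic50/dose)^hill)` on log dose, by Levenberg-Marquardt with
#' multi-start initialisation (IC50 starts spread over the observed dose
#' range, several Hill slopes, both signs). The IC50 is parameterised on
#' the log scale so it stays positive, and the fit is reported with
#' `bottom <= top` (an inverted solution is mapped back by negating the
#' Hill slope, which leaves the curve unchanged). By construction the
#' fitted curve at `ic50` equals `(bottom + top) / 2`.
#'
#' If no start converges the result is returned with `converged = FALSE`
#' and the diagnostics of the attempts rather than an error.
#'
#' @param data data frame with columns `dose` and `response` (replicates as
#'   extra rows), e.g. from [generate_dose_response()].
#' @param normalize if `TRUE`, responses are first rescaled to
#'   percent-of-maximum (`response / max(response)`); off by default.
#' @param start optional list with `bottom`, `top`, `ic50`, `hill`: tried
#'   as the only start (multi-start fallback if it fails). Used by the
#'   bootstrap, where each refit begins at the original solution.
#' @return object of class `"fourpl_fit"`: `bottom`, `top`, `ic50`, `hill`,
#'   `rss`, `converged`, `fitted`, `residuals`, the data used and the
#'   number of starts tried.
#' @export
fit_4pl <- function(data, normalize = FALSE, start = NULL) {
  check_that(is.data.frame(data) &&
               all(c("dose", "response") %in% names(data)),
             "data", "needs columns dose and response")
  check_numeric_vec(data$dose, "dose", positive = TRUE)
  check_numeric_vec(data$response, "response")
  check_that(length(unique(data$dose)) >= 4L, "data",
             "needs at least 4 distinct doses")
  y <- data$response
  if (normalize) y <- y / max(y)
  d <- data$dose
  df <- data.frame(dose = d, y = y)

  one_fit <- function(st) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) /
          (1 + exp(hill * (lic50 - log(dose)))),
        data = df, start = st,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  best <- NULL
  tried <- 0L
  if (!is.null(start)) {
    tried <- 1L
    fit <- one_fit(list(bottom = start$bottom, top = start$top,
                        lic50 = log(start$ic50), hill = start$hill))
    if (!is.null(fit)) best <- list(fit = fit, rss = sum(stats::resid(fit)^2))
  }
  if (is.null(best)) {
    lic_starts <- stats::quantile(log(d), c(0.2, 0.35, 0.5, 0.65, 0.8),
                                  names = FALSE)
    hill_starts <- c(0.5, 1, 2, -1)
    for (lic in lic_starts) {
      for (h0 in hill_starts) {
        tried <- tried + 1L
        fit <- one_fit(list(bottom = min(y), top = max(y), lic50 = lic,
                            hill = h0))
        if (!is.null(fit)) {
          rss <- sum(stats::resid(fit)^2)
          if (is.null(best) || rss < best$rss - 1e-12) {
            best <- list(fit = fit, rss = rss)
          }
        }
      }
    }
  }
  if (is.null(best)) {
    out <- list(bottom = NA_real_, top = NA_real_, ic50 = NA_real_,
                hill = NA_real_, rss = NA_real_, converged = FALSE,
                fitted = NULL, residuals = NULL, data = df,
                n_starts = tried)
    class(out) <- "fourpl_fit"
    return(out)
  }
  cf <- stats::coef(best$fit)
  bottom <- unname(cf["bottom"])
  top <- unname(cf["top"])
  hill <- unname(cf["hill"])
  ic50 <- exp(unname(cf["lic50"]))
  if (bottom > top) {  # equivalent curve with asymptotes in order
    tmp <- bottom; bottom <- top; top <- tmp
    hill <- -hill
  }
  out <- list(bottom = bottom, top = top, ic50 = ic50, hill = hill,
              rss = best$rss, converged = TRUE,
              fitted = as.vector(stats::fitted(best$fit)),
              residuals = as.vector(stats::resid(best$fit)),
              data = df, n_starts = tried)
  class(out) <- "fourpl_fit"
  out
}

#' @export
print.fourpl_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("4PL fit FAILED after %d starts\n", x$n_starts))
  } else {
    cat(sprintf(
      "4PL fit: IC50 = %.4g, hill = %.3f, bottom = %.3f, top = %.3f (RSS %.3g)\n",
      x$ic50, x$hill, x$bottom, x$top, x$rss))
  }
  invisible(x)
}

#' Predict from a 4PL fit
#'
#' @param object a [fit_4pl()] result.
#' @param newdata optional data frame with a `dose` column.
#' @param ... unused.
#' @return predicted responses.
#' @export
predict.fourpl_fit <- function(object, newdata = NULL, ...) {
  stopifnot(object$converged)
  d <- if (is.null(newdata)) object$data$dose else newdata$dose
  fourpl(d, object$bottom, object$top, object$ic50, object$hill)
}

#' Compare two fitted dose-response curves
#'
#' Reports the IC50 ratio (curve B over curve A) and per-dose predicted
#' response differences (B minus A), with confidence intervals from a
#' residual-resampling bootstrap: residuals of each fit are resampled with
#' replacement, added back to that curve's fitted values, and the curve is
#' refitted. With `n_boot = 0` only point estimates are returned.
#'
#' @param fit_a,fit_b converged [fit_4pl()] results.
#' @param n_boot bootstrap resamples (default 200).
#' @param level confidence level.
#' @param seed optional RNG seed.
#' @return list with `ic50_ratio`, `ic50_ratio_ci`, `dose_diff` (data frame
#'   of per-dose differences with CIs), and `n_boot`.
#' @export
compare_dose_response <- function(fit_a, fit_b, n_boot = 200L,
                                  level = 0.95, seed = NULL) {
  stopifnot(inherits(fit_a, "fourpl_fit"), inherits(fit_b, "fourpl_fit"))
  if (!fit_a$converged || !fit_b$converged) {
    stop("cannot compare: at least one 4PL fit did not converge",
         call. = FALSE)
  }
  doses <- sort(unique(c(fit_a$data$dose, fit_b$data$dose)))
  point_ratio <- fit_b$ic50 / fit_a$ic50
  point_diff <- fourpl(doses, fit_b$bottom, fit_b$top, fit_b$ic50,
                       fit_b$hill) -
    fourpl(doses, fit_a$bottom, fit_a$top, fit_a$ic50, fit_a$hill)
  if (n_boot <= 0) {
    return(list(ic50_ratio = point_ratio, ic50_ratio_ci = NULL,
                dose_diff = data.frame(dose = doses, diff = point_diff),
                n_boot = 0L))
  }
  refit <- function(fit) {
    y_star <- fit$fitted + sample(fit$residuals, length(fit$residuals),
                                  replace = TRUE)
    fit_4pl(data.frame(dose = fit$data$dose, response = y_star),
            start = fit[c("bottom", "top", "ic50", "hill")])
  }
  with_seed(seed, {
    ratios <- rep(NA_real_, n_boot)
    diffs <- matrix(NA_real_, nrow = n_boot, ncol = length(doses))
    for (b in seq_len(n_boot)) {
      fa <- refit(fit_a)
      fb <- refit(fit_b)
      if (fa$converged && fb$converged) {
        ratios[b] <- fb$ic50 / fa$ic50
        diffs[b, ] <- fourpl(doses, fb$bottom, fb$top, fb$ic50, fb$hill) -
          fourpl(doses, fa$bottom, fa$top, fa$ic50, fa$hill)
      }
    }
    alpha <- (1 - level) / 2
    ci <- stats::quantile(ratios, c(alpha, 1 - alpha), na.rm = TRUE,
                          names = FALSE)
    dlo <- apply(diffs, 2L, stats::quantile, probs = alpha, na.rm = TRUE)
    dhi <- apply(diffs, 2L, stats::quantile, probs = 1 - alpha,
                 na.rm = TRUE)
    list(ic50_ratio = point_ratio,
         ic50_ratio_ci = ci,
         dose_diff = data.frame(dose = doses, diff = point_diff,
                                lower = dlo, upper = dhi),
         n_boot = as.integer(n_boot))
  })
}
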