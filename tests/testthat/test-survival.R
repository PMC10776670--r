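# Kaplan-Meier, log-rank, Cox partial likelihood and BH adjustment,
# cross-checked against the survival package and stats::p.adjust.

test_that("KM curve reproduces hand-computed toy examples", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(median_survival(km), 2)

  all_cens <- km_estimate(c(2, 5, 9), c(FALSE, FALSE, FALSE))
  expect_length(all_cens$surv, 0)
  expect_true(is.na(median_survival(all_cens)))

  # mixed: censoring at 2 removes one from the risk set at 3
  km2 <- km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(km2$time, c(1, 3))
  expect_equal(km2$surv, c(2 / 3, 0))
  expect_equal(median_survival(km2), 3)
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(7)
  for (i in 1:20) {
    tm <- rexp(sample(5:40, 1))
    km <- km_estimate(tm, rep(TRUE, length(tm)))
    emp <- vapply(km$time, function(tt) mean(tm > tt), numeric(1))
    expect_equal(km$surv, emp)
  }
})

test_that("KM curve is a valid non-increasing step function", {
  set.seed(8)
  for (i in 1:20) {
    d <- random_surv(sample(10:60, 1), tie_prob = i %% 2)
    km <- km_estimate(d$time, d$event)
    expect_true(all(km$surv >= 0 & km$surv <= 1))
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_true(all(diff(km$n_risk) < 0))
  }
})

test_that("median survival uses the <= 0.5 boundary convention", {
  # survival exactly 0.5 after the event at t = 10 -> median is 10
  km <- km_estimate(c(10, 10, 20, 20), c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(km$surv[1], 0.5)
  expect_equal(median_survival(km), 10)
  # curve that never reaches 0.5 -> undefined
  km2 <- km_estimate(c(1, 2, 3, 4), c(TRUE, FALSE, FALSE, FALSE))
  expect_true(is.na(median_survival(km2)))
})

test_that("KM and median agree with survival::survfit", {
  skip_if_not_installed("survival")
  set.seed(9)
  for (i in 1:10) {
    d <- random_surv(40, tie_prob = i %% 2)
    km <- km_estimate(d$time, d$event)
    sf <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
    st <- summary(sf, times = km$time)
    expect_equal(km$surv, st$surv, tolerance = 1e-12)
    expect_equal(unname(summary(sf)$table["median"]), km$median)
  }
})

test_that("log-rank is symmetric, powerful when separated, null when equal", {
  tm <- c(1, 3, 5, 7, 9)
  dup <- logrank_test(c(tm, tm), rep(TRUE, 10), rep(0:1, each = 5))
  expect_equal(dup$chisq, 0)
  expect_equal(dup$p, 1)
  # complete separation: all events in A precede all in B
  lr <- logrank_test(c(1:20, 101:120), rep(TRUE, 40), rep(0:1, each = 20))
  expect_lt(lr$p, 0.001)
  expect_error(logrank_test(1:4, rep(TRUE, 4), rep(1, 4)), "group")
})

test_that("log-rank equals survival::survdiff", {
  skip_if_not_installed("survival")
  set.seed(10)
  for (i in 1:20) {
    d <- random_surv(sample(10:50, 1), tie_prob = i %% 2)
    if (length(unique(d$group)) < 2 || sum(d$event) < 2) next
    lr <- logrank_test(d$time, d$event, d$group)
    sd_ <- survival::survdiff(survival::Surv(d$time, d$event) ~ d$group)
    expect_equal(lr$chisq, sd_$chisq, tolerance = 1e-10)
  }
})

test_that("Cox fit matches survival::coxph for both tie methods", {
  skip_if_not_installed("survival")
  set.seed(12)
  for (i in 1:25) {
    d <- random_surv(sample(15:50, 1), tie_prob = i %% 2)
    x <- rnorm(length(d$time))
    for (ties in c("efron", "breslow")) {
      f <- cox_fit(d$time, d$event, x, ties = ties)
      o <- survival::coxph(survival::Surv(d$time, d$event) ~ x, ties = ties)
      expect_equal(f$beta, unname(coef(o)), tolerance = 1e-7)
      expect_equal(f$se, unname(sqrt(vcov(o)[1, 1])), tolerance = 1e-7)
      expect_equal(f$p, summary(o)$coefficients[1, 5], tolerance = 1e-7)
      expect_equal(f$loglik, o$loglik[2], tolerance = 1e-7)
    }
  }
})

test_that("group-label swap inverts the hazard ratio exactly", {
  set.seed(13)
  for (i in 1:10) {
    d <- random_surv(40)
    f1 <- cox_fit(d$time, d$event, d$group)
    f2 <- cox_fit(d$time, d$event, 1 - d$group)
    expect_equal(f1$hr, 1 / f2$hr, tolerance = 1e-8)
    expect_equal(f1$p, f2$p, tolerance = 1e-10)
  }
})

test_that("partial likelihood never decreases across Newton steps", {
  # step-halving guarantees monotone ascent; optimum beats beta = 0
  set.seed(14)
  for (i in 1:10) {
    d <- random_surv(30)
    x <- rnorm(30)
    f <- cox_fit(d$time, d$event, x)
    expect_true(f$converged)
    expect_gte(f$loglik, f$loglik0 - 1e-12)
  }
})

test_that("perfect separation is flagged as divergence, not an error", {
  # the single event carries the largest covariate: monotone likelihood
  tm <- c(5, 4, 3, 2, 1)
  ev <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  x <- c(10, 9, 1, 1, 1)
  f <- cox_fit(tm, ev, x)
  expect_false(f$converged)
  expect_true(f$diverged)
  expect_error(cox_fit(tm, ev, rep(1, 5)), "covariate")
})

test_that("null Cox fits are calibrated: |beta| rarely exceeds 3 SE", {
  set.seed(15)
  n_large <- 0L
  for (i in 1:200) {
    tm <- rexp(100)
    ev <- rbinom(100, 1, 0.8) == 1
    f <- cox_fit(tm, ev, rnorm(100))
    if (abs(f$beta) > 3 * f$se) n_large <- n_large + 1L
  }
  expect_lte(n_large / 200, 0.03)
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "p")
})

test_that("BH matches p.adjust and is permutation invariant", {
  set.seed(16)
  for (i in 1:50) {
    p <- runif(sample(1:60, 1))
    q <- bh_fdr(p)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-14)
    perm <- sample(seq_along(p))
    expect_equal(bh_fdr(p[perm]), q[perm])
    # monotone non-decreasing in sorted-p order
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})
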