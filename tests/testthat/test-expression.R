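# Delta-Ct quantification and the group-comparison tests.

test_that("delta-Ct expression ratio follows the 2^-dCt rule", {
  expect_equal(relative_expression(24, 24), 1.0)
  expect_equal(relative_expression(25, 24), 0.5)
  expect_equal(relative_expression(22, 24), 4.0)
  expect_error(relative_expression(Inf, 24), "ct_target")
  # strictly decreasing in target Ct, increasing in reference Ct
  ct <- seq(20, 30, 0.5)
  expect_true(all(diff(relative_expression(ct, 25)) < 0))
  expect_true(all(diff(relative_expression(25, ct)) > 0))
})

test_that("rescaling puts the reference median at 1", {
  donors <- c(0.5, 0.95, 1.4)
  expect_equal(rescale_expression(0.95, donors), 1)
  expect_equal(rescale_expression(c(0.33, 0.95), donors) * 0.95,
               c(0.33, 0.95))
})

test_that("exact Mann-Whitney enumeration matches hand-derived values", {
  # all C(4,2) = 6 rank assignments: U = 0 and its mirror U = 4 -> p = 1/3
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1 / 3)
  expect_equal(r$mode, "exact")
  # identical multisets: perfectly symmetric, p = 1 with midranks
  r2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3), mode = "exact")
  expect_equal(r2$p, 1)
})

test_that("Mann-Whitney agrees with the reference implementation", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:9, 1); m <- sample(3:9, 1)
    x <- rnorm(n); y <- rnorm(m, 0.4)
    expect_equal(mann_whitney_u(x, y)$p,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # large samples, ties: normal approximation with tie + continuity correction
  for (i in 1:20) {
    x <- round(rnorm(35), 1); y <- round(rnorm(40, 0.3), 1)
    expect_lt(abs(mann_whitney_u(x, y)$p -
                    suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                                 correct = TRUE)$p.value)),
              1e-6)
  }
})

test_that("exact and approximate Mann-Whitney p converge at n = m = 10", {
  set.seed(21)
  for (i in 1:15) {
    x <- rnorm(10); y <- rnorm(10, runif(1, -1, 1))
    pe <- mann_whitney_u(x, y, mode = "exact")$p
    pa <- mann_whitney_u(x, y, mode = "normal_approx")$p
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("two-sample t statistic matches the closed form", {
  r <- student_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  # equal-variance shift: t = diff / (sp * sqrt(2/n)) with sp = 1, df = 4
  x <- c(1, 2, 3); y <- x + 10
  r2 <- student_t(x, y, variant = "pooled")
  t_closed <- -10 / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(r2$statistic, t_closed)
  expect_equal(r2$df, 4)
  expect_equal(r2$p, 2 * pt(-abs(t_closed), 4))
  # Welch reduces to pooled when sizes and variances are equal
  rw <- student_t(x, y, variant = "welch")
  expect_equal(rw$statistic, r2$statistic)
  expect_equal(rw$df, r2$df)
  expect_error(student_t(c(1, 1), c(1, 1)), "zero variance")
})

test_that("t test agrees with the reference implementation", {
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(12, 0.5, 1.5)
    expect_equal(student_t(x, y)$p, t.test(x, y)$p.value, tolerance = 1e-12)
    expect_equal(student_t(x, y, "pooled")$p,
                 t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("Spearman correlation handles monotone and tied data", {
  expect_equal(spearman_corr(1:5, c(2, 4, 6, 9, 20))$statistic, 1)
  expect_equal(spearman_corr(1:5, -(1:5))$statistic, -1)
  x <- c(1, 2, 2, 3, 4, 4, 5)
  y <- c(2, 1, 3, 3, 5, 4, 6)
  expect_equal(spearman_corr(x, y)$statistic,
               suppressWarnings(cor.test(x, y, method = "spearman")$estimate),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
})

test_that("tests are invariant to sample order and group relabeling", {
  set.seed(41)
  x <- rnorm(12); y <- rnorm(15, 0.8)
  for (f in list(function(a, b) mann_whitney_u(a, b)$p,
                 function(a, b) student_t(a, b)$p)) {
    expect_equal(f(x, y), f(sample(x), sample(y)))
    expect_equal(f(x, y), f(y, x))
  }
  # signed statistics flip consistently under relabeling
  expect_equal(student_t(x, y)$statistic, -student_t(y, x)$statistic)
})

test_that("compare_groups reports pairwise medians, means and stars", {
  set.seed(61)
  d <- data.frame(grp = rep(c("AML", "donor"), c(30, 12)),
                  expr = c(rlnorm(30, log(0.3), 0.6),
                           rlnorm(12, log(0.95), 0.3)))
  cmp <- compare_groups(d, "grp", "expr")
  expect_equal(nrow(cmp), 1L)
  expect_equal(cmp$n_a + cmp$n_b, 42L)
  expect_equal(cmp$median_a, median(d$expr[d$grp == "AML"]))
  expect_true(cmp$stars %in% c("ns", "*", "**", "***", "****"))
  # degenerate: two single-value identical groups -> p = 1, equal medians
  d1 <- data.frame(grp = c("a", "b"), expr = c(2, 2))
  cmp1 <- compare_groups(d1, "grp", "expr")
  expect_equal(cmp1$p, 1)
  expect_equal(cmp1$median_a, cmp1$median_b)
  expect_error(compare_groups(d1[1, ], "grp", "expr"), "levels")
})

test_that("risk-group levels can be merged before comparison", {
  set.seed(51)
  d <- data.frame(eln = sample(c("favorable", "intermediate", "adverse"),
                               60, replace = TRUE),
                  expr = rlnorm(60, -1, 0.7))
  cmp3 <- compare_groups(d, "eln", "expr")
  expect_equal(nrow(cmp3), 3L)  # pairwise over three levels
  cmp2 <- compare_groups(d, "eln", "expr",
                         merge_levels = list(int_adv = c("intermediate",
                                                         "adverse")))
  expect_equal(nrow(cmp2), 1L)
  expect_setequal(c(cmp2$group_a, cmp2$group_b), c("favorable", "int_adv"))
})

test_that("a simulated location shift is detected with high power", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(600 + s)
    aml <- rlnorm(39, log(0.33), 0.8)
    donor <- rlnorm(12, log(0.95), 0.4)
    if (mann_whitney_u(aml, donor)$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
  # and under identical distributions the rejection rate stays near alpha
  fp <- 0L
  for (s in 1:200) {
    set.seed(800 + s)
    if (mann_whitney_u(rnorm(20), rnorm(20))$p < 0.05) fp <- fp + 1L
  }
  expect_lt(fp / 200, 0.1)
})
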