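# Relative expression quantification (delta-Ct) and the group comparisons
# used for cohort contrasts: Mann-Whitney U (exact enumeration or normal
# approximation), two-sample t, and Spearman rank correlation.

#' Relative expression from a Ct pair
#'
#' Converts qRT-PCR threshold cycles into a relative expression ratio with
#' the single-reference 2^-dCt method: `2^-(ct_target - ct_reference)`.
#' One cycle difference corresponds to a factor of two. No calibrator sample
#' is involved; to put ratios on a donor-median scale use
#' [rescale_expression()].
#'
#' @param ct_target,ct_reference threshold cycles for the gene of interest
#'   and the housekeeping reference (e.g. GAPDH); vectors recycle as usual.
#' @return relative expression ratio(s), strictly positive.
#' @examples
#' relative_expression(24, 24)  # 1
#' relative_expression(25, 24)  # 0.5
#' @export
relative_expression <- function(ct_target, ct_reference) {
  check_numeric_vec(ct_target, "ct_target", positive = TRUE)
  check_numeric_vec(ct_reference, "ct_reference", positive = TRUE)
  2^-(ct_target - ct_reference)
}

#' Rescale expression ratios to a reference cohort's median
#'
#' Divides each value by the median of a reference group (typically healthy
#' donors), so that the reference median sits at 1.
#'
#' @param x expression ratios to rescale.
#' @param reference expression ratios of the reference group.
#' @return rescaled values.
#' @export
rescale_expression <- function(x, reference) {
  check_numeric_vec(x, "x", positive = TRUE)
  check_numeric_vec(reference, "reference", positive = TRUE)
  x / stats::median(reference)
}

#' Significance stars
#'
#' The usual four-level convention: `ns`, `*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001, `****` p < 0.0001.
#'
#' @param p p-value(s).
#' @return character vector of star labels.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

group_summary <- function(test, statistic, p, x, y = NULL, extra = list()) {
  out <- c(list(test = test, statistic = statistic, p = p,
                stars = p_stars(p),
                n_x = length(x), n_y = length(y),
                median_x = stats::median(x), mean_x = mean(x),
                median_y = if (is.null(y)) NA_real_ else stats::median(y),
                mean_y = if (is.null(y)) NA_real_ else mean(y)),
           extra)
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s)\n",
              x$test, x$statistic, x$p, x$stars))
  if (!is.na(x$median_y)) {
    cat(sprintf("  n = %d vs %d; median %.3g vs %.3g; mean %.3g vs %.3g\n",
                x$n_x, x$n_y, x$median_x, x$median_y, x$mean_x, x$mean_y))
  }
  invisible(x)
}

# Exact two-sided Mann-Whitney p by full enumeration of all C(n+m, n)
# assignments of the (mid)ranks to the first sample. The null distribution
# of U is symmetric about n*m/2 (complement symmetry), so the two-sided p
# is P(|U - nm/2| >= |u_obs - nm/2|).
mwu_exact_p <- function(r, n, m, u_obs) {
  combs <- utils::combn(n + m, n)
  u_all <- colSums(matrix(r[combs], nrow = n)) - n * (n + 1) / 2
  centre <- n * m / 2
  mean(abs(u_all - centre) >= abs(u_obs - centre) - 1e-9)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. In `auto` mode the exact p-value is computed by
#' full enumeration when both samples have at most 10 observations and there
#' are no ties; otherwise the normal approximation with midrank tie
#' correction and continuity correction is used. `exact` forces enumeration
#' (with midranks if ties are present), `normal_approx` forces the
#' approximation.
#'
#' @param x,y the two samples (non-empty numeric vectors).
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return a `group_comparison` with the U statistic for `x` (number of
#'   (x, y) pairs with x > y, counting ties as 1/2), the p-value and the
#'   mode actually used.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p  # exact: 1/3
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  check_numeric_vec(x, "x")
  check_numeric_vec(y, "y")
  n <- length(x)
  m <- length(y)
  r <- midranks(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = n <= 10L && m <= 10L && !has_ties)
  if (use_exact) {
    p <- mwu_exact_p(r, n, m, u)
    used <- "exact"
  } else {
    nn <- n + m
    tie_tab <- table(c(x, y))
    sigma2 <- n * m / 12 * ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    dev <- max(abs(u - n * m / 2) - 0.5, 0)   # continuity correction
    p <- if (sigma2 <= 0) 1 else 2 * stats::pnorm(-dev / sqrt(sigma2))
    p <- min(p, 1)
    used <- "normal_approx"
  }
  group_summary("mann_whitney_u", u, p, x, y, extra = list(mode = used))
}

#' Two-sample t test
#'
#' Welch (default) or pooled-variance Student t, two-sided.
#'
#' @param x,y samples with at least 2 observations each.
#' @param variant `"welch"` or `"pooled"`.
#' @return a `group_comparison` with the t statistic, degrees of freedom
#'   (`df`) and p-value.
#' @export
student_t <- function(x, y, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  check_numeric_vec(x, "x", min_len = 2L)
  check_numeric_vec(y, "y", min_len = 2L)
  n <- length(x)
  m <- length(y)
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0 && mean(x) == mean(y)) {
    stop("undefined statistic: both samples have zero variance", call. = FALSE)
  }
  if (variant == "pooled") {
    sp2 <- ((n - 1) * vx + (m - 1) * vy) / (n + m - 2)
    se <- sqrt(sp2 * (1 / n + 1 / m))
    df <- n + m - 2
  } else {
    se <- sqrt(vx / n + vy / m)
    df <- (vx / n + vy / m)^2 /
      ((vx / n)^2 / (n - 1) + (vy / m)^2 / (m - 1))
  }
  if (se == 0) {
    stop("undefined statistic: zero pooled variance", call. = FALSE)
  }
  tstat <- (mean(x) - mean(y)) / se
  p <- 2 * stats::pt(-abs(tstat), df = df)
  group_summary("student_t", tstat, p, x, y,
                extra = list(df = df, variant = variant))
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of midranks; the p-value uses the
#' t-distribution approximation on `n - 2` degrees of freedom.
#'
#' @param x,y paired samples, at least 3 pairs.
#' @return a `group_comparison` with `statistic = rho` and the p-value.
#' @export
spearman_corr <- function(x, y) {
  check_numeric_vec(x, "x", min_len = 3L)
  check_that(length(y) == length(x), "y", "must pair with `x`")
  check_numeric_vec(y, "y", min_len = 3L)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("undefined statistic: constant input", call. = FALSE)
  }
  n <- length(x)
  rho <- stats::cor(midranks(x), midranks(y))
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  out <- group_summary("spearman", rho, p, x)
  out$n <- n
  out
}

#' Pairwise group comparisons on a cohort table
#'
#' Compares a numeric column between the levels of a label column, pairwise
#' for more than two levels, reporting per-group sizes, medians and means
#' alongside the test p-value. Rows with a missing label or value are
#' dropped (complete-case, per comparison). Levels can be merged first
#' (e.g. collapsing intermediate and adverse risk into one group) via
#' `merge_levels`.
#'
#' @param cohort a data frame.
#' @param label name of the grouping column.
#' @param value_field name of the numeric column to compare.
#' @param test `"mannwhitney"` or `"t"`.
#' @param merge_levels optional named list: `list(new = c("old1", "old2"))`.
#' @param ... passed to the underlying test.
#' @return data frame with one row per pair: group names, sizes, medians,
#'   means, statistic, p-value and stars.
#' @export
compare_groups <- function(cohort, label, value_field,
                           test = c("mannwhitney", "t"),
                           merge_levels = NULL, ...) {
  test <- match.arg(test)
  check_that(is.data.frame(cohort), "cohort", "must be a data frame")
  check_that(label %in% names(cohort), "label", "column not found")
  check_that(value_field %in% names(cohort), "value_field", "column not found")
  g <- as.character(cohort[[label]])
  v <- cohort[[value_field]]
  keep <- !is.na(g) & g != "" & !is.na(v)
  g <- g[keep]
  v <- v[keep]
  if (!is.null(merge_levels)) {
    for (new in names(merge_levels)) {
      g[g %in% merge_levels[[new]]] <- new
    }
  }
  lev <- sort(unique(g))
  check_that(length(lev) >= 2L, "label", "needs at least 2 non-empty levels")
  pairs <- utils::combn(lev, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- v[g == pr[1L]]
    b <- v[g == pr[2L]]
    cmp <- if (test == "mannwhitney") mann_whitney_u(a, b, ...)
           else student_t(a, b, ...)
    data.frame(label = label, group_a = pr[1L], group_b = pr[2L],
               n_a = length(a), n_b = length(b),
               median_a = stats::median(a), median_b = stats::median(b),
               mean_a = mean(a), mean_b = mean(b),
               test = cmp$test, statistic = cmp$statistic,
               p = cmp$p, stars = cmp$stars)
  })
  do.call(rbind, rows)
}
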