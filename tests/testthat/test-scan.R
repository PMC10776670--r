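# Quartile-restricted cutoff scan: candidate generation, BH across the
# scan, selection rule, subgroup scans and reporting.

test_that("candidate cutoffs follow the linear-interpolation quartiles", {
  cand <- candidate_cutoffs(1:8, scan_config(min_group_size = 1))
  # Q1 = 2.75, Q3 = 6.25 under type-7 quantiles
  expect_equal(cand, c(3, 4, 5, 6))
  expect_error(candidate_cutoffs(rep(2, 10), scan_config()), "empty scan")
  # duplicated values collapse to a single candidate
  cand2 <- candidate_cutoffs(c(1, 2, 2, 2, 2, 2, 2, 8),
                             scan_config(min_group_size = 1))
  expect_equal(cand2, 2)
})

test_that("minimum group size prunes tail candidates", {
  x <- c(1:20)
  all_c <- candidate_cutoffs(x, scan_config(min_group_size = 1))
  pruned <- candidate_cutoffs(x, scan_config(min_group_size = 8))
  expect_true(all(pruned %in% all_c))
  n_low <- vapply(pruned, function(v) sum(x <= v), numeric(1))
  expect_true(all(n_low >= 8 & (20 - n_low) >= 8))
})

test_that("selection takes minimum FDR with highest-HR tie-breaking", {
  tbl <- data.frame(cutoff = c(0.2, 0.3, 0.4),
                    hr = c(1.5, 2.0, 3.0),
                    p = c(0.02, 0.004, 0.005),
                    fdr_q = c(0.20, 0.05, 0.05))
  sel <- select_cutoff(tbl)
  expect_equal(sel$selected$cutoff, 0.4)
  expect_equal(sel$selection_reason, "hr_tiebreak")
  # unique minimum
  tbl$fdr_q <- c(0.20, 0.01, 0.05)
  expect_equal(select_cutoff(tbl)$selection_reason, "unique_min_fdr")
  expect_equal(select_cutoff(tbl)$selected$cutoff, 0.3)
  # residual tie on FDR and HR: lower p, then smaller cutoff
  tbl2 <- data.frame(cutoff = c(0.2, 0.3), hr = c(2, 2),
                     p = c(0.004, 0.004), fdr_q = c(0.05, 0.05))
  expect_equal(select_cutoff(tbl2)$selected$cutoff, 0.2)
})

test_that("scan outcome satisfies its structural invariants", {
  co <- quick_cohort(n = 150, seed = 2)
  sc <- cutoff_scan(co$data)
  r <- sc$results
  expect_equal(r$n_low + r$n_high, rep(sc$n, nrow(r)))
  expect_true(all(r$hr > 0))
  expect_true(all(diff(r$cutoff) > 0))
  # selected FDR is the minimum over the table
  expect_equal(sc$selected$fdr_q, min(r$fdr_q))
  # BH across the scan equals the oracle applied to the p vector
  expect_equal(r$fdr_q, p.adjust(r$p, "BH"), tolerance = 1e-14)
  # attached KM strata split the cohort at the selected cutoff
  expect_equal(sc$km_low$n + sc$km_high$n, sc$n)
  expect_equal(sc$km_low$n,
               sum(co$data$relative_expression <= sc$selected$cutoff))
})

test_that("flipping the low/high coding inverts every HR, p unchanged", {
  co <- quick_cohort(n = 120, seed = 4)
  d <- co$data
  cand <- candidate_cutoffs(d$relative_expression, scan_config())
  for (v in cand[c(1, length(cand) %/% 2, length(cand))]) {
    low <- as.numeric(d$relative_expression <= v)
    f_low <- cox_fit(d$os_time, d$os_event, low)
    f_high <- cox_fit(d$os_time, d$os_event, 1 - low)
    expect_equal(f_low$hr, 1 / f_high$hr, tolerance = 1e-8)
    expect_equal(f_low$p, f_high$p, tolerance = 1e-10)
  }
})

test_that("the scan recovers a planted cutoff and its hazard ratio", {
  co <- generate_cohort(cohort_spec(n_patients = 800, seed = 5,
                                    true_cutoff = 0.33,
                                    true_log_hr_low = log(2)))
  sc <- cutoff_scan(co$data)
  expect_lt(abs(sc$selected$cutoff - 0.33), 0.12)
  expect_lt(abs(sc$selected$hr - 2), 0.5)
  expect_lt(sc$selected$fdr_q, 0.001)
  # HR > 1 encodes "low expression is adverse"
  expect_gt(sc$selected$hr, 1)
})

test_that("cox_wald and logrank p-sources give concordant scans", {
  co <- quick_cohort(n = 200, seed = 6)
  sw <- cutoff_scan(co$data, scan_config())
  sl <- cutoff_scan(co$data, scan_config(p_source = "logrank"))
  expect_equal(sw$results$cutoff, sl$results$cutoff)
  expect_gt(cor(sw$results$p, sl$results$p), 0.99)
})

test_that("subgroup scans isolate a subgroup-specific effect", {
  sp <- cohort_spec(n_patients = 900, seed = 7, true_log_hr_low = 0,
                    subgroup_log_hr = list(flt3_itd = log(2.5)),
                    subgroup_fractions = c(flt3_itd = 0.4))
  co <- generate_cohort(sp)
  scs <- subgroup_scan(co$data, "flt3_itd")
  expect_setequal(names(scs), c("flt3_itd+", "flt3_itd-"))
  expect_lt(scs[["flt3_itd+"]]$selected$fdr_q, 0.01)
  expect_gt(scs[["flt3_itd-"]]$selected$fdr_q,
            scs[["flt3_itd+"]]$selected$fdr_q)
})

test_that("undersized subgroups are skipped with a warning", {
  co <- quick_cohort(n = 100, seed = 8)
  d <- co$data
  d$rare <- c(rep(TRUE, 5), rep(FALSE, 95))
  expect_warning(scs <- subgroup_scan(d, "rare", min_subgroup_n = 30),
                 "skipped")
  expect_false("rare+" %in% names(scs))
  expect_true("rare-" %in% names(scs))
  # single-level flag: one stratum
  d$mono <- TRUE
  scs2 <- subgroup_scan(d, "mono", min_subgroup_n = 30)
  expect_equal(names(scs2), "mono+")
})

test_that("the scan runs on the event-free-survival endpoint", {
  co <- quick_cohort(n = 200, seed = 9)
  sc <- cutoff_scan(co$data, time_col = "efs_time", event_col = "efs_event")
  expect_equal(unname(sc$endpoint["time"]), "efs_time")
  expect_gt(sc$n_event, 0)
})

test_that("scan reports are consistent, serialisable and deterministic", {
  co <- quick_cohort(n = 120, seed = 10)
  sc <- cutoff_scan(co$data)
  rep1 <- scan_report(sc)
  expect_equal(rep1$all$median_survival_low, median_survival(sc$km_low))
  expect_equal(rep1$all$median_survival_high, median_survival(sc$km_high))
  expect_equal(rep1$all$scan_table, sc$results)

  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  scan_report(sc, path = d1)
  scan_report(sc, path = d2)
  j1 <- readLines(file.path(d1, "scan_report.json"))
  j2 <- readLines(file.path(d2, "scan_report.json"))
  expect_identical(j1, j2)
  # round trip: the scan table written out reads back unchanged
  tab <- read.delim(file.path(d1, "scan_table_all.tsv"))
  expect_equal(tab$cutoff, sc$results$cutoff)
  expect_equal(tab$fdr_q, sc$results$fdr_q, tolerance = 1e-12)
})
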