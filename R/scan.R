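# Quartile-restricted exhaustive cutoff scan: every observed expression
# value inside the interquartile range is tried as a low/high threshold,
# each stratification is tested with a single-covariate Cox model, p-values
# are Benjamini-Hochberg adjusted across the whole candidate set, and the
# minimum-FDR cutoff is selected with highest-hazard-ratio tie-breaking.
# The minimum p over many cutoffs is anti-conservative; the FDR step is
# what makes the selected threshold's significance honest.

#' Configuration of a cutoff scan
#'
#' @param lower_quantile,upper_quantile quantile bounds of the candidate
#'   window (defaults: the interquartile range).
#' @param min_group_size smallest stratum size a candidate may produce
#'   (default 10); prevents degenerate tail strata.
#' @param p_source `"cox_wald"` (default) for the Wald p of the Cox fit, or
#'   `"logrank"` for the score test with Breslow ties (identical to the
#'   two-group log-rank test).
#' @param ties Cox tie handling, `"efron"` (default) or `"breslow"`;
#'   forced to `"breslow"` when `p_source = "logrank"`.
#' @param fdr_alpha significance level applied to the selected cutoff's
#'   adjusted q-value when reporting.
#' @return object of class `"scan_config"`. The quantile convention (linear
#'   interpolation between order statistics, R type 7) is recorded in the
#'   config because the convention changes the candidate set.
#' @export
scan_config <- function(lower_quantile = 0.25, upper_quantile = 0.75,
                        min_group_size = 10L,
                        p_source = c("cox_wald", "logrank"),
                        ties = c("efron", "breslow"),
                        fdr_alpha = 0.05) {
  p_source <- match.arg(p_source)
  ties <- match.arg(ties)
  check_number(lower_quantile, "lower_quantile", lower = 0, upper = 1)
  check_number(upper_quantile, "upper_quantile", lower = 0, upper = 1)
  check_that(lower_quantile < upper_quantile, "lower_quantile",
             "must be < upper_quantile")
  check_number(min_group_size, "min_group_size", lower = 1)
  check_number(fdr_alpha, "fdr_alpha", lower = 0, upper = 1)
  if (p_source == "logrank") ties <- "breslow"
  out <- list(lower_quantile = lower_quantile,
              upper_quantile = upper_quantile,
              min_group_size = as.integer(min_group_size),
              p_source = p_source, ties = ties,
              fdr_alpha = fdr_alpha,
              quantile_convention = "linear_interpolation_type7")
  class(out) <- "scan_config"
  out
}

#' Candidate cutoffs within the interquartile window
#'
#' Sorted unique observed expression values `v` with `Q1 <= v <= Q3`
#' (quantiles by linear interpolation, R type 7). Each candidate defines
#' strata low = `{expr <= v}`, high = `{expr > v}`; candidates whose strata
#' would fall below `min_group_size` are removed. Observed values are the
#' only points at which the stratification changes, so scanning them is
#' exhaustive.
#'
#' @param expression expression ratios (>= 4 values).
#' @param config a [scan_config()].
#' @return numeric vector of candidate cutoffs.
#' @examples
#' candidate_cutoffs(1:8, scan_config(min_group_size = 1))  # 3 4 5 6
#' @export
candidate_cutoffs <- function(expression, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  check_numeric_vec(expression, "expression", min_len = 4L)
  qs <- stats::quantile(expression,
                        c(config$lower_quantile, config$upper_quantile),
                        type = 7, names = FALSE)
  cand <- sort(unique(expression))
  cand <- cand[cand >= qs[1L] & cand <= qs[2L]]
  if (length(cand)) {
    n <- length(expression)
    n_low <- vapply(cand, function(v) sum(expression <= v), numeric(1))
    keep <- n_low >= config$min_group_size &
      (n - n_low) >= config$min_group_size
    cand <- cand[keep]
  }
  if (!length(cand)) {
    stop("empty scan: no candidate cutoff between the quartiles satisfies ",
         "the minimum group size", call. = FALSE)
  }
  cand
}

#' Select the optimal cutoff from a scan table
#'
#' The selection rule of the scan, exposed on its own so it can be applied
#' to any table of per-cutoff results: take the minimum adjusted q-value;
#' among cutoffs tied on FDR, prefer the highest hazard ratio; residual
#' ties break by lower raw p, then by smaller cutoff (deterministic).
#'
#' @param results data frame with columns `cutoff`, `hr`, `p`, `fdr_q`
#'   (rows with missing `fdr_q` are ineligible).
#' @return list with `selected` (the chosen row) and `selection_reason`
#'   (`"unique_min_fdr"` or `"hr_tiebreak"`).
#' @export
select_cutoff <- function(results) {
  check_that(is.data.frame(results) &&
               all(c("cutoff", "hr", "p", "fdr_q") %in% names(results)),
             "results", "needs columns cutoff, hr, p, fdr_q")
  elig <- which(is.finite(results$fdr_q))
  check_that(length(elig) >= 1L, "results", "no eligible cutoff")
  qmin <- min(results$fdr_q[elig])
  tied <- elig[abs(results$fdr_q[elig] - qmin) < 1e-12]
  if (length(tied) == 1L) {
    return(list(selected = results[tied, , drop = FALSE],
                selection_reason = "unique_min_fdr"))
  }
  hrmax <- max(results$hr[tied])
  tied <- tied[abs(results$hr[tied] - hrmax) < 1e-12]
  tied <- tied[order(results$p[tied], results$cutoff[tied])]
  list(selected = results[tied[1L], , drop = FALSE],
       selection_reason = "hr_tiebreak")
}

#' Exhaustive quartile-restricted cutoff scan
#'
#' For every candidate cutoff (see [candidate_cutoffs()]) the cohort is
#' split into low (`expr <= cutoff`) and high strata and a single-covariate
#' Cox proportional-hazards model is fitted with the low stratum coded 1,
#' so HR > 1 means low expression is adverse. P-values (Cox Wald by
#' default, log-rank optionally) are Benjamini-Hochberg adjusted across the
#' whole candidate set of this scan (the FDR family is one scan: one
#' marker, one cohort, one endpoint). The minimum-FDR cutoff is selected
#' with highest-HR tie-breaking, and Kaplan-Meier curves of the selected
#' strata are attached. Cutoffs whose Cox fit fails to converge are kept in
#' the table but excluded from selection, with a warning.
#'
#' @param data data frame with expression, time and event columns; rows
#'   with missing values in those columns are dropped (complete-case).
#' @param config a [scan_config()].
#' @param expr_col,time_col,event_col column names (defaults
#'   `relative_expression`, `os_time`, `os_event`; pass `efs_time` /
#'   `efs_event` for the event-free-survival endpoint).
#' @param subgroup label recorded in the outcome (`"all"` for an
#'   unstratified scan).
#' @return object of class `"scan_outcome"`: `results` (the full scan table
#'   ordered by cutoff: cutoff, n_low, n_high, hr, p, fdr_q, converged),
#'   `selected`, `selection_reason`, `km_low`, `km_high`, `config`,
#'   `subgroup`, `endpoint`, `n`, `n_event`.
#' @examples
#' co <- generate_cohort(cohort_spec(n_patients = 120, seed = 11))
#' sc <- cutoff_scan(co$data, scan_config())
#' sc$selected
#' @export
cutoff_scan <- function(data, config = scan_config(),
                        expr_col = "relative_expression",
                        time_col = "os_time", event_col = "os_event",
                        subgroup = "all") {
  stopifnot(inherits(config, "scan_config"))
  check_that(is.data.frame(data), "data", "must be a data frame")
  for (cl in c(expr_col, time_col, event_col)) {
    check_that(cl %in% names(data), "data",
               sprintf("column '%s' not found", cl))
  }
  keep <- stats::complete.cases(data[, c(expr_col, time_col, event_col)])
  expr <- data[[expr_col]][keep]
  time <- data[[time_col]][keep]
  event <- as.logical(data[[event_col]][keep])
  check_that(sum(event) >= 2L, "data", "needs at least 2 events")

  cand <- candidate_cutoffs(expr, config)
  prep <- cox_prep(time, event)
  expr_s <- expr[prep$ord]

  n_cand <- length(cand)
  hr <- p <- numeric(n_cand)
  n_low <- n_high <- integer(n_cand)
  converged <- logical(n_cand)
  beta_warm <- 0
  for (i in seq_len(n_cand)) {
    x <- as.numeric(expr_s <= cand[i])
    n_low[i] <- as.integer(sum(x))
    n_high[i] <- length(x) - n_low[i]
    fit <- tryCatch(
      cox_fit_prepped(prep, x, ties = config$ties, init = beta_warm),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      hr[i] <- if (is.null(fit)) NA_real_ else fit$hr
      p[i] <- NA_real_
      converged[i] <- FALSE
      beta_warm <- 0
    } else {
      hr[i] <- fit$hr
      p[i] <- if (config$p_source == "logrank") fit$score_p else fit$p
      converged[i] <- TRUE
      beta_warm <- fit$beta
    }
  }
  if (any(!converged)) {
    warning(sprintf("%d cutoff(s) excluded from selection (non-convergence)",
                    sum(!converged)))
  }
  check_that(any(converged), "data", "no cutoff produced a converged fit")
  fdr_q <- rep(NA_real_, n_cand)
  fdr_q[converged] <- bh_fdr(p[converged])
  results <- data.frame(cutoff = cand, n_low = n_low, n_high = n_high,
                        hr = hr, p = p, fdr_q = fdr_q,
                        converged = converged)
  sel <- select_cutoff(results)
  low <- expr <= sel$selected$cutoff
  out <- list(results = results,
              selected = sel$selected,
              selection_reason = sel$selection_reason,
              km_low = km_estimate(time[low], event[low]),
              km_high = km_estimate(time[!low], event[!low]),
              config = config, subgroup = subgroup,
              endpoint = c(time = time_col, event = event_col),
              n = length(expr), n_event = sum(event))
  class(out) <- "scan_outcome"
  out
}

#' @export
print.scan_outcome <- function(x, ...) {
  s <- x$selected
  cat(sprintf(
    paste0("Cutoff scan [%s], endpoint %s: %d candidates, n = %d ",
           "(%d events)\n  selected cutoff %.4g (%s): HR = %.3f, ",
           "p = %.3g, FDR q = %.3g\n  median survival: low %s vs high %s\n"),
    x$subgroup, x$endpoint[["time"]], nrow(x$results), x$n, x$n_event,
    s$cutoff, x$selection_reason, s$hr, s$p, s$fdr_q,
    if (is.na(x$km_low$median)) "not reached" else format(x$km_low$median),
    if (is.na(x$km_high$median)) "not reached" else format(x$km_high$median)))
  invisible(x)
}

#' Independent cutoff scans within mutation subgroups
#'
#' Runs [cutoff_scan()] separately inside the mutation-positive and
#' mutation-negative stratum of each requested flag (e.g. FLT3-ITD+,
#' FLT3-ITD-, NPM1+, ...), on a selectable endpoint. Strata that are
#' undersized, have too few events, or admit no candidate cutoff are
#' skipped with a warning rather than an error. A flag column with a single
#' level yields one stratum.
#'
#' @param data cohort data frame with logical mutation-flag columns.
#' @param flags character vector of flag column names.
#' @param config a [scan_config()].
#' @param expr_col,time_col,event_col as in [cutoff_scan()].
#' @param min_subgroup_n smallest stratum analysed (default 30).
#' @return named list of `scan_outcome` objects, names like `"flt3_itd+"`.
#' @export
subgroup_scan <- function(data, flags, config = scan_config(),
                          expr_col = "relative_expression",
                          time_col = "os_time", event_col = "os_event",
                          min_subgroup_n = 30L) {
  check_that(is.data.frame(data), "data", "must be a data frame")
  check_that(all(flags %in% names(data)), "flags",
             "all flag columns must be present")
  out <- list()
  for (fl in flags) {
    vals <- as.logical(data[[fl]])
    for (lv in sort(unique(vals[!is.na(vals)]), decreasing = TRUE)) {
      name <- paste0(fl, if (lv) "+" else "-")
      sub <- data[!is.na(vals) & vals == lv, , drop = FALSE]
      if (nrow(sub) < min_subgroup_n) {
        warning(sprintf("subgroup %s skipped: n = %d below minimum %d",
                        name, nrow(sub), min_subgroup_n))
        next
      }
      res <- tryCatch(
        cutoff_scan(sub, config, expr_col = expr_col,
                    time_col = time_col, event_col = event_col,
                    subgroup = name),
        error = function(e) {
          warning(sprintf("subgroup %s skipped: %s", name,
                          conditionMessage(e)))
          NULL
        })
      if (!is.null(res)) out[[name]] <- res
    }
  }
  out
}

#' Machine-readable report of scan outcomes
#'
#' Collects full scan tables, selections, stratified median survivals and
#' Kaplan-Meier exports for one or more outcomes into a single list, echoes
#' each scan's configuration, and (optionally) writes it out: one JSON
#' report plus per-outcome `scan_table_<name>.tsv`, `km_low_<name>.tsv`,
#' `km_high_<name>.tsv`. Serialisation is deterministic: identical outcomes
#' give byte-identical JSON.
#'
#' @param outcomes a `scan_outcome` or list of them.
#' @param path optional output directory (created if needed).
#' @return the report list, invisibly when written.
#' @export
scan_report <- function(outcomes, path = NULL) {
  if (inherits(outcomes, "scan_outcome")) outcomes <- list(outcomes)
  check_that(length(outcomes) >= 1L &&
               all(vapply(outcomes, inherits, logical(1), "scan_outcome")),
             "outcomes", "must be scan_outcome objects")
  nm <- names(outcomes) %||% vapply(outcomes, `[[`, "", "subgroup")
  if (is.null(names(outcomes))) names(outcomes) <- nm
  rep_one <- function(o) {
    list(subgroup = o$subgroup,
         endpoint = as.list(o$endpoint),
         n = o$n, n_event = o$n_event,
         config = unclass(o$config),
         selected = as.list(o$selected),
         selection_reason = o$selection_reason,
         significant = isTRUE(o$selected$fdr_q < o$config$fdr_alpha),
         median_survival_low = o$km_low$median,
         median_survival_high = o$km_high$median,
         scan_table = o$results,
         km_low = as.data.frame(o$km_low),
         km_high = as.data.frame(o$km_high))
  }
  report <- lapply(outcomes, rep_one)
  if (!is.null(path)) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(path, "scan_report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    for (nm_i in names(outcomes)) {
      o <- outcomes[[nm_i]]
      safe <- gsub("[^A-Za-z0-9_+-]", "_", nm_i)
      utils::write.table(o$results,
                         file.path(path, sprintf("scan_table_%s.tsv", safe)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(as.data.frame(o$km_low),
                         file.path(path, sprintf("km_low_%s.tsv", safe)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(as.data.frame(o$km_high),
                         file.path(path, sprintf("km_high_%s.tsv", safe)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    return(invisible(report))
  }
  report
}
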