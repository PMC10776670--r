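# Cohort table ingestion/validation, serialisation, and end-to-end pipeline
# orchestration: simulate or load a cohort, filter, then run the requested
# analyses (group comparisons, cutoff scan, subgroup scans, growth, IC50)
# into one reproducible report directory.

# Small deterministic string hash (djb2), used to stamp outputs with the
# configuration that produced them.
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  h <- 5381
  for (ch in utf8ToInt(as.character(s))) {
    h <- (h * 33 + ch) %% 2^28
  }
  sprintf("%07x", h)
}

#' Load a cohort table from delimited text
#'
#' Reads a TSV/CSV cohort file (header required; delimiter inferred from
#' the extension or first line unless given; empty fields and `NA` are
#' missing). Columns can be renamed to the canonical names via `mapping`.
#' If `relative_expression` is absent but `ct_target`/`ct_reference` are
#' present, expression is computed with [relative_expression()]. Rows
#' violating hard invariants (non-positive survival time, non-positive
#' expression) are rejected with a warning naming their line numbers;
#' remaining missing values are left for per-analysis complete-case
#' handling.
#'
#' @param path file path.
#' @param mapping optional named character vector, canonical name ->
#'   file column name, e.g. `c(os_time = "time_months")`.
#' @param delimiter optional field delimiter.
#' @return data frame with attribute `"provenance"` (the file path).
#' @export
load_cohort <- function(path, mapping = NULL, delimiter = NULL) {
  check_that(file.exists(path), "path", "file not found")
  if (is.null(delimiter)) {
    first <- readLines(path, n = 1L)
    delimiter <- if (grepl("\t", first)) "\t" else
      if (grepl(",", first)) "," else "\t"
  }
  dat <- utils::read.table(path, header = TRUE, sep = delimiter,
                           na.strings = c("", "NA"), comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  check_that(nrow(dat) >= 1L, "path", "no data rows")
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      src <- mapping[[canon]]
      check_that(src %in% names(dat), "mapping",
                 sprintf("column '%s' (for '%s') not found", src, canon))
      names(dat)[names(dat) == src] <- canon
    }
  }
  if (!"relative_expression" %in% names(dat) &&
      all(c("ct_target", "ct_reference") %in% names(dat))) {
    dat$relative_expression <-
      relative_expression(dat$ct_target, dat$ct_reference)
  }
  bad <- rep(FALSE, nrow(dat))
  for (cl in intersect(c("os_time", "efs_time"), names(dat))) {
    bad <- bad | (!is.na(dat[[cl]]) & dat[[cl]] <= 0)
  }
  if ("relative_expression" %in% names(dat)) {
    bad <- bad | (!is.na(dat$relative_expression) &
                    dat$relative_expression <= 0)
  }
  if (any(bad)) {
    warning(sprintf("rejected %d invalid row(s) at line(s): %s",
                    sum(bad), paste(which(bad) + 1L, collapse = ", ")))
    dat <- dat[!bad, , drop = FALSE]
  }
  check_that(nrow(dat) >= 1L, "path", "no valid rows after validation")
  attr(dat, "provenance") <- path
  dat
}

#' Write a cohort table
#'
#' Tab-separated text with a header line. For a [generate_cohort()] result
#' the generating spec (ground truth and seed) is written to a sidecar
#' `<path>.meta.json`, keeping ground truth next to, never inside, the
#' data. A write/load round trip preserves all values.
#'
#' @param cohort a data frame or `synthetic_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  meta <- NULL
  if (inherits(cohort, "synthetic_cohort")) {
    meta <- cohort$spec
    cohort <- cohort$data
  }
  check_that(is.data.frame(cohort), "cohort", "must be a data frame")
  utils::write.table(cohort, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(meta)) {
    jsonlite::write_json(unclass(meta), paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' One JSON-serialisable document describing an entire analysis run. The
#' cohort comes either from `input` (a file, with optional `mapping`) or
#' from `simulate` (arguments to [cohort_spec()]). `analyses` is a named
#' list of stages, each a list with a `type` of `"compare"`, `"cutscan"`,
#' `"subgroup_scan"`, `"growth"` or `"ic50"` plus that stage's arguments.
#'
#' @param input optional cohort file path.
#' @param simulate optional list of [cohort_spec()] arguments.
#' @param mapping optional column mapping for `input`.
#' @param exclude_fab_m3 if `TRUE` and a `fab` column exists, drop FAB M3
#'   rows before any analysis (promyelocytic cases filter).
#' @param analyses named list of analysis stages.
#' @param output_dir report directory.
#' @param seed integer seed used for the simulation and any resampling.
#' @param fail_fast abort on the first stage error (default) or record it
#'   and continue.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL, mapping = NULL,
                            exclude_fab_m3 = FALSE, analyses = list(),
                            output_dir = tempfile("exprsurv_report_"),
                            seed = 1L, fail_fast = TRUE) {
  check_that(!is.null(input) || !is.null(simulate), "input",
             "either `input` or `simulate` must be given")
  out <- list(input = input, simulate = simulate, mapping = mapping,
              exclude_fab_m3 = isTRUE(exclude_fab_m3),
              analyses = analyses, output_dir = output_dir,
              seed = as.integer(seed), fail_fast = isTRUE(fail_fast))
  class(out) <- "pipeline_config"
  out
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order on one cohort and writes a
#' report directory containing the echoed configuration (stamped with a
#' deterministic hash and the seed), the cohort used, every stage's tables
#' and JSON reports, and a log of all row exclusions. Identical config and
#' seed produce identical reports (timestamps are confined to the log).
#'
#' @param config a [pipeline_config()], or a path to its JSON form.
#' @return named list of stage results, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cj <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- do.call(pipeline_config, cj)
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  # hash over everything that shapes the results; where the report lands
  # must not change its contents
  hash <- config_hash(unclass(config)[setdiff(names(config), "output_dir")])
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time()), " ", line))
  }

  if (!is.null(config$simulate)) {
    args <- config$simulate
    if (is.null(args$seed)) args$seed <- config$seed
    cohort_obj <- generate_cohort(do.call(cohort_spec, args))
    cohort <- cohort_obj$data
    write_cohort(cohort_obj, file.path(config$output_dir, "cohort.tsv"))
    note("simulated cohort: n = %d, seed = %d", nrow(cohort), args$seed)
  } else {
    cohort <- load_cohort(config$input, mapping = config$mapping)
    write_cohort(cohort, file.path(config$output_dir, "cohort.tsv"))
    note("loaded cohort '%s': n = %d", config$input, nrow(cohort))
  }
  if (config$exclude_fab_m3 && "fab" %in% names(cohort)) {
    n0 <- nrow(cohort)
    cohort <- cohort[is.na(cohort$fab) | cohort$fab != "M3", , drop = FALSE]
    note("FAB M3 filter: excluded %d of %d rows", n0 - nrow(cohort), n0)
  }

  results <- list()
  stage_names <- names(config$analyses) %||%
    vapply(config$analyses, `[[`, "", "type")
  for (i in seq_along(config$analyses)) {
    stage <- config$analyses[[i]]
    nm <- if (!is.null(names(config$analyses)) &&
                nzchar(names(config$analyses)[i])) {
      names(config$analyses)[i]
    } else {
      sprintf("%02d_%s", i, stage$type)
    }
    res <- tryCatch(
      run_stage(stage, cohort, config, nm, hash),
      error = function(e) {
        note("stage %s FAILED: %s", nm, conditionMessage(e))
        if (config$fail_fast) stop(e)
        structure(list(error = conditionMessage(e)), class = "stage_error")
      })
    if (!inherits(res, "stage_error")) note("stage %s completed", nm)
    results[[nm]] <- res
  }

  echo <- unclass(config)
  echo$config_hash <- hash
  jsonlite::write_json(echo, file.path(config$output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  writeLines(log_lines, file.path(config$output_dir, "pipeline.log"))
  invisible(results)
}

# Dispatch one analysis stage; writes its artifacts under the output dir.
run_stage <- function(stage, cohort, config, nm, hash) {
  out_dir <- config$output_dir
  stamp <- sprintf("# exprsurv config_hash=%s seed=%d", hash, config$seed)
  write_tsv_stamped <- function(df, file) {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(stamp, con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  switch(stage$type,
    compare = {
      cmp <- compare_groups(cohort, label = stage$label,
                            value_field = stage$value_field %||%
                              "relative_expression",
                            test = stage$test %||% "mannwhitney")
      write_tsv_stamped(cmp, file.path(out_dir,
                                       sprintf("%s_comparisons.tsv", nm)))
      cmp
    },
    cutscan = {
      cfg <- do.call(scan_config, stage$scan_config %||% list())
      sc <- cutoff_scan(cohort, cfg,
                        expr_col = stage$expr_col %||% "relative_expression",
                        time_col = stage$time_col %||% "os_time",
                        event_col = stage$event_col %||% "os_event")
      scan_report(sc, path = file.path(out_dir, nm))
      sc
    },
    subgroup_scan = {
      cfg <- do.call(scan_config, stage$scan_config %||% list())
      scs <- subgroup_scan(cohort, flags = stage$flags, config = cfg,
                           expr_col = stage$expr_col %||%
                             "relative_expression",
                           time_col = stage$time_col %||% "os_time",
                           event_col = stage$event_col %||% "os_event",
                           min_subgroup_n = stage$min_subgroup_n %||% 30L)
      if (length(scs)) scan_report(scs, path = file.path(out_dir, nm))
      scs
    },
    growth = {
      series <- if (!is.null(stage$input)) {
        utils::read.table(stage$input, header = TRUE, sep = "\t",
                          comment.char = "#")
      } else {
        stage$series
      }
      fit <- fit_doubling_time(series,
                               method = stage$method %||%
                                 "log_linear_regression")
      jsonlite::write_json(c(fit, list(config_hash = hash)),
                           file.path(out_dir, sprintf("%s_growth.json", nm)),
                           auto_unbox = TRUE, digits = NA, na = "null",
                           pretty = TRUE)
      fit
    },
    ic50 = {
      dr <- if (!is.null(stage$input)) {
        utils::read.table(stage$input, header = TRUE, sep = "\t",
                          comment.char = "#")
      } else {
        stage$data
      }
      fit <- fit_4pl(dr, normalize = isTRUE(stage$normalize))
      jsonlite::write_json(
        list(bottom = fit$bottom, top = fit$top, ic50 = fit$ic50,
             hill = fit$hill, rss = fit$rss, converged = fit$converged,
             config_hash = hash),
        file.path(out_dir, sprintf("%s_ic50.json", nm)),
        auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
      fit
    },
    stop(sprintf("unknown analysis type '%s'", stage$type), call. = FALSE)
  )
}
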