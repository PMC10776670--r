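# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Validation: stop with the offending argument named, so callers can see
# which field of a spec/config failed.
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  invisible(TRUE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         finite = TRUE, allow_null = FALSE) {
  if (is.null(x) && allow_null) return(invisible(NULL))
  check_that(is.numeric(x) && length(x) == 1L && !is.na(x), field,
             "must be a single non-missing number")
  if (finite) check_that(is.finite(x), field, "must be finite")
  check_that(x >= lower, field, sprintf("must be >= %g", lower))
  check_that(x <= upper, field, sprintf("must be <= %g", upper))
  invisible(x)
}

check_numeric_vec <- function(x, field, min_len = 1L, positive = FALSE,
                              finite = TRUE) {
  check_that(is.numeric(x) && length(x) >= min_len, field,
             sprintf("must be numeric with at least %d value(s)", min_len))
  check_that(!anyNA(x), field, "must not contain missing values")
  if (finite) check_that(all(is.finite(x)), field, "must be finite")
  if (positive) check_that(all(x > 0), field, "must be strictly positive")
  invisible(x)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so simulation helpers never perturb the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Midranks (average ranks for ties); base rank() with ties.method "average".
midranks <- function(x) rank(x, ties.method = "average")

`%||%` <- function(a, b) if (is.null(a)) b else a
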