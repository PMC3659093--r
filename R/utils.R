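`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global random number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards so library functions do not
#' perturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# round-half-up; base round() rounds half to even
round_half_up <- function(x) floor(x + 0.5)

# full-precision decimal text for a double, so XML round trips are exact
num_str <- function(x) sprintf("%.17g", x)

stop_tma <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop_tma("%s must be a single string", what)
  }
  invisible(x)
}

assert_nonempty_string <- function(x, what) {
  assert_scalar_string(x, what)
  if (!nzchar(x)) stop_tma("%s must be non-empty", what)
  invisible(x)
}

assert_count <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    stop_tma("%s must be a single integer >= %d", what, min)
  }
  invisible(as.integer(x))
}

# path components for the document store: no separators, no traversal
assert_path_safe <- function(x, what) {
  assert_nonempty_string(x, what)
  if (grepl("[/\\\\]", x) || x %in% c(".", "..") || startsWith(x, "_")) {
    stop_tma(
      "%s must be a path-safe name (no slashes, no leading underscore), got '%s'",
      what, x)
  }
  invisible(x)
}

#' Construct a validation result
#'
#' A lightweight container used by the registry, scoring and store modules to
#' report whether a value or record conforms to its governing definition.
#' Invalid values are a *result*, not an error condition.
#'
#' @param valid Logical flag.
#' @param message Explanation; empty when valid.
#' @return An object of class `tma_validation` with fields `valid`, `message`.
#' @export
validation_result <- function(valid, message = "") {
  structure(list(valid = isTRUE(valid), message = message),
            class = "tma_validation")
}

#' @export
print.tma_validation <- function(x, ...) {
  cat(if (x$valid) "valid" else paste0("invalid: ", x$message), "\n")
  invisible(x)
}

#' Current time as an ISO-8601 UTC timestamp
#'
#' The default clock for score records. Tests and deterministic pipelines
#' inject a fixed clock instead.
#'
#' @return A string like `"2013-05-01T12:00:00Z"`.
#' @export
iso_now <- function() {
  format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

is_iso_timestamp <- function(x) {
  is.character(x) && length(x) == 1L &&
    grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}Z?$", x)
}
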