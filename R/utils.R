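`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are not disturbed. With
#' `seed = NULL` the code runs against the ambient RNG unchanged.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_vector = TRUE) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || !all(is.finite(x)))
    stopf("'%s' must be a finite numeric value", name)
  if (!allow_vector && length(x) != 1L)
    stopf("'%s' must be a single number", name)
  lo_ok <- if (strict_lower) all(x > lower) else all(x >= lower)
  if (!lo_ok || !all(x <= upper))
    stopf("'%s' must lie in %s%g, %g]", name,
          if (strict_lower) "(" else "[", lower, upper)
  invisible(x)
}

# comma-grouped whole-dollar formatting; negatives take a leading minus
format_aud <- function(x) {
  sign <- ifelse(x < 0, "-", "")
  paste0(sign, formatC(abs(round(x)), format = "d", big.mark = ","))
}
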