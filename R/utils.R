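# Internal helpers shared across modules.

stop_invalid <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x)))
    stop_invalid("'", name, "' must be finite numeric")
  if (strict_lower) {
    if (any(x <= lower))
      stop_invalid("'", name, "' must be > ", lower)
  } else if (any(x < lower)) {
    stop_invalid("'", name, "' must be >= ", lower)
  }
  if (any(x > upper)) stop_invalid("'", name, "' must be <= ", upper)
  invisible(x)
}

#' Round to the printing precision used in reports
#'
#' Raw values are kept at full precision throughout the package; this
#' formatter rounds to a given number of significant figures (two by
#' default) for report tables.
#'
#' @param x numeric vector.
#' @param digits significant digits.
#' @return numeric vector rounded to `digits` significant figures.
#' @export
report_signif <- function(x, digits = 2) signif(x, digits)

# Evaluate an expression with a temporarily seeded RNG, restoring the
# caller's RNG state afterwards so seeded operations do not perturb the
# global random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stage-specific 31-bit seed from a root seed, so one root seed
# drives every stage without correlated streams.
derive_seed <- function(root_seed, label) {
  digest <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(root_seed) * 69069 + digest) %% 2147483647)
}
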