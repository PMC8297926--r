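# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a dedicated pseudo-random stream derived from
# (seed, stream), restoring the caller's RNG state afterwards. Each output
# table of the generator draws from its own stream, so adding a table never
# perturbs the others. Derived seeds are kept below 2^31.
with_stream <- function(seed, stream, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed((abs(as.integer(seed)) %% 40000000L) * 53L + as.integer(stream))
  force(code)
}

# Inverse-CDF truncated-normal draw: uses exactly n uniforms, which keeps
# stream consumption independent of the acceptance region.
rtruncnorm_icdf <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

stop_named <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "mrsma_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE, allow_equal_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_named("mrsma_validation_error", "'%s' must be a finite numeric scalar", name)
  lo_ok <- if (allow_equal_lower) x >= lower else x > lower
  hi_ok <- if (allow_equal_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok)
    stop_named("mrsma_validation_error", "'%s' = %g is outside its valid range", name, x)
  invisible(x)
}

# z-score against the sample itself; errors (by name) on zero spread.
zscore <- function(x, name = deparse(substitute(x))) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop_named("mrsma_degenerate_error", "component '%s' has zero variance; z-score undefined", name)
  (x - mean(x)) / s
}
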