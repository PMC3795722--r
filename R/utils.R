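# Internal helpers shared across modules.

#' @keywords internal
fc_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "fibrecall_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves going away from zero, the
#' convention that reproduces printed allele-frequency tables (e.g. 3/46 ->
#' 0.07, 5/46 -> 0.11), unlike banker's rounding in [round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Exact truncated-normal draw via inverse CDF; consumes exactly n uniforms so
# simulation streams stay aligned across configurations.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

# Deterministic per-fibre substream seed derived from a cohort seed and a
# running fibre counter (keeps generation reproducible and order-stable).
substream_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 8191 + 1) %%
               2147483629)
}

# Interval intersection length for 0-based half-open intervals.
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
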