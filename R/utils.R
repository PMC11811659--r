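# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Stop with a classed condition so tests can target error families.
stop_input <- function(msg, class = "mcitriage_input_error") {
  abort(msg, class = class)
}

stop_format <- function(msg) {
  abort(msg, class = c("mcitriage_format_error", "mcitriage_input_error"))
}

stop_config <- function(msg) {
  abort(msg, class = c("mcitriage_config_error", "mcitriage_input_error"))
}

stop_degenerate <- function(msg) {
  abort(msg, class = c("mcitriage_degenerate_error", "mcitriage_input_error"))
}

# Clamp a numeric vector to [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Draw from a normal distribution truncated to [lo, hi] by inverse-CDF.
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

# Shoelace polygon area (vertices as two-column matrix, open ring).
polygon_area <- function(verts) {
  x <- verts[, 1]
  y <- verts[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

`%||%` <- rlang::`%||%`
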