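# Internal helpers shared across modules.

# truncate toward zero to one decimal (how field-trial percentage tables
# report rates: 83.673... prints as 83.6)
trunc_1dp <- function(x) trunc(x * 10 + sign(x) * 1e-9) / 10

# assert a scalar condition with a formatted message
stopf <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x >= 0

# clamp numeric vector into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# linear interpolation of X at a given Z along a polyline (Z strictly increasing)
interp_polyline_x <- function(polyline, z) {
  approx(polyline[, 2], polyline[, 1], xout = z, rule = 1)$y
}

# cumulative arc length (mm) along a polyline at each vertex
polyline_arclen <- function(polyline) {
  d <- sqrt(rowSums(diff(polyline)^2))
  c(0, cumsum(d))
}
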