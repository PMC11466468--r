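# Internal helpers shared across modules.

MLC_N_LEAVES <- 64L
MV_N_CHANNELS <- 640L
CHAMBER_LEAVES <- c(27L, 39L, 47L)

assert_fraction <- function(x, name, open_left = FALSE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !lo_ok || !hi_ok) {
    abort(sprintf("`%s` must be a single fraction in %s0, 1%s (got %s).",
                  name, if (open_left) "(" else "[",
                  if (open_right) ")" else "]", format(x)))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    abort(sprintf("`%s` must be a whole number >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Fractional-power ramp whose fluence-equivalent step sits at fraction g of the
# transition: f(u) = u^p with p = g / (1 - g), so that the integral of (1 - f)
# over [0, 1] equals g.
ramp_power <- function(g) {
  assert_fraction(g, "g", open_left = TRUE, open_right = TRUE)
  g / (1 - g)
}

# Integral of ((t - o)/d)^p over [a, b] (clipped to the ramp's support).
ramp_up_integral <- function(a, b, o, d, p) {
  za <- pmin(pmax((a - o) / d, 0), 1)
  zb <- pmin(pmax((b - o) / d, 0), 1)
  d / (p + 1) * (zb^(p + 1) - za^(p + 1)) + pmax(b - pmax(a, o + d), 0)
}

leaf_state_levels <- c("CLOSED", "TRANSITION", "OPEN")
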