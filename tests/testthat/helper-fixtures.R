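# Small in-code fixtures shared across the suite.

# A compact static-gantry plan with the three chamber leaves active.
small_plan <- function(n_proj = 6L, x = 0.5, t_proj = 348, jaw = 2.5) {
  lot <- matrix(0, 64, n_proj)
  lot[c(27L, 39L, 47L), ] <- x * t_proj
  delivery_plan(lot, t_proj_ms = t_proj, jaw_opening_cm = jaw,
                plan_id = sprintf("small_x%g", 100 * x), lot_fraction_x = x)
}

# Single-leaf plan whose commanded LOTs/gaps exercise all three optical
# sequences: a merged-open pair (20 ms commanded gap), a too-short opening
# (10 ms) and a normal pulse.
coverage_plan <- function() {
  lot <- matrix(0, 64, 6)
  lot[27L, ] <- c(200, 200, 0, 10, 0, 200)
  delivery_plan(lot, t_proj_ms = 220, plan_id = "coverage")
}

# Hand-built optical log for one leaf from (time, state) pairs.
log_from_states <- function(times, states, leaf = 1L, resolution = 0) {
  optical_log(tibble::tibble(time_ms = times, leaf = leaf, state = states),
              resolution_ms = resolution)
}

expect_tibble_cols <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}
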