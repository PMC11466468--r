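test_that("discrepancy statistics match brute-force computation", {
  x <- c(100, 150, 200, 260)
  s <- discrepancy_stats(x, x)
  expect_equal(s$mean, 0); expect_equal(s$sd, 0)
  expect_equal(nrow(s$outliers), 0L)

  s2 <- discrepancy_stats(x + 1.8, x)
  expect_equal(s2$mean, 1.8); expect_equal(s2$sd, 0)
  expect_equal(s2$median, 1.8)

  expect_error(discrepancy_stats(1:3, 1:4), "equal length")
})

test_that("a single gross point in a 54-point sample is flagged as outlier", {
  set.seed(50)
  ref <- runif(54, 80, 270)
  calc <- ref + rnorm(54, 0, 0.3)
  calc[17] <- ref[17] + 5.9
  labels <- tibble::tibble(leaf = rep(c(27L, 39L, 47L), 18),
                           plan_id = rep(sprintf("p%d", 1:18), each = 3))
  s <- discrepancy_stats(calc, ref, labels = labels)
  # brute-force fences from the quartiles of the discrepancies
  d <- calc - ref
  q <- quantile(d, c(0.25, 0.75), names = FALSE)
  fence <- c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q))
  expect_equal(sort(s$outliers$value_ms), sort(d[d < fence[1] | d > fence[2]]))
  expect_true(5.9 %in% round(s$outliers$value_ms, 1))
  expect_equal(s$outliers$leaf[which.max(s$outliers$value_ms)], labels$leaf[17])
})

test_that("threshold calibration finds the zero crossing by interpolation", {
  taus <- seq(0.30, 0.70, by = 0.01)
  ref <- tibble::tibble(plan_id = rep(sprintf("p%d", 1:3), each = 3),
                        leaf = rep(c(27L, 39L, 47L), 3),
                        mean_lot_ms = rep(c(87, 174, 261), each = 3))
  # calculated equals reference at tau = 0.5 by construction, slope -45 ms
  calc <- tidyr::crossing(tau = taus, ref) |>
    dplyr::mutate(method = "optical_sensor",
                  mean_lot_ms = mean_lot_ms + (0.5 - tau) * 45)
  cal <- calibrate_threshold(calc, ref)
  expect_equal(cal$tau_star, 0.5, tolerance = 1e-9)
  expect_equal(cal$method, "optical_sensor")
  # curve is monotone, hence the root is unique
  expect_true(all(diff(cal$curve$mean_discrepancy_ms) < 0))

  # evaluating the curve at tau* returns 0 within interpolation tolerance
  at_star <- calc |> dplyr::filter(abs(tau - 0.5) < 1e-9)
  expect_lt(abs(mean_discrepancy(at_star, ref)), 0.05)

  # off-centre crossing lands between the bracketing grid points
  calc2 <- calc |> dplyr::mutate(mean_lot_ms = mean_lot_ms - 0.2)
  cal2 <- calibrate_threshold(calc2, ref)
  expect_true(cal2$tau_star > 0.49 & cal2$tau_star < 0.50)

  # no sign change: advise a wider grid
  calc3 <- calc |> dplyr::mutate(mean_lot_ms = mean_lot_ms + 50)
  expect_error(calibrate_threshold(calc3, ref), "widen the threshold grid")
})

test_that("calibration recovers the generator's fluence-equivalent fraction", {
  # the generator places the fluence-equivalent opening at 60 % of each
  # transition; with unequal transition durations the optical sweep must
  # recover tau* = 0.6
  model <- leaf_motion_model(g_open = 0.6, g_close = 0.6)
  st <- run_reference_study(model, seed = 77, taus = seq(0.30, 0.70, 0.01),
                            methods = "optical_sensor", replicates = 2L,
                            n_projections = 100L)
  cal <- calibrate_threshold(st$calculated, st$reference)
  expect_lt(abs(cal$tau_star - 0.6), 0.02)

  # noiseless symmetric-ramp generator calibrates to 0.5 exactly
  st0 <- run_reference_study(noiseless_motion_model(), seed = 78,
                             taus = seq(0.40, 0.60, 0.05),
                             methods = "optical_sensor", replicates = 1L,
                             n_projections = 20L)
  cal0 <- calibrate_threshold(st0$calculated, st0$reference)
  expect_equal(cal0$tau_star, 0.5, tolerance = 1e-3)
})

test_that("validation statistics match their closed forms", {
  ref <- tibble::tibble(plan_id = sprintf("p%d", 1:5), leaf = 27L,
                        mean_lot_ms = c(87, 130.5, 174, 217.5, 261))
  calc <- ref |> dplyr::mutate(method = "optical_sensor",
                               mean_lot_ms = mean_lot_ms + c(0.2, -0.1, 0.4, 0.0, 0.3))
  v <- validate_methods(calc, ref)
  m <- v$per_method[["optical_sensor"]]
  d <- c(0.2, -0.1, 0.4, 0.0, 0.3)
  expect_equal(m$t_test$statistic, mean(d) / (sd(d) / sqrt(5)),
               tolerance = 1e-12)
  f <- lm(calc$mean_lot_ms ~ ref$mean_lot_ms)
  expect_equal(m$fit$slope, unname(coef(f)[2]))
  expect_equal(m$pearson$r, cor(calc$mean_lot_ms, ref$mean_lot_ms))

  # identical data: perfect correlation, unit slope, zero intercept,
  # degenerate paired t-test (zero-variance differences), not an exception
  calc_id <- ref |> dplyr::mutate(method = "mv_detector")
  v2 <- validate_methods(calc_id, ref)
  m2 <- v2$per_method[["mv_detector"]]
  expect_equal(m2$pearson$r, 1)
  expect_equal(m2$fit$slope, 1)
  expect_equal(m2$fit$intercept_ms, 0, tolerance = 1e-10)
  expect_equal(m2$t_test$decision, "degenerate")

  td <- tidy(v2)
  expect_tibble_cols(td, c("method", "mean_ms", "sd_ms", "pearson_r",
                           "slope", "t_p_value"))
})

test_that("removing flagged outliers changes only the outlier list, not the data", {
  set.seed(51)
  ref <- runif(30, 87, 261)
  calc <- ref + rnorm(30, 0, 0.3)
  calc[4] <- ref[4] + 6
  s <- discrepancy_stats(calc, ref)
  keep <- !(calc - ref) %in% s$outliers$value_ms
  s2 <- discrepancy_stats(calc[keep], ref[keep])
  expect_equal(s2$n, s$n - nrow(s$outliers))
  # the retained pairs are untouched
  expect_equal(calc[keep] - ref[keep], (calc - ref)[keep])
})

test_that("the per-fraction report summarizes short LOTs and discrepancies", {
  lot <- matrix(0, 64, 5)
  lot[27, ] <- c(80, 80, 150, 150, 150)
  lot[39, ] <- c(80, 80, 150, 150, 150)
  plan <- delivery_plan(lot, t_proj_ms = 348, plan_id = "toy")
  performed <- tidy(plan) |> dplyr::mutate(method = "optical_sensor",
                                           tau = 0.5)
  rep1 <- fraction_report(list(fx1 = performed), plan)
  expect_equal(rep1$n_open, 10L)
  expect_equal(rep1$pct_short, 40)        # 4 of 10 nonzero LOTs below 100 ms
  expect_equal(rep1$pct_below_50, 0)      # every planned LOT is >= 50 ms
  expect_equal(rep1$mean_discrepancy_ms, 0)

  shifted <- performed |> dplyr::mutate(lot_ms = ifelse(lot_ms > 0, lot_ms + 2, 0))
  rep2 <- fraction_report(list(fx1 = performed, fx2 = shifted), plan)
  expect_equal(rep2$mean_discrepancy_ms, c(0, 2))

  bad <- performed |> dplyr::filter(projection < 5)
  expect_error(fraction_report(list(fx = bad), plan), "64 x 5")
})
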