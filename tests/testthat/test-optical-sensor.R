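test_that("segmentation reads the three transition sequences", {
  # normal: CLOSED -> TRANSITION -> OPEN -> TRANSITION -> CLOSED
  log <- log_from_states(c(0, 20, 100, 120),
                         c("TRANSITION", "OPEN", "TRANSITION", "CLOSED"))
  ev <- segment_leaf_events(log, 1L)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "normal")
  expect_equal(c(ev$t1, ev$t2, ev$t3, ev$t4), c(0, 20, 100, 120))

  # leaf never reaches open: LOT 0
  log <- log_from_states(c(0, 15), c("TRANSITION", "CLOSED"))
  ev <- segment_leaf_events(log, 1L)
  expect_equal(ev$kind, "no_open")
  expect_equal(lot_from_event(ev, 0.57), 0)

  # two opens separated only by a transition: split at its midpoint
  log <- log_from_states(c(0, 20, 200, 230, 300, 320),
                         c("TRANSITION", "OPEN", "TRANSITION", "OPEN",
                           "TRANSITION", "CLOSED"))
  ev <- segment_leaf_events(log, 1L)
  expect_equal(nrow(ev), 2L)
  expect_true(all(ev$kind == "merged_open"))
  expect_equal(ev$t4[1], 215)
  expect_equal(ev$t1[2], 215)
  expect_equal(ev$t2[2], 230)
})

test_that("malformed logs are rejected with the offending record", {
  log <- log_from_states(c(0, 10), c("TRANSITION", "OPEN"), leaf = 3L)
  bad <- optical_log(tibble::tibble(
    time_ms = c(0, 5), leaf = 3L, state = c("OPEN", "TRANSITION")))
  expect_error(segment_leaf_events(bad, 3L), "record 1")
  expect_error(optical_log(tibble::tibble(time_ms = 0, leaf = 1L,
                                          state = "AJAR")), "unknown state")
  expect_error(optical_log(tibble::tibble(time_ms = c(5, 0), leaf = 1L,
                                          state = c("TRANSITION", "CLOSED"))),
               "non-decreasing")
})

test_that("the threshold-weighted LOT formula evaluates exactly", {
  ev <- tibble::tibble(leaf = 1L, kind = "normal", t1 = 0, t2 = 20, t3 = 100,
                       t4 = 120)
  # equal transition durations cancel the threshold terms
  expect_equal(lot_from_event(ev, 0.57), 100)
  expect_equal(lot_from_event(ev, 0.1), 100)

  ev2 <- tibble::tibble(leaf = 1L, kind = "normal", t1 = 0, t2 = 30, t3 = 100,
                        t4 = 110)
  expect_equal(lot_from_event(ev2, 0.57), (100 + 5.7) - 17.1)
  expect_equal(lot_from_event(ev2, 0), 100)  # t3 - t1 at tau = 0
})

test_that("the event LOT is affine in the threshold and properly bounded", {
  set.seed(42)
  for (i in 1:25) {
    t1 <- runif(1, 0, 50)
    t2 <- t1 + runif(1, 1, 40)
    t3 <- t2 + runif(1, 0, 200)
    t4 <- t3 + runif(1, 1, 40)
    ev <- tibble::tibble(leaf = 1L, kind = "normal",
                         t1 = t1, t2 = t2, t3 = t3, t4 = t4)
    taus <- seq(0, 1, by = 0.1)
    lots <- vapply(taus, function(tt) lot_from_event(ev, tt), numeric(1))
    slope <- (t4 - t3) - (t2 - t1)
    expect_equal(lots, (t3 - t1) + taus * slope, tolerance = 1e-12)
    expect_true(all(lots >= t3 - t2 - 1e-9 & lots <= t4 - t1 + 1e-9))
  }
})

test_that("optical reconstruction assigns events by temporal midpoint", {
  plan <- small_plan(4, x = 0.5)
  dl <- simulate_delivery(plan, noiseless_motion_model(), seed = 21)
  sino <- compute_lots_optical(dl$log, plan, 0.5)
  m <- sinogram_matrix(sino)
  expect_equal(m[c(27, 39, 47), ], matrix(174, 3, 4), tolerance = 1e-9)
  expect_true(all(m[-c(27, 39, 47), ] == 0))

  # empty log: all-zero sinogram
  empty <- optical_log(tibble::tibble(time_ms = numeric(0), leaf = integer(0),
                                      state = character(0)))
  expect_true(all(sinogram_matrix(compute_lots_optical(empty, plan, 0.5)) == 0))
})

test_that("reconstruction is threshold-independent for symmetric transitions", {
  plan <- small_plan(4, x = 0.5)
  model <- noiseless_motion_model(open_transition_ms = 20,
                                  close_transition_ms = 20)
  dl <- simulate_delivery(plan, model, seed = 22)
  l1 <- mean_lots(compute_lots_optical(dl$log, plan, 0.2))$mean_lot_ms
  l2 <- mean_lots(compute_lots_optical(dl$log, plan, 0.8))$mean_lot_ms
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("the coverage plan exercises all three sensor sequences", {
  dl <- simulate_delivery(coverage_plan(), noiseless_motion_model(), seed = 23)
  ev <- segment_leaf_events(dl$log, 27L)
  expect_setequal(unique(ev$kind), c("normal", "merged_open", "no_open"))
  # merged pair shares its split boundary
  merged <- ev[ev$kind == "merged_open", ]
  expect_equal(merged$t4[1], merged$t1[2])
})

test_that("simulated timestamps are quantized to the sensor cycle", {
  dl <- simulate_delivery(small_plan(3), leaf_motion_model(), seed = 24)
  res <- attr(dl$log, "resolution_ms")
  expect_equal(res, 0.18)
  expect_true(all(abs(dl$log$time_ms / res - round(dl$log$time_ms / res)) < 1e-6))
})

test_that("optical logs round-trip through CSV", {
  dl <- simulate_delivery(small_plan(3), leaf_motion_model(), seed = 25)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "log.csv")
  write_optical_log(dl$log, path)
  back <- read_optical_log(path)
  expect_equal(back$time_ms, dl$log$time_ms)
  expect_equal(back$leaf, dl$log$leaf)
  expect_equal(back$state, dl$log$state)
  expect_equal(attr(back, "resolution_ms"), 0.18)
})
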