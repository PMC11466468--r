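test_that("width_at_threshold matches hand-computed pulse geometries", {
  # symmetric triangle sampled at 1 ms: crossings sit on the sampled 0.5s
  expect_equal(width_at_threshold(c(0, 0.5, 1, 0.5, 0), 0:4, c(0, 4), 0.5), 2)

  # trapezoid: rise over [0, 20], flat to 100, fall to 0 at 120
  t <- 0:130
  v <- pmin(pmax(t / 20, 0), 1) * pmin(pmax((120 - t) / 20, 0), 1)
  expect_equal(width_at_threshold(v, t, c(0, 130), 0.42), 111.6 - 8.4,
               tolerance = 1e-12)

  expect_equal(width_at_threshold(rep(0, 50), 0:49, c(0, 49), 0.5), 0)
  expect_error(width_at_threshold(c(0, 1, 0), 0:2, c(-5, 2), 0.5),
               "outside the sampled")
})

test_that("width at threshold is non-increasing in the threshold", {
  set.seed(101)
  t <- seq(0, 200, by = 1000 / 300)
  taus <- seq(0.05, 0.95, by = 0.05)
  for (i in 1:20) {
    rise <- runif(1, 5, 40); fall <- runif(1, 5, 40)
    top0 <- runif(1, 50, 90); top1 <- top0 + runif(1, 10, 80)
    v <- pmin(pmax((t - top0 + rise) / rise, 0), 1) *
      pmin(pmax((top1 + fall - t) / fall, 0), 1)
    w <- vapply(taus, function(tt) width_at_threshold(v, t, range(t), tt),
                numeric(1))
    expect_true(all(diff(w) <= 1e-9))
  }
})

test_that("Richardson-Lucy conserves per-sample flux and inverts the forward model", {
  set.seed(7)
  M <- matrix(runif(64 * 40), 64, 40)
  kern <- c(0.1, 0.8, 0.1)
  u <- richardson_lucy(M, kern, 10)
  expect_lt(max(abs(colSums(u) - colSums(M)) / colSums(M)), 1e-6)
  expect_true(all(u >= 0))

  # forward-convolve a known single-leaf box, then deconvolve it back
  box <- c(rep(0, 10), rep(1, 20), rep(0, 10))
  S <- matrix(0, 64, length(box))
  S[30, ] <- box
  fwd <- 0.8 * S
  fwd[29, ] <- fwd[29, ] + 0.1 * box
  fwd[31, ] <- fwd[31, ] + 0.1 * box
  rec <- richardson_lucy(fwd, kern, 25)
  expect_lt(max(rec[c(29, 31), ]), 0.05)
  expect_equal(rec[30, ], box, tolerance = 0.02)
})

test_that("a constant-offset trace with no open leaf preprocesses to zero", {
  n_t <- 120
  pw <- tibble::tibble(projection = 1:2, start_ms = c(0, 174),
                       end_ms = c(174, 348))
  tr <- mv_trace(matrix(0.07, n_t, 640), 300, pw)
  plan <- delivery_plan(matrix(0, 64, 2), t_proj_ms = 174)
  sig <- preprocess_trace(tr, plan)
  expect_true(all(sig$values == 0))
})

test_that("an opening leaf's central-window maximum normalizes to exactly 1", {
  plan <- small_plan(4)
  dl <- simulate_delivery(plan, noiseless_motion_model(), seed = 5)
  sig <- preprocess_trace(dl$trace, plan)
  pw <- sig$projection_windows
  for (p in 1:4) {
    w0 <- pw$start_ms[p]; w1 <- pw$end_ms[p]
    c_idx <- which(sig$times_ms >= w0 + 0.25 * (w1 - w0) &
                     sig$times_ms <= w1 - 0.25 * (w1 - w0))
    expect_equal(max(sig$values[27, c_idx]), 1)
  }
  # closed leaves are never inflated to amplitude 1
  expect_lt(max(sig$values[10, ]), 0.1)
})

test_that("reconstruction matches a 10x-oversampled brute-force oracle", {
  # noiseless linear transitions: d_open = d_close = 20 ms, no shift
  plan <- small_plan(6, x = 0.5)
  model <- noiseless_motion_model(open_transition_ms = 20,
                                  close_transition_ms = 20)
  dl <- simulate_delivery(plan, model, seed = 2)

  # the oracle builds the commanded trapezoid itself and measures the width
  # on a 3 kHz grid
  latency <- model$latency_ms
  L <- 174; tp <- 348
  brute_width <- function(p, tau) {
    o0 <- (p - 1) * tp + (tp - L) / 2 + latency - 10
    c0 <- (p - 1) * tp + (tp + L) / 2 + latency - 10
    tt <- seq((p - 1) * tp, p * tp, by = 1000 / 3000)
    v <- pmin(pmax((tt - o0) / 20, 0), 1) - pmin(pmax((tt - c0) / 20, 0), 1)
    ab <- which(v >= tau)
    i1 <- ab[1]; i2 <- ab[length(ab)]
    up <- tt[i1 - 1] + (tau - v[i1 - 1]) / (v[i1] - v[i1 - 1]) * diff(tt[1:2])
    dn <- tt[i2] + (v[i2] - tau) / (v[i2] - v[i2 + 1]) * diff(tt[1:2])
    dn - up
  }
  for (tau in c(0.35, 0.5, 0.65)) {
    sg <- compute_lots_mv(dl$trace, plan, tau, leaves = 27L)
    got <- sinogram_matrix(sg)[27, 3]
    expect_equal(got, brute_width(3, tau), tolerance = 0.05)
    # analytic trapezoid width: plateau + (1 - tau) * (d_open + d_close)
    expect_equal(got, (L - 20) + (1 - tau) * 40, tolerance = 0.05)
  }
})

test_that("ideal instant-transition deliveries reconstruct the full projection time", {
  plan <- small_plan(5, x = 1)
  model <- noiseless_motion_model(open_transition_ms = 0,
                                  close_transition_ms = 0)
  dl <- simulate_delivery(plan, model, seed = 3)
  sg <- compute_lots_mv(dl$trace, plan, 0.5)
  m <- sinogram_matrix(sg)
  active <- m[c(27, 39, 47), ]
  expect_true(all(abs(active - 348) <= 1000 / 300 + 1e-9))
  expect_true(all(m[-c(27, 39, 47), ] == 0))
})

test_that("arc spikes are detected and removed before width measurement", {
  plan <- small_plan(6)
  clean <- simulate_delivery(plan, noiseless_motion_model(), seed = 9)
  spiky <- clean
  hit <- c(150, 400, 611)
  spiky$trace$samples[hit, ] <- spiky$trace$samples[hit, ] + 3
  expect_setequal(tomolot:::detect_arcs(spiky$trace$samples), hit)
  sg_clean <- compute_lots_mv(clean$trace, plan, 0.5, leaves = 27L)
  sg_spiky <- compute_lots_mv(spiky$trace, plan, 0.5, leaves = 27L)
  expect_equal(sg_spiky$lot_ms, sg_clean$lot_ms, tolerance = 0.2)
})

test_that("MV trace bundles round-trip through the CSV container", {
  plan <- small_plan(2)
  dl <- simulate_delivery(plan, noiseless_motion_model(), seed = 12)
  dir <- withr::local_tempdir()
  write_trace(dl$trace, dir)
  back <- read_trace(dir)
  expect_equal(back$samples, dl$trace$samples, tolerance = 1e-6)
  expect_equal(back$leaf_channel_map, dl$trace$leaf_channel_map)
  expect_equal(back$projection_windows$end_ms,
               dl$trace$projection_windows$end_ms)
})
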