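#' Parametric leaf-motion model
#'
#' Describes how the pneumatic binary MLC executes a commanded LOT sinogram
#' and how the three telemetry streams observe it. Transitions are modelled as
#' fractional-power transmission ramps: `g_open` / `g_close` set the fraction
#' of each transition at which the fluence-equivalent state change sits
#' (0.5 = linear ramp). The executed fluence-equivalent LOT of a commanded
#' interval is `commanded + lot_shift_ms` plus edge jitter; the optical
#' sensors mark the mechanical transition boundaries, the MV detector sees the
#' cross-talk-convolved transmission sampled at 300 Hz, and the chamber charge
#' is the transmission time-integral.
#'
#' @param open_transition_ms,close_transition_ms Transition durations in ms.
#' @param latency_ms Systematic command-to-motion delay (shifts both edges).
#' @param lot_shift_ms Systematic executed-minus-planned LOT shift in ms
#'   (default +1.8, the magnitude observed on real units).
#' @param jitter_sd_ms Gaussian timing noise per transition edge.
#' @param g_open,g_close Fluence-equivalent state-change fraction of each
#'   transition, in (0, 1); 0.5 gives a linear transmission ramp.
#' @param crosstalk_kernel Non-negative inter-leaf point-spread function
#'   (odd length, sums to 1).
#' @param mv_noise_sd Detector noise SD in normalized fluence units.
#' @param offset_level Constant detector offset (leakage + dark current), a.u.
#' @param arcing_rate_hz Poisson rate of full-channel single-sample arc spikes.
#' @param arc_amplitude Spike amplitude, a.u.
#' @param charge_noise_rel Relative noise of each chamber charge reading.
#' @param min_close_time_ms Commanded closed gap below which the leaf does not
#'   fully close (merged-open sensor sequence).
#' @param leakage Transmission fraction through a closed leaf (affects
#'   chamber charges only; default 0).
#' @param sensor_resolution_ms Optical sensor cycle time; event timestamps are
#'   quantized to this grid (0 disables quantization).
#' @return An object of class `leaf_motion_model` (a named list).
#' @export
leaf_motion_model <- function(open_transition_ms = 20,
                              close_transition_ms = 25,
                              latency_ms = 2,
                              lot_shift_ms = 1.8,
                              jitter_sd_ms = 0.3,
                              g_open = 0.5,
                              g_close = 0.5,
                              crosstalk_kernel = c(0.1, 0.8, 0.1),
                              mv_noise_sd = 0.01,
                              offset_level = 0.05,
                              arcing_rate_hz = 0.02,
                              arc_amplitude = 3,
                              charge_noise_rel = 0.001,
                              min_close_time_ms = 50,
                              leakage = 0,
                              sensor_resolution_ms = 0.18) {
  assert_fraction(g_open, "g_open", open_left = TRUE, open_right = TRUE)
  assert_fraction(g_close, "g_close", open_left = TRUE, open_right = TRUE)
  if (open_transition_ms < 0 || close_transition_ms < 0) {
    abort("transition durations must be >= 0.")
  }
  if (length(crosstalk_kernel) %% 2L != 1L || any(crosstalk_kernel < 0) ||
      sum(crosstalk_kernel) <= 0) {
    abort("`crosstalk_kernel` must be non-negative with odd length and positive mass.")
  }
  structure(list(
    open_transition_ms = open_transition_ms,
    close_transition_ms = close_transition_ms,
    latency_ms = latency_ms, lot_shift_ms = lot_shift_ms,
    jitter_sd_ms = jitter_sd_ms, g_open = g_open, g_close = g_close,
    crosstalk_kernel = crosstalk_kernel / sum(crosstalk_kernel),
    mv_noise_sd = mv_noise_sd, offset_level = offset_level,
    arcing_rate_hz = arcing_rate_hz, arc_amplitude = arc_amplitude,
    charge_noise_rel = charge_noise_rel,
    min_close_time_ms = min_close_time_ms, leakage = leakage,
    sensor_resolution_ms = sensor_resolution_ms
  ), class = "leaf_motion_model")
}

#' A fully deterministic motion model
#'
#' Convenience variant of [leaf_motion_model()] with every stochastic and
#' quantization term switched off (and no systematic LOT shift unless given),
#' used to check exact agreement between the three telemetry streams.
#'
#' @param ... Overrides passed on to [leaf_motion_model()].
#' @export
noiseless_motion_model <- function(...) {
  defaults <- list(jitter_sd_ms = 0, mv_noise_sd = 0, offset_level = 0,
                   arcing_rate_hz = 0, charge_noise_rel = 0,
                   sensor_resolution_ms = 0, lot_shift_ms = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(leaf_motion_model, args)
}

# ---- leaf trajectory ------------------------------------------------------

# Transmission trajectories are piecewise: power-law rises, flat plateaus,
# power-law falls. Each segment carries its ramp origin `o`, full-scale
# duration `d` and exponent `p` so values and integrals have closed forms.

seg_collector <- function() {
  env <- new.env(parent = emptyenv())
  env$kind <- character(0); env$t0 <- env$t1 <- env$o <- env$d <- env$p <- numeric(0)
  env
}

seg_add <- function(env, kind, t0, t1, o = NA_real_, d = NA_real_, p = NA_real_) {
  if (t1 <= t0) return(invisible(env))
  env$kind <- c(env$kind, kind)
  env$t0 <- c(env$t0, t0); env$t1 <- c(env$t1, t1)
  env$o <- c(env$o, o); env$d <- c(env$d, d); env$p <- c(env$p, p)
  invisible(env)
}

# Build the realized trajectory of one leaf from its merged commanded open
# segments. Returns the transmission segments plus the optical state-change
# record times.
leaf_trajectory <- function(starts, ends, model) {
  d_o <- model$open_transition_ms; d_c <- model$close_transition_ms
  g_o <- model$g_open; g_c <- model$g_close
  p_o <- ramp_power(g_o); p_c <- ramp_power(g_c)
  n <- length(starts)
  jit <- if (model$jitter_sd_ms > 0) rnorm(2 * n, 0, model$jitter_sd_ms) else numeric(2 * n)
  T_open <- starts + model$latency_ms - model$lot_shift_ms / 2 + jit[seq_len(n) * 2 - 1]
  T_close <- ends + model$latency_ms + model$lot_shift_ms / 2 + jit[seq_len(n) * 2]
  min_open <- (1 - g_o) * d_o + g_c * d_c
  open_ok <- (T_close - T_open) >= min_open

  segs <- seg_collector()
  ev_t <- numeric(0); ev_s <- character(0)
  emit <- function(t, s) { ev_t <<- c(ev_t, t); ev_s <<- c(ev_s, s) }

  pending_reopen <- NA_real_  # completion time of a merged reopening
  for (k in seq_len(n)) {
    if (!open_ok[k]) {
      # leaf starts opening but reverses before reaching the open state
      o0 <- T_open[k] - g_o * d_o
      t_m <- (T_open[k] + T_close[k]) / 2
      if (d_o > 0 && t_m > o0) {
        u_m <- min((t_m - o0) / d_o, 0.999)
        rise_end <- o0 + u_m * d_o
        f_m <- u_m^p_o
        seg_add(segs, "up", o0, rise_end, o = o0, d = d_o, p = p_o)
        if (d_c > 0) {
          c0p <- rise_end - d_c * (1 - f_m)^(1 / p_c)
          seg_add(segs, "down", rise_end, c0p + d_c, o = c0p, d = d_c, p = p_c)
          fall_end <- c0p + d_c
        } else fall_end <- rise_end
        emit(o0, "TRANSITION"); emit(fall_end, "CLOSED")
      }
      next
    }
    if (is.na(pending_reopen)) {
      o0 <- T_open[k] - g_o * d_o
      rise_end <- o0 + d_o
      if (d_o > 0) seg_add(segs, "up", o0, rise_end, o = o0, d = d_o, p = p_o)
      emit(o0, "TRANSITION"); emit(rise_end, "OPEN")
    } else {
      rise_end <- pending_reopen
      emit(rise_end, "OPEN")
      pending_reopen <- NA_real_
    }
    c0 <- max(T_close[k] - g_c * d_c, rise_end)
    seg_add(segs, "flat", rise_end, c0)
    merged_next <- k < n && open_ok[k + 1] && d_o > 0 && d_c > 0 &&
      (T_open[k + 1] - T_close[k]) < model$min_close_time_ms
    if (merged_next) {
      t_m <- max((T_close[k] + T_open[k + 1]) / 2, c0 + 1e-9)
      u_f <- min((t_m - c0) / d_c, 0.999)
      f_m <- 1 - u_f^p_c
      seg_add(segs, "down", c0, t_m, o = c0, d = d_c, p = p_c)
      a_p <- t_m - d_o * f_m^(1 / p_o)
      seg_add(segs, "up", t_m, a_p + d_o, o = a_p, d = d_o, p = p_o)
      emit(c0, "TRANSITION")
      pending_reopen <- a_p + d_o
    } else {
      if (d_c > 0) seg_add(segs, "down", c0, c0 + d_c, o = c0, d = d_c, p = p_c)
      emit(c0, "TRANSITION"); emit(c0 + d_c, "CLOSED")
    }
  }
  list(segments = segs, event_times = ev_t, event_states = ev_s)
}

# Evaluate the piecewise transmission on a uniform sample grid times[j] =
# (j - 1) * dt. Index arithmetic keeps this O(total samples).
eval_segments <- function(segs, n_times, dt) {
  f <- numeric(n_times)
  for (i in seq_along(segs$kind)) {
    j0 <- max(ceiling(segs$t0[i] / dt + 1 - 1e-9), 1L)
    j1 <- min(floor(segs$t1[i] / dt + 1 - 1e-9), n_times)
    if (j1 < j0) next
    tt <- (seq.int(j0, j1) - 1) * dt
    f[j0:j1] <- switch(segs$kind[i],
      flat = 1,
      up = pmin(pmax((tt - segs$o[i]) / segs$d[i], 0), 1)^segs$p[i],
      down = 1 - pmin(pmax((tt - segs$o[i]) / segs$d[i], 0), 1)^segs$p[i])
  }
  f
}

# Integral of the transmission over [a, b].
integrate_segments <- function(segs, a, b) {
  tot <- 0
  for (i in seq_along(segs$kind)) {
    lo <- max(a, segs$t0[i]); hi <- min(b, segs$t1[i])
    if (hi <= lo) next
    tot <- tot + switch(segs$kind[i],
      flat = hi - lo,
      up = ramp_up_integral(lo, hi, segs$o[i], segs$d[i], segs$p[i]),
      down = (hi - lo) - ramp_up_integral(lo, hi, segs$o[i], segs$d[i], segs$p[i]))
  }
  tot
}

# ---- delivery simulation --------------------------------------------------

#' Simulate a delivery: MV trace, optical log, chamber charges, ground truth
#'
#' Executes a [delivery_plan()] under a [leaf_motion_model()]. Commanded open
#' intervals are centered in their projection windows; contiguous commands
#' merge into one interval. The returned ground-truth sinogram holds each
#' leaf's fluence-equivalent LOT per projection (the time-integral of its
#' transmission within the window), which is the quantity the chamber
#' charge-ratio method measures by construction.
#'
#' @param plan A [delivery_plan()].
#' @param model A [leaf_motion_model()].
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   deliveries.
#' @param replicate Replicate delivery index recorded in the charge records.
#' @param unit_id Treatment-unit label recorded in the charge records.
#' @param streams Which telemetry streams to generate (subset of `"trace"`,
#'   `"log"`, `"charges"`); the ground truth is always computed.
#' @return An object of class `synthetic_delivery`: a list with elements
#'   `plan`, `model`, `replicate`, `truth` (long sinogram tibble), `trace`
#'   (an `mv_trace` or `NULL`), `log` (optical event tibble or `NULL`) and
#'   `charges` (tibble or `NULL`).
#' @export
simulate_delivery <- function(plan, model = leaf_motion_model(), seed = NULL,
                              replicate = 1L, unit_id = "SIM1",
                              streams = c("trace", "log", "charges")) {
  validate_plan(plan)
  streams <- match.arg(streams, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  P <- plan$n_projections; tp <- plan$t_proj_ms
  total <- P * tp
  leaves <- active_leaves(plan)
  jaw_factor <- plan$jaw_opening_cm / 2.5

  trajs <- vector("list", length(leaves))
  names(trajs) <- as.character(leaves)
  for (li in seq_along(leaves)) {
    L <- plan$planned_lot[leaves[li], ]
    idx <- which(L > 0)
    c0 <- (idx - 1) * tp + (tp - L[idx]) / 2
    c1 <- c0 + L[idx]
    # merge contiguous commanded intervals (x = 100% plans)
    keep_start <- c(TRUE, c0[-1] - c1[-length(c1)] > 1e-9)
    starts <- c0[keep_start]
    ends <- c1[cumsum(keep_start) |> (\(g) tapply(seq_along(g), g, max))() |> as.integer()]
    trajs[[li]] <- leaf_trajectory(starts, ends, model)
  }

  # ground truth: fluence-equivalent LOT per (leaf, projection)
  truth_m <- matrix(0, MLC_N_LEAVES, P)
  for (li in seq_along(leaves)) {
    segs <- trajs[[li]]$segments
    for (i in seq_along(segs$kind)) {
      p0 <- max(floor(segs$t0[i] / tp) + 1L, 1L)
      p1 <- min(floor((segs$t1[i] - 1e-12) / tp) + 1L, P)
      for (pp in seq.int(p0, length.out = max(p1 - p0 + 1L, 0L))) {
        truth_m[leaves[li], pp] <- truth_m[leaves[li], pp] +
          integrate_segments(
            list(kind = segs$kind[i], t0 = segs$t0[i], t1 = segs$t1[i],
                 o = segs$o[i], d = segs$d[i], p = segs$p[i]),
            (pp - 1) * tp, pp * tp)
      }
    }
  }
  truth <- new_lot_sinogram(plan, "truth", NULL, truth_m)

  trace <- log <- charges <- NULL

  if ("trace" %in% streams) {
    dt <- 1000 / 300
    pad <- model$latency_ms + model$open_transition_ms +
      model$close_transition_ms + abs(model$lot_shift_ms) + 20
    n_t <- floor((total + pad) / dt) + 1L
    s_leaf <- matrix(0, MLC_N_LEAVES, n_t)
    for (li in seq_along(leaves)) {
      s_leaf[leaves[li], ] <- eval_segments(trajs[[li]]$segments, n_t, dt)
    }
    s_x <- convolve_leaves(s_leaf * jaw_factor, model$crosstalk_kernel)
    S <- matrix(0, n_t, MV_N_CHANNELS)
    ch_map <- mv_leaf_channel_map()
    hot <- which(rowSums(s_x) > 0)
    for (k in hot) {
      jj <- seq.int(ceiling(ch_map[k] - 5), floor(ch_map[k] + 5))
      jj <- jj[jj >= 1 & jj <= MV_N_CHANNELS]
      w <- 1 - abs(jj - ch_map[k]) / 5
      for (m in seq_along(jj)) S[, jj[m]] <- S[, jj[m]] + w[m] * s_x[k, ]
    }
    S <- S + model$offset_level
    if (model$mv_noise_sd > 0) {
      S <- S + rnorm(length(S), 0, model$mv_noise_sd)
    }
    if (model$arcing_rate_hz > 0) {
      n_arc <- rpois(1, model$arcing_rate_hz * total / 1000)
      if (n_arc > 0) {
        idx <- unique(pmax(2L, pmin(n_t - 1L, ceiling(runif(n_arc) * n_t))))
        S[idx, ] <- S[idx, ] + model$arc_amplitude
      }
    }
    trace <- mv_trace(
      samples = S, sample_rate_hz = 300,
      projection_windows = tibble(projection = seq_len(P),
                                  start_ms = (seq_len(P) - 1) * tp,
                                  end_ms = seq_len(P) * tp),
      leaf_channel_map = ch_map)
  }

  if ("log" %in% streams) {
    recs <- list_rbind(c(
      list(tibble(time_ms = numeric(0), leaf = integer(0),
                  state = character(0))),
      imap(trajs, function(tr, leaf) {
        tibble(time_ms = tr$event_times, leaf = as.integer(leaf),
               state = tr$event_states)
      })))
    res <- model$sensor_resolution_ms
    if (nrow(recs) > 0 && res > 0) {
      recs$time_ms <- round(recs$time_ms / res) * res
    }
    recs <- recs |> arrange(.data$time_ms, .data$leaf)
    log <- optical_log(recs, resolution_ms = res)
  }

  if ("charges" %in% streams) {
    # the chambers sit on the beamlet paths of leaves 27/39/47 and read a
    # charge for every delivery, including all-closed ones (leakage only)
    q <- vapply(CHAMBER_LEAVES, function(lf) {
      tr <- trajs[[as.character(lf)]]
      open_int <- if (is.null(tr)) 0 else integrate_segments(tr$segments, -Inf, Inf)
      (1 - model$leakage) * open_int + model$leakage * total
    }, numeric(1))
    q <- q * jaw_factor
    if (model$charge_noise_rel > 0) {
      q <- q * (1 + rnorm(length(q), 0, model$charge_noise_rel))
    }
    charges <- tibble(
      unit_id = unit_id, chamber = seq_along(CHAMBER_LEAVES),
      leaf = CHAMBER_LEAVES, jaw_cm = plan$jaw_opening_cm,
      x_fraction = plan$lot_fraction_x %||% NA_real_,
      replicate = as.integer(replicate), plan_id = plan$plan_id,
      charge = q)
  }

  structure(list(plan = plan, model = model, replicate = as.integer(replicate),
                 unit_id = unit_id, truth = truth, trace = trace, log = log,
                 charges = charges),
            class = "synthetic_delivery")
}

#' @export
print.synthetic_delivery <- function(x, ...) {
  cat(sprintf("<synthetic_delivery> plan %s (replicate %d, unit %s)\n",
              x$plan$plan_id, x$replicate, x$unit_id))
  cat(sprintf("  streams: %s\n", paste(
    c("truth", "trace", "log", "charges")[!vapply(
      x[c("truth", "trace", "log", "charges")], is.null, TRUE)],
    collapse = ", ")))
  invisible(x)
}

#' Ground-truth mean LOT of an active leaf
#'
#' Mean over projections of the simulator's fluence-equivalent LOT; for a
#' noiseless delivery this equals the chamber charge-ratio value exactly.
#'
#' @param delivery A [simulate_delivery()] result.
#' @param leaf 1-based leaf index; must be active in the plan.
#' @return Mean LOT in ms.
#' @export
true_mean_lot <- function(delivery, leaf) {
  if (!leaf %in% active_leaves(delivery$plan)) {
    abort(sprintf("leaf %d is not active in plan %s.", leaf,
                  delivery$plan$plan_id))
  }
  delivery$truth |> filter(.data$leaf == !!leaf) |> pull(.data$lot_ms) |> mean()
}

#' Ground-truth mean LOTs of all active leaves
#'
#' @param delivery A [simulate_delivery()] result.
#' @return A tibble with `plan_id`, `replicate`, `leaf`, `mean_lot_ms`.
#' @export
true_mean_lots <- function(delivery) {
  tibble(plan_id = delivery$plan$plan_id, replicate = delivery$replicate,
         leaf = active_leaves(delivery$plan)) |>
    mutate(mean_lot_ms = map_dbl(.data$leaf, ~ true_mean_lot(delivery, .x)))
}
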