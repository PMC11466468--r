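#' MV exit-detector trace container
#'
#' The exit detector opposite the linac comprises 640 adjacent ionization
#' chambers sampled at 300 Hz; a trace is the `[time sample x channel]`
#' fluence matrix plus the projection windows and the per-leaf fractional
#' channel coordinates used to extract leaf signals.
#'
#' @param samples Numeric matrix, time samples in rows, 640 channels in
#'   columns.
#' @param sample_rate_hz Sampling rate (nominal 300).
#' @param projection_windows Tibble with columns `projection`, `start_ms`,
#'   `end_ms`; windows must be ordered and non-overlapping.
#' @param leaf_channel_map Length-64 numeric vector of fractional channel
#'   coordinates, strictly increasing in leaf index.
#' @return An object of class `mv_trace`.
#' @export
mv_trace <- function(samples, sample_rate_hz = 300,
                     projection_windows, leaf_channel_map = mv_leaf_channel_map()) {
  samples <- as.matrix(samples)
  if (ncol(samples) != MV_N_CHANNELS) {
    abort(sprintf("trace must have %d channels (got %d).", MV_N_CHANNELS,
                  ncol(samples)))
  }
  if (length(leaf_channel_map) != MLC_N_LEAVES ||
      any(diff(leaf_channel_map) <= 0)) {
    abort("`leaf_channel_map` must be strictly increasing with one entry per leaf.")
  }
  pw <- as_tibble(projection_windows)
  if (any(diff(pw$start_ms) <= 0) || any(pw$end_ms <= pw$start_ms) ||
      any(head(pw$end_ms, -1) > tail(pw$start_ms, -1) + 1e-9)) {
    abort("`projection_windows` must be ordered and non-overlapping.")
  }
  structure(list(
    sample_rate_hz = sample_rate_hz,
    times_ms = (seq_len(nrow(samples)) - 1) * 1000 / sample_rate_hz,
    samples = samples,
    projection_windows = pw,
    leaf_channel_map = leaf_channel_map
  ), class = "mv_trace")
}

#' @export
print.mv_trace <- function(x, ...) {
  cat(sprintf("<mv_trace> %d samples x %d channels at %g Hz, %d projections\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate_hz,
              nrow(x$projection_windows)))
  invisible(x)
}

#' Default leaf-to-channel mapping
#'
#' Fractional channel coordinate of each leaf's beamlet on the 640-channel
#' detector (uniform spacing, deliberately non-integer so extraction always
#' exercises the channel interpolation).
#' @return Length-64 numeric vector.
#' @export
mv_leaf_channel_map <- function() 5.5 + 9.9 * (0:(MLC_N_LEAVES - 1))

# Circular convolution along the leaf axis (rows) of a 64 x T matrix.
convolve_leaves <- function(M, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  n <- nrow(M)
  out <- matrix(0, n, ncol(M))
  for (j in seq_along(kernel)) {
    s <- j - r - 1L  # source offset
    idx <- ((seq_len(n) - 1L - s) %% n) + 1L
    out <- out + kernel[j] * M[idx, , drop = FALSE]
  }
  out
}

#' Richardson-Lucy deconvolution along the leaf axis
#'
#' Multiplicative RL iterations applied independently to each time sample's
#' 64-leaf fluence vector, undoing the inter-leaf cross-talk described by
#' `kernel`. With a normalized kernel the per-time-sample sum across leaves is
#' conserved at every iteration (to floating-point precision), and
#' non-negativity is preserved.
#'
#' @param M Non-negative matrix, leaves in rows, time samples in columns.
#' @param kernel Non-negative cross-talk kernel (odd length, positive mass);
#'   normalized internally.
#' @param iterations Number of RL iterations (>= 1).
#' @return Deconvolved matrix of the same shape.
#' @export
richardson_lucy <- function(M, kernel = c(0.1, 0.8, 0.1), iterations = 10L) {
  if (sum(kernel) <= 0 || any(kernel < 0)) abort("kernel must be non-negative with positive mass.")
  iterations <- assert_count(iterations, "iterations")
  kernel <- kernel / sum(kernel)
  u <- M
  for (it in seq_len(iterations)) {
    Ku <- convolve_leaves(u, kernel)
    r <- M / pmax(Ku, 1e-12)
    u <- u * convolve_leaves(r, rev(kernel))
  }
  u
}

# ---- preprocessing --------------------------------------------------------

# Arc artifacts are transient full-detector spikes: a time sample is flagged
# when the cross-channel median (taken over a spread 9-channel subsample, so
# at most a couple of leaf beamlets can contaminate it) jumps by > 5 robust
# SDs relative to BOTH neighbours with the same sign; flagged samples are
# replaced by linear temporal interpolation per channel.
detect_arcs <- function(S) {
  n <- nrow(S)
  if (n < 3) return(integer(0))
  cols <- unique(round(seq(20, ncol(S) - 20, length.out = 9)))
  M <- S[, cols, drop = FALSE]
  k <- ncol(M)
  cnt <- vapply(seq_len(k), function(j) rowSums(M <= M[, j]), numeric(n))
  V <- M
  V[cnt < (k + 1) / 2] <- Inf
  med <- do.call(pmin, as.data.frame(V))
  d_prev <- c(0, diff(med))
  d_next <- c(diff(med), 0) * -1  # med[i] - med[i+1]
  rsd <- max(mad(diff(med)), 1e-9)
  which(abs(d_prev) > 5 * rsd & abs(d_next) > 5 * rsd & d_prev * d_next > 0)
}

correct_arcs <- function(S, flagged) {
  if (length(flagged) == 0) return(S)
  n <- nrow(S)
  good <- setdiff(seq_len(n), flagged)
  if (length(good) < 2) return(S)
  repl <- matrix(0, length(flagged), ncol(S))
  for (run in split(seq_along(flagged),
                    cumsum(c(1, diff(flagged) != 1)))) {
    rows <- flagged[run]
    lo <- suppressWarnings(max(good[good < rows[1]]))
    hi <- suppressWarnings(min(good[good > rows[length(rows)]]))
    if (!is.finite(lo)) { repl[run, ] <- rep(S[hi, ], each = length(run)) }
    else if (!is.finite(hi)) { repl[run, ] <- rep(S[lo, ], each = length(run)) }
    else {
      w <- (rows - lo) / (hi - lo)
      repl[run, ] <- outer(1 - w, S[lo, ]) + outer(w, S[hi, ])
    }
  }
  S[flagged, ] <- repl
  S
}

#' Preprocess an MV-detector trace into normalized per-leaf signals
#'
#' Runs the five-step chain: (1) arc-artifact correction (transient
#' full-detector spikes replaced by temporal interpolation); (2) per-leaf
#' signal extraction by linear interpolation of the channel axis at each
#' leaf's fractional channel coordinate; (3) offset subtraction — the
#' baseline from MLC leakage and detector dark current, estimated per leaf as
#' the 5th percentile of the samples in projections the plan keeps fully
#' closed (or of the whole leaf trace when the leaf is never commanded closed
#' for a whole projection), capped at an array-wide robust bound and clipped
#' at zero; (4) Richardson-Lucy deconvolution
#' across the leaf axis to undo inter-leaf cross-talk; (5) per-leaf,
#' per-projection normalization by the maximum value within the central half
#' of the projection window, so a fully open leaf sits near amplitude 1.
#'
#' A projection whose central-window maximum falls below 20 % of the leaf
#' array's global maximum is treated as closed and normalized by the global
#' maximum instead, so detector noise on a closed leaf is never inflated to
#' amplitude 1.
#'
#' @param trace An [mv_trace()].
#' @param plan Optional [delivery_plan()] used for the closed-projection
#'   offset estimate (the percentile fallback is used without it).
#' @param kernel Cross-talk kernel (non-negative, odd length, positive mass).
#' @param iterations Richardson-Lucy iteration count.
#' @return An object of class `leaf_signals`: times, the 64 x T normalized
#'   signal matrix and the projection windows.
#' @export
preprocess_trace <- function(trace, plan = NULL, kernel = c(0.1, 0.8, 0.1),
                             iterations = 10L) {
  if (sum(kernel) <= 0) abort("cross-talk kernel has zero mass.")
  pw <- trace$projection_windows
  if (nrow(pw) == 0) abort("trace has no projection windows.")
  S <- correct_arcs(trace$samples, detect_arcs(trace$samples))

  # channel-axis interpolation at each leaf's fractional coordinate
  lo <- floor(trace$leaf_channel_map)
  fr <- trace$leaf_channel_map - lo
  hi <- pmin(lo + 1L, MV_N_CHANNELS)
  L <- t(S[, lo, drop = FALSE]) * (1 - fr) + t(S[, hi, drop = FALSE]) * fr

  # offset subtraction
  times <- trace$times_ms
  win <- window_indices(times, pw)
  off <- vapply(seq_len(MLC_N_LEAVES), function(k) {
    closed <- if (!is.null(plan)) which(plan$planned_lot[k, ] == 0) else integer(0)
    closed <- closed[closed <= nrow(pw)]
    # low percentile, not the mean: a closed leaf next to an open one still
    # carries the cross-talk bump, which is RL's job to remove, not the
    # offset estimator's
    if (length(closed) > 0) {
      quantile(L[k, unlist(win[closed])], 0.05, names = FALSE)
    } else {
      quantile(L[k, ], 0.05, names = FALSE)
    }
  }, numeric(1))
  # dark current and leakage are detector-wide: cap each leaf's estimate at
  # an array-wide robust bound so a leaf that stays open through the whole
  # delivery cannot mistake its own open signal for baseline
  off <- pmin(off, median(off) + 3 * mad(off) + 1e-12)
  L <- L - off
  L[L < 0] <- 0

  L <- richardson_lucy(L, kernel, iterations)

  # per-leaf, per-projection normalization by the central-window maximum
  G <- max(L)
  N <- L
  if (G > 0) {
    for (p in seq_len(nrow(pw))) {
      w0 <- pw$start_ms[p]; w1 <- pw$end_ms[p]
      idx <- win[[p]]
      tt <- times[idx]
      c_idx <- idx[tt >= w0 + 0.25 * (w1 - w0) & tt <= w1 - 0.25 * (w1 - w0)]
      if (length(c_idx) == 0) {
        abort(sprintf("projection window %d contains no samples in its central half.", p))
      }
      Lc <- L[, c_idx, drop = FALSE]
      m <- Lc[, 1]
      for (j in seq_len(ncol(Lc))[-1]) m <- pmax(m, Lc[, j])
      scale <- ifelse(m >= 0.2 * G & m > 0, m, G)
      N[, idx] <- L[, idx, drop = FALSE] / scale
    }
    beyond <- which(times >= pw$end_ms[nrow(pw)])
    if (length(beyond)) N[, beyond] <- L[, beyond, drop = FALSE] / G
  }
  structure(list(times_ms = times, values = N, projection_windows = pw),
            class = "leaf_signals")
}

#' Extract one leaf's normalized signal as a tibble
#' @param signals A [preprocess_trace()] result.
#' @param leaf 1-based leaf index.
#' @return A tibble with `time_ms`, `value`.
#' @export
leaf_signal <- function(signals, leaf) {
  tibble(time_ms = signals$times_ms, value = signals$values[leaf, ])
}

#' Width of a signal pulse at a threshold level
#'
#' Measures the time between the first upward and the last downward crossing
#' of level `tau` inside the window, with crossings located by linear
#' interpolation between adjacent samples. A pulse still above `tau` at a
#' window boundary contributes width up to that boundary; a signal that never
#' reaches `tau` has width 0.
#'
#' @param values Normalized signal samples.
#' @param times_ms Sample times (same length as `values`).
#' @param window Length-2 numeric: window start and end in ms. Must lie
#'   within the sampled support.
#' @param tau Threshold level in (0, 1).
#' @return Width in ms.
#' @export
width_at_threshold <- function(values, times_ms, window, tau) {
  assert_fraction(tau, "tau", open_left = TRUE, open_right = TRUE)
  if (window[1] < times_ms[1] - 1e-9 ||
      window[2] > times_ms[length(times_ms)] + 1e-9) {
    abort("projection window lies outside the sampled signal support.")
  }
  idx <- which(times_ms >= window[1] & times_ms <= window[2])
  if (length(idx) == 0) abort("projection window contains no samples.")
  width_profile(values[idx], times_ms[idx], window[1], window[2], tau)
}

# Widths of one pulse at a vector of thresholds (no validation; hot path).
width_profile <- function(v, t, w0, w1, taus) {
  n <- length(v)
  out <- numeric(length(taus))
  for (j in seq_along(taus)) {
    tau <- taus[j]
    ab <- v >= tau
    if (!any(ab)) next
    i1 <- which.max(ab)
    i2 <- n + 1L - which.max(rev(ab))
    t_up <- if (i1 == 1L) w0 else
      t[i1 - 1L] + (tau - v[i1 - 1L]) / (v[i1] - v[i1 - 1L]) * (t[i1] - t[i1 - 1L])
    t_dn <- if (i2 == n) w1 else
      t[i2] + (v[i2] - tau) / (v[i2] - v[i2 + 1L]) * (t[i2 + 1L] - t[i2])
    out[j] <- max(t_dn - t_up, 0)
  }
  out
}

# Sample-index range of each projection window (uniform grid assumed).
window_indices <- function(times, pw) {
  dt <- times[2] - times[1]
  lapply(seq_len(nrow(pw)), function(p) {
    j0 <- max(ceiling(pw$start_ms[p] / dt + 1 - 1e-9), 1L)
    j1 <- min(floor(pw$end_ms[p] / dt + 1 - 1e-9), length(times))
    if (j1 < j0) abort(sprintf("projection window %d contains no samples.", p))
    seq.int(j0, j1)
  })
}

#' Reconstruct a LOT sinogram from an MV-detector trace
#'
#' Applies [preprocess_trace()] and measures [width_at_threshold()] for every
#' leaf and projection.
#'
#' @param trace An [mv_trace()].
#' @param plan The [delivery_plan()] of the same delivery.
#' @param tau Threshold level in (0, 1) (recorded in the result).
#' @param kernel,iterations Passed to [preprocess_trace()].
#' @param leaves Leaves to reconstruct (default all 64).
#' @return A long sinogram tibble (`method = "mv_detector"`).
#' @export
compute_lots_mv <- function(trace, plan, tau, kernel = c(0.1, 0.8, 0.1),
                            iterations = 10L, leaves = NULL) {
  assert_fraction(tau, "tau", open_left = TRUE, open_right = TRUE)
  signals <- preprocess_trace(trace, plan, kernel, iterations)
  leaves <- leaves %||% seq_len(MLC_N_LEAVES)
  pw <- signals$projection_windows
  win <- window_indices(signals$times_ms, pw)
  lot <- matrix(0, plan$n_leaves, plan$n_projections)
  for (k in leaves) {
    vk <- signals$values[k, ]
    for (p in seq_len(nrow(pw))) {
      lot[k, p] <- width_profile(vk[win[[p]]], signals$times_ms[win[[p]]],
                                 pw$start_ms[p], pw$end_ms[p], tau)
    }
  }
  new_lot_sinogram(plan, "mv_detector", tau, lot)
}

# Mean LOT per active leaf for a grid of thresholds, preprocessing once.
mv_mean_lots_by_tau <- function(trace, plan, taus, kernel = c(0.1, 0.8, 0.1),
                                iterations = 10L) {
  signals <- preprocess_trace(trace, plan, kernel, iterations)
  pw <- signals$projection_windows
  win <- window_indices(signals$times_ms, pw)
  leaves <- active_leaves(plan)
  out <- vector("list", length(leaves))
  for (li in seq_along(leaves)) {
    k <- leaves[li]
    vk <- signals$values[k, ]
    acc <- matrix(0, length(taus), nrow(pw))
    for (p in seq_len(nrow(pw))) {
      acc[, p] <- width_profile(vk[win[[p]]], signals$times_ms[win[[p]]],
                                pw$start_ms[p], pw$end_ms[p], taus)
    }
    out[[li]] <- tibble(method = "mv_detector", tau = taus, leaf = k,
                        plan_id = plan$plan_id,
                        mean_lot_ms = rowMeans(acc))
  }
  list_rbind(out)
}

#' Write / read an MV trace bundle
#'
#' Plain-text container: a JSON metadata file plus a CSV sample matrix (one
#' row per time sample, one column per channel).
#'
#' @param trace An [mv_trace()].
#' @param path Directory to hold `trace.json` and `samples.csv`.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` an
#'   [mv_trace()].
#' @export
write_trace <- function(trace, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(sample_rate_hz = trace$sample_rate_hz,
         leaf_channel_map = trace$leaf_channel_map,
         projection_windows = trace$projection_windows),
    file.path(path, "trace.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(as.data.frame(trace$samples), file.path(path, "samples.csv"),
                   col_names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "trace.json"),
                              simplifyVector = TRUE)
  S <- as.matrix(readr::read_csv(file.path(path, "samples.csv"),
                                 col_names = FALSE, show_col_types = FALSE))
  dimnames(S) <- NULL
  mv_trace(S, sample_rate_hz = meta$sample_rate_hz,
           projection_windows = as_tibble(meta$projection_windows),
           leaf_channel_map = meta$leaf_channel_map)
}
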