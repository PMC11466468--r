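#' Optical sensor event log
#'
#' Each MLC leaf carries a notch read by two photoemitter/photoreceptor
#' pairs, yielding a three-state position reading — CLOSED, TRANSITION, OPEN —
#' polled at a cycle time of about 0.18 ms (5556 Hz). The log stores the
#' state-change records sparsely: one row per (time, leaf, new state).
#'
#' @param records Data frame with columns `time_ms`, `leaf`, `state`
#'   (`"CLOSED"`, `"TRANSITION"` or `"OPEN"`).
#' @param resolution_ms Sensor cycle time the timestamps are quantized to.
#' @return A tibble of class `optical_log` with a `resolution_ms` attribute.
#' @export
optical_log <- function(records, resolution_ms = 0.18) {
  log <- as_tibble(records)
  if (!all(c("time_ms", "leaf", "state") %in% names(log))) {
    abort("an optical log needs columns `time_ms`, `leaf`, `state`.")
  }
  bad <- which(!log$state %in% leaf_state_levels)
  if (length(bad)) {
    abort(sprintf("record %d has unknown state `%s`.", bad[1], log$state[bad[1]]))
  }
  if (is.unsorted(log$time_ms)) abort("log timestamps must be non-decreasing.")
  attr(log, "resolution_ms") <- resolution_ms
  class(log) <- c("optical_log", class(log))
  log
}

state_level <- function(s) match(s, leaf_state_levels) - 1L  # CLOSED=0 .. OPEN=2

#' Segment one leaf's state stream into open events
#'
#' Partitions a leaf's CLOSED/TRANSITION/OPEN record sequence (initial state
#' CLOSED) into open events of three kinds: `normal`
#' (CLOSED-TRANSITION-OPEN-TRANSITION-CLOSED, timestamps t1..t4);
#' `merged_open` when two OPEN states are separated only by a TRANSITION —
#' the leaf had no time to close fully, and the shared transition is split at
#' its midpoint, ending the first event (its t4) and starting the second (its
#' t1); and `no_open` (CLOSED-TRANSITION-CLOSED) where the leaf never reached
#' the open state and the LOT is 0. States may only step between adjacent
#' levels; a jump (e.g. CLOSED to OPEN) is a malformed log.
#'
#' @param log An [optical_log()].
#' @param leaf 1-based leaf index.
#' @return A tibble with columns `leaf`, `kind`, `t1`, `t2`, `t3`, `t4`
#'   (ms; `t2`/`t3` are `NA` for `no_open` events).
#' @export
segment_leaf_events <- function(log, leaf) {
  rows <- which(log$leaf == leaf)
  tm <- log$time_ms[rows]; st <- log$state[rows]
  prev <- "CLOSED"
  t1 <- t2 <- t3 <- NA_real_
  from_split <- FALSE
  out <- list()
  push <- function(kind, t1, t2, t3, t4) {
    out[[length(out) + 1L]] <<- tibble(leaf = leaf, kind = kind,
                                       t1 = t1, t2 = t2, t3 = t3, t4 = t4)
  }
  for (i in seq_along(rows)) {
    if (abs(state_level(st[i]) - state_level(prev)) != 1L) {
      abort(sprintf(
        "malformed log: record %d moves leaf %d from %s directly to %s.",
        rows[i], leaf, prev, st[i]))
    }
    if (prev == "CLOSED" && st[i] == "TRANSITION") {
      t1 <- tm[i]; t2 <- t3 <- NA_real_; from_split <- FALSE
    } else if (prev == "TRANSITION" && st[i] == "OPEN") {
      if (!is.na(t3)) {
        # merged: OPEN -> TRANSITION -> OPEN with no CLOSED in between
        m <- (t3 + tm[i]) / 2
        push("merged_open", t1, t2, t3, m)
        t1 <- m; t2 <- tm[i]; t3 <- NA_real_; from_split <- TRUE
      } else {
        t2 <- tm[i]
      }
    } else if (prev == "OPEN" && st[i] == "TRANSITION") {
      t3 <- tm[i]
    } else if (prev == "TRANSITION" && st[i] == "CLOSED") {
      if (is.na(t2)) {
        push("no_open", t1, NA_real_, NA_real_, tm[i])
      } else {
        push(if (from_split) "merged_open" else "normal", t1, t2, t3, tm[i])
      }
      t1 <- t2 <- t3 <- NA_real_; from_split <- FALSE
    }
    prev <- st[i]
  }
  if (!is.na(t1)) {
    warn(sprintf("leaf %d: event starting at %.3f ms is unterminated at end of log; dropped.",
                 leaf, t1))
  }
  if (length(out) == 0) {
    return(tibble(leaf = integer(0), kind = character(0), t1 = numeric(0),
                  t2 = numeric(0), t3 = numeric(0), t4 = numeric(0)))
  }
  list_rbind(out)
}

#' LOT of an open event at an optical threshold
#'
#' For a normal event the LOT is the threshold-weighted interval
#' `(t3 + tau * (t4 - t3)) - (t1 + tau * (t2 - t1))`: `tau` places the
#' effective opening/closing instant within each transition. `no_open` events
#' return 0; merged events carry their midpoint-split boundaries in t1..t4
#' and evaluate the same formula. The result is affine in `tau` with slope
#' `(t4 - t3) - (t2 - t1)`, hence threshold-independent when the two
#' transitions last equally long.
#'
#' @param events Event tibble from [segment_leaf_events()].
#' @param tau Optical threshold in `[0, 1]`.
#' @return Numeric vector of LOTs in ms, one per event.
#' @export
lot_from_event <- function(events, tau) {
  assert_fraction(tau, "tau")
  ifelse(events$kind == "no_open", 0,
         (events$t3 + tau * (events$t4 - events$t3)) -
           (events$t1 + tau * (events$t2 - events$t1)))
}

#' Reconstruct a LOT sinogram from an optical event log
#'
#' Segments every leaf's state stream, evaluates each event's LOT at `tau`,
#' and assigns each event to the projection containing its temporal midpoint
#' `(t1 + t4) / 2`. Events spanning more than two projection windows are
#' still assigned by midpoint, with a warning.
#'
#' @param log An [optical_log()].
#' @param plan The [delivery_plan()] of the same delivery.
#' @param tau Optical threshold in `[0, 1]` (recorded in the result).
#' @return A long sinogram tibble (`method = "optical_sensor"`).
#' @export
compute_lots_optical <- function(log, plan, tau) {
  assert_fraction(tau, "tau")
  lot <- matrix(0, plan$n_leaves, plan$n_projections)
  tp <- plan$t_proj_ms
  for (k in sort(unique(log$leaf))) {
    ev <- segment_leaf_events(log, k)
    if (nrow(ev) == 0) next
    if (any(ev$t4 - ev$t1 > 2 * tp)) {
      warn(sprintf("leaf %d has an event spanning more than two projection windows; assigned by midpoint.", k))
    }
    lots <- lot_from_event(ev, tau)
    proj <- pmin(pmax(floor(((ev$t1 + ev$t4) / 2) / tp) + 1L, 1L),
                 plan$n_projections)
    for (i in seq_along(lots)) {
      lot[k, proj[i]] <- lot[k, proj[i]] + lots[i]
    }
  }
  new_lot_sinogram(plan, "optical_sensor", tau, lot)
}

# Mean LOT per active leaf for a grid of thresholds; events are segmented
# once since the per-event LOT is affine in tau.
optical_mean_lots_by_tau <- function(log, plan, taus) {
  leaves <- active_leaves(plan)
  P <- plan$n_projections
  out <- vector("list", length(leaves))
  for (li in seq_along(leaves)) {
    ev <- segment_leaf_events(log, leaves[li])
    base <- if (nrow(ev) == 0) rep(0, length(taus)) else {
      a <- ifelse(ev$kind == "no_open", 0, ev$t3 - ev$t1)
      b <- ifelse(ev$kind == "no_open", 0, (ev$t4 - ev$t3) - (ev$t2 - ev$t1))
      vapply(taus, function(tt) sum(a + tt * b), numeric(1)) / P
    }
    out[[li]] <- tibble(method = "optical_sensor", tau = taus,
                        leaf = leaves[li], plan_id = plan$plan_id,
                        mean_lot_ms = base)
  }
  list_rbind(out)
}

#' Write / read an optical event log CSV
#'
#' Columns `time_ms`, `leaf`, `state`, sorted by time, plus a constant
#' `resolution_ms` column carrying the sensor cycle time.
#'
#' @param log An [optical_log()].
#' @param path CSV file path.
#' @return `write_optical_log()` returns `path` invisibly;
#'   `read_optical_log()` an [optical_log()].
#' @export
write_optical_log <- function(log, path) {
  df <- as_tibble(log)[, c("time_ms", "leaf", "state")]
  df$resolution_ms <- attr(log, "resolution_ms") %||% NA_real_
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_optical_log
#' @export
read_optical_log <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  res <- if ("resolution_ms" %in% names(df)) df$resolution_ms[1] else 0.18
  optical_log(df[, c("time_ms", "leaf", "state")], resolution_ms = res)
}
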