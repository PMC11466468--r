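# Threshold calibration against the chamber ground truth and the validation
# statistics (paired t-test, Pearson correlation, OLS fit, violin-style
# discrepancy summaries).

average_replicates <- function(df) {
  if (!"replicate" %in% names(df)) return(df)
  df |>
    group_by(across(dplyr::any_of(c("method", "tau", "unit_id", "plan_id", "leaf")))) |>
    summarise(mean_lot_ms = mean(.data$mean_lot_ms), .groups = "drop")
}

pair_mean_lots <- function(calculated, reference) {
  calc <- average_replicates(calculated)
  ref <- average_replicates(reference) |>
    select("plan_id", "leaf", ref_lot_ms = "mean_lot_ms")
  out <- inner_join(calc, ref, by = c("plan_id", "leaf"))
  if (nrow(out) == 0) abort("no (plan, leaf) pairs shared between calculated and reference tables.")
  out
}

#' Summary statistics of LOT discrepancies
#'
#' Elementwise discrepancies (calculated minus reference) summarized the way
#' the violin plots report them: sample mean, median, SD (n - 1), IQR and
#' range, with outliers flagged beyond 1.5 x IQR from the quartiles.
#'
#' @param calculated,reference Paired numeric vectors of mean LOTs (ms).
#' @param labels Optional data frame (same length) carried into the outlier
#'   table, e.g. leaf and plan identifiers.
#' @return An object of class `discrepancy_stats` with fields `n`, `mean`,
#'   `median`, `sd`, `iqr`, `min`, `max` (ms) and an `outliers` tibble.
#' @export
discrepancy_stats <- function(calculated, reference, labels = NULL) {
  if (length(calculated) != length(reference)) {
    abort("`calculated` and `reference` must be paired vectors of equal length.")
  }
  d <- calculated - reference
  q <- quantile(d, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  is_out <- d < q[1] - 1.5 * iqr | d > q[2] + 1.5 * iqr
  outliers <- tibble(value_ms = d[is_out])
  if (!is.null(labels)) {
    outliers <- dplyr::bind_cols(outliers,
                                 as_tibble(labels)[is_out, , drop = FALSE])
  }
  structure(list(
    n = length(d), mean = mean(d), median = median(d),
    sd = if (length(d) > 1) sd(d) else 0, iqr = iqr,
    min = min(d), max = max(d), outliers = outliers
  ), class = "discrepancy_stats")
}

#' @export
print.discrepancy_stats <- function(x, ...) {
  cat(sprintf(
    "<discrepancy_stats> n = %d: mean %.2f, median %.2f, SD %.2f, IQR %.2f, range [%.2f, %.2f] ms; %d outlier(s)\n",
    x$n, x$mean, x$median, x$sd, x$iqr, x$min, x$max, nrow(x$outliers)))
  invisible(x)
}

#' @method tidy discrepancy_stats
#' @export
tidy.discrepancy_stats <- function(x, ...) {
  tibble(n = x$n, mean_ms = x$mean, median_ms = x$median, sd_ms = x$sd,
         iqr_ms = x$iqr, min_ms = x$min, max_ms = x$max,
         n_outliers = nrow(x$outliers))
}

#' Mean discrepancy between calculated and reference mean LOTs
#'
#' Replicates are averaged before pairing; pairs are matched on
#' (`plan_id`, `leaf`).
#'
#' @param calculated Tibble of reconstructed mean LOTs (`plan_id`, `leaf`,
#'   `mean_lot_ms`, optional `replicate`).
#' @param reference Tibble of ground-truth mean LOTs (same keys).
#' @return Mean of (calculated - reference) in ms.
#' @export
mean_discrepancy <- function(calculated, reference) {
  p <- pair_mean_lots(calculated, reference)
  mean(p$mean_lot_ms - p$ref_lot_ms)
}

#' Calibrate a reconstruction threshold against the ground truth
#'
#' Sweeps the threshold grid, averages the discrepancy between reconstructed
#' and ground-truth mean LOTs over all active leaves, plans and replicates at
#' each threshold, and locates the zero crossing `tau_star` by linear
#' interpolation between the bracketing grid points.
#'
#' @param calculated Tibble of reconstructed mean LOTs over a threshold grid:
#'   columns `tau`, `plan_id`, `leaf`, `mean_lot_ms` (optional `replicate`,
#'   `method`).
#' @param reference Ground-truth mean LOT tibble (`plan_id`, `leaf`,
#'   `mean_lot_ms`, optional `replicate`).
#' @param method Method label recorded in the result (taken from
#'   `calculated$method` if present).
#' @return An object of class `lot_calibration`: the discrepancy curve, the
#'   interpolated `tau_star` and the pair count.
#' @export
calibrate_threshold <- function(calculated, reference, method = NULL) {
  if (is.null(method)) {
    method <- if ("method" %in% names(calculated)) calculated$method[1] else "unknown"
  }
  pairs <- pair_mean_lots(calculated, reference)
  curve <- pairs |>
    group_by(.data$tau) |>
    summarise(mean_discrepancy_ms = mean(.data$mean_lot_ms - .data$ref_lot_ms),
              n_pairs = dplyr::n(), .groups = "drop") |>
    arrange(.data$tau)
  y <- curve$mean_discrepancy_ms
  if (any(!is.finite(y))) abort("discrepancy curve contains non-finite values.")
  hit <- which(y == 0)
  if (length(hit) > 0) {
    tau_star <- curve$tau[hit[1]]
  } else {
    sgn <- which(y[-1] * y[-length(y)] < 0)
    if (length(sgn) == 0) {
      abort(sprintf(
        "mean discrepancy does not change sign on the grid [%g, %g]; widen the threshold grid.",
        min(curve$tau), max(curve$tau)))
    }
    i <- sgn[1]
    tau_star <- curve$tau[i] + (0 - y[i]) * (curve$tau[i + 1] - curve$tau[i]) /
      (y[i + 1] - y[i])
  }
  structure(list(method = method, tau_grid = curve$tau,
                 curve = curve |> select("tau", "mean_discrepancy_ms"),
                 tau_star = tau_star, n_pairs = curve$n_pairs[1]),
            class = "lot_calibration")
}

#' @export
print.lot_calibration <- function(x, ...) {
  cat(sprintf("<lot_calibration> %s: tau* = %.4f (grid %g..%g, %d pairs)\n",
              x$method, x$tau_star, min(x$tau_grid), max(x$tau_grid), x$n_pairs))
  invisible(x)
}

#' @method tidy lot_calibration
#' @export
tidy.lot_calibration <- function(x, ...) {
  x$curve |> mutate(method = x$method, .before = 1)
}

#' @method glance lot_calibration
#' @export
glance.lot_calibration <- function(x, ...) {
  tibble(method = x$method, tau_star = x$tau_star, n_pairs = x$n_pairs,
         tau_min = min(x$tau_grid), tau_max = max(x$tau_grid))
}

#' Threshold-sweep curve plot
#' @param object A [calibrate_threshold()] result.
#' @param ... Unused.
#' @return A ggplot of the mean discrepancy versus threshold with the
#'   calibrated zero crossing marked.
#' @method autoplot lot_calibration
#' @export
autoplot.lot_calibration <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$tau, .data$mean_discrepancy_ms)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$tau_star, colour = "red",
                        linetype = 3) +
    ggplot2::labs(x = expression(tau), y = "mean discrepancy [ms]",
                  title = sprintf("%s: tau* = %.3f", object$method,
                                  object$tau_star)) +
    ggplot2::theme_minimal()
}

#' Reconstruct mean LOTs of one delivery for a threshold grid
#'
#' @param delivery A [simulate_delivery()] result (or any list with `plan`
#'   plus the stream the method needs).
#' @param method `"mv_detector"` or `"optical_sensor"`.
#' @param taus Threshold values.
#' @param kernel,iterations MV preprocessing settings.
#' @return A tibble with `method`, `tau`, `plan_id`, `replicate`, `leaf`,
#'   `mean_lot_ms`.
#' @export
reconstruct_mean_lots <- function(delivery, method = c("mv_detector", "optical_sensor"),
                                  taus, kernel = c(0.1, 0.8, 0.1),
                                  iterations = 10L) {
  method <- match.arg(method)
  out <- if (method == "mv_detector") {
    if (is.null(delivery$trace)) abort("delivery has no MV trace stream.")
    mv_mean_lots_by_tau(delivery$trace, delivery$plan, taus, kernel, iterations)
  } else {
    if (is.null(delivery$log)) abort("delivery has no optical log stream.")
    optical_mean_lots_by_tau(delivery$log, delivery$plan, taus)
  }
  out |> mutate(replicate = delivery$replicate %||% 1L)
}

#' Simulate and reconstruct a full reference study
#'
#' Runs the calibration-protocol workflow end to end on synthetic data: the
#' reference plans (three jaw openings, the requested LOT fractions plus the
#' 100 % charge-reference plans) are each delivered `replicates` times under
#' `model`; chamber charges are collected for every delivery, and the
#' x < 100 % deliveries are reconstructed with the requested methods at every
#' threshold in `taus`. Deliveries are simulated one at a time and their
#' telemetry discarded after reconstruction, so memory stays flat.
#'
#' @param model A [leaf_motion_model()].
#' @param seed Integer seed driving all randomness of the study.
#' @param taus Threshold grid (or a single threshold), or a named list with
#'   one grid per method.
#' @param methods Reconstruction methods to run.
#' @param x_fractions LOT fractions reconstructed against ground truth.
#' @param replicates Deliveries per plan.
#' @param n_projections,t_proj_ms Reference plan geometry.
#' @param unit_id Unit label for the charge records.
#' @param kernel,iterations MV preprocessing settings.
#' @return A list of class `lot_study`: `calculated` (mean LOTs per method,
#'   threshold, plan, replicate, leaf), `reference` (charge-derived ground
#'   truth), `truth` (simulator fluence truth), `charges`.
#' @export
run_reference_study <- function(model = leaf_motion_model(), seed = 1L,
                                taus = seq(0.30, 0.70, by = 0.01),
                                methods = c("mv_detector", "optical_sensor"),
                                x_fractions = c(0.25, 0.50, 0.75),
                                replicates = 2L,
                                n_projections = 400L, t_proj_ms = 348,
                                unit_id = "SIM1",
                                kernel = c(0.1, 0.8, 0.1), iterations = 10L) {
  methods <- match.arg(methods, several.ok = TRUE)
  set.seed(seed)
  plans <- reference_plans(x_fractions = sort(unique(c(x_fractions, 1))),
                           n_projections = n_projections,
                           t_proj_ms = t_proj_ms)
  calc <- list(); charges <- list(); truth <- list()
  for (plan in plans) {
    is_ref_only <- isTRUE(all.equal(plan$lot_fraction_x, 1))
    streams <- c("charges",
                 if (!is_ref_only && "mv_detector" %in% methods) "trace",
                 if (!is_ref_only && "optical_sensor" %in% methods) "log")
    for (r in seq_len(replicates)) {
      dl <- simulate_delivery(plan, model, replicate = r, unit_id = unit_id,
                              streams = streams)
      charges[[length(charges) + 1L]] <- dl$charges
      if (!is_ref_only) {
        truth[[length(truth) + 1L]] <- true_mean_lots(dl)
        for (m in methods) {
          tau_m <- if (is.list(taus)) taus[[m]] else taus
          calc[[length(calc) + 1L]] <-
            reconstruct_mean_lots(dl, m, tau_m, kernel, iterations)
        }
      }
      rm(dl)
    }
  }
  structure(list(
    calculated = list_rbind(calc),
    reference = ground_truth_table(list_rbind(charges), t_proj_ms),
    truth = list_rbind(truth),
    charges = list_rbind(charges),
    model = model, seed = seed, taus = taus, methods = methods
  ), class = "lot_study")
}

#' Validate reconstruction methods against the ground truth
#'
#' For each method: discrepancy summary statistics, a paired two-tailed
#' t-test between calculated and reference mean LOTs (equivalently, between
#' their discrepancies from the plan), Pearson's correlation, and the
#' ordinary-least-squares fit of calculated on reference. Replicates are
#' averaged at the mean-LOT level before pairing. A zero-variance pairing is
#' reported as a degenerate t-test rather than an error.
#'
#' @param calculated Tibble of reconstructed mean LOTs with a `method` column
#'   (single threshold per method).
#' @param reference Ground-truth mean LOT tibble.
#' @param alpha Significance level of the t-test decision.
#' @return An object of class `lot_validation`; see [tidy.lot_validation()].
#' @export
validate_methods <- function(calculated, reference, alpha = 0.05) {
  methods <- unique(calculated$method)
  per_method <- lapply(methods, function(m) {
    p <- pair_mean_lots(calculated |> filter(.data$method == m), reference)
    if (nrow(p) < 3) abort("validation needs at least 3 paired mean LOTs.")
    stats <- discrepancy_stats(p$mean_lot_ms, p$ref_lot_ms,
                               labels = p[, c("plan_id", "leaf")])
    tt <- tryCatch(t.test(p$mean_lot_ms, p$ref_lot_ms, paired = TRUE),
                   error = function(e) NULL)
    if (!is.null(tt) && !is.finite(tt$p.value)) tt <- NULL
    t_row <- if (is.null(tt)) {
      list(statistic = NA_real_, p_value = NA_real_, decision = "degenerate")
    } else {
      list(statistic = unname(tt$statistic), p_value = tt$p.value,
           decision = if (tt$p.value < alpha) "significant" else "not significant")
    }
    ct <- cor.test(p$mean_lot_ms, p$ref_lot_ms, method = "pearson")
    fit <- lm(mean_lot_ms ~ ref_lot_ms, data = p)
    list(method = m, pairs = p, stats = stats, t_test = t_row,
         pearson = list(r = unname(ct$estimate), p_value = ct$p.value),
         fit = list(slope = unname(coef(fit)[2]),
                    intercept_ms = unname(coef(fit)[1])))
  })
  names(per_method) <- methods
  structure(list(per_method = per_method, alpha = alpha),
            class = "lot_validation")
}

#' @export
print.lot_validation <- function(x, ...) {
  for (m in x$per_method) {
    cat(sprintf(
      "%s: mean %.2f ms, SD %.2f ms, r = %.4f, slope %.3f, intercept %.2f ms, t-test p = %.3g (%s)\n",
      m$method, m$stats$mean, m$stats$sd, m$pearson$r, m$fit$slope,
      m$fit$intercept_ms, m$t_test$p_value, m$t_test$decision))
  }
  invisible(x)
}

#' Tidy a validation report
#' @param x A [validate_methods()] result.
#' @param ... Unused.
#' @return One row per method with discrepancy statistics, t-test, Pearson r
#'   and linear-fit coefficients.
#' @method tidy lot_validation
#' @export
tidy.lot_validation <- function(x, ...) {
  list_rbind(lapply(x$per_method, function(m) {
    tidy(m$stats) |>
      mutate(method = m$method, .before = 1) |>
      mutate(t_statistic = m$t_test$statistic, t_p_value = m$t_test$p_value,
             t_decision = m$t_test$decision, pearson_r = m$pearson$r,
             pearson_p = m$pearson$p_value, slope = m$fit$slope,
             intercept_ms = m$fit$intercept_ms)
  }))
}

#' @method glance lot_validation
#' @export
glance.lot_validation <- function(x, ...) {
  tidy(x) |> select("method", "mean_ms", "sd_ms", "pearson_r", "slope",
                    "t_p_value")
}

#' Discrepancy distribution plot
#' @param object A [validate_methods()] result.
#' @param ... Unused.
#' @return A ggplot violin of per-pair discrepancies by method.
#' @method autoplot lot_validation
#' @export
autoplot.lot_validation <- function(object, ...) {
  df <- list_rbind(lapply(object$per_method, function(m) {
    m$pairs |> mutate(method = m$method,
                      discrepancy_ms = .data$mean_lot_ms - .data$ref_lot_ms)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$method, .data$discrepancy_ms)) +
    ggplot2::geom_violin(fill = "steelblue", alpha = 0.5) +
    ggplot2::geom_jitter(width = 0.05, size = 0.6) +
    ggplot2::labs(x = NULL, y = "LOT discrepancy [ms]") +
    ggplot2::theme_minimal()
}

#' Per-fraction MLC performance report
#'
#' Summarizes the LOTs a patient's fractions actually executed: central
#' statistics of the nonzero LOTs, the share of short LOTs (below 100 ms,
#' with the sub-class below 50 ms where the leaf cannot fully close), and the
#' mean discrepancy against the planned sinogram over the plan's open cells.
#'
#' @param fractions Named list of long sinogram tibbles, one per fraction.
#' @param plan The planned [delivery_plan()] (shape-compatible with every
#'   fraction).
#' @return A tibble with one row per fraction.
#' @export
fraction_report <- function(fractions, plan) {
  planned <- as.vector(plan$planned_lot)
  rows <- imap(fractions, function(sino, fx) {
    m <- sinogram_matrix(sino)
    if (nrow(m) != plan$n_leaves || ncol(m) != plan$n_projections) {
      abort(sprintf("fraction %s sinogram is %d x %d; plan is %d x %d.",
                    fx, nrow(m), ncol(m), plan$n_leaves, plan$n_projections))
    }
    v <- as.vector(m)
    nz <- v[v > 0]
    open <- planned > 0
    tibble(
      fraction = fx, n_open = length(nz),
      mean_ms = mean(nz), median_ms = median(nz),
      sd_ms = if (length(nz) > 1) sd(nz) else 0,
      min_ms = if (length(nz)) min(nz) else NA_real_,
      max_ms = if (length(nz)) max(nz) else NA_real_,
      pct_short = 100 * mean(nz < 100),
      pct_below_50 = 100 * mean(nz < 50),
      mean_discrepancy_ms = mean(v[open] - planned[open]))
  })
  list_rbind(rows)
}
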