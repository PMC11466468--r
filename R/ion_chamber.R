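#' Mean LOT from an ionization-chamber charge ratio
#'
#' Converts a chamber charge into the mean LOT of the leaf whose beamlet the
#' chamber sits on: `mean LOT = q_x / q_100 * t_proj`, where `q_100` is the
#' charge collected for the reference delivery whose active-leaf LOT is 100 %
#' of the projection time. Only the relative charge matters, so no
#' electrometer calibration or volume-averaging correction enters.
#'
#' @param q_x Charge for the delivery under test (a.u., >= 0). Vectorized.
#' @param q_100 Reference charge of the matching 100 %-LOT delivery (> 0).
#' @param t_proj_ms Projection duration in ms.
#' @return Mean LOT in ms.
#' @examples
#' mean_lot_from_charges(5, 5, 348)    # 348
#' mean_lot_from_charges(1.25, 5, 348) # 87
#' @export
mean_lot_from_charges <- function(q_x, q_100, t_proj_ms) {
  if (any(!is.finite(q_100)) || any(q_100 <= 0)) {
    abort("`q_100` must be a positive reference charge.")
  }
  if (any(q_x < 0)) abort("`q_x` must be >= 0.")
  if (any(q_x > q_100)) {
    warn("charge ratio exceeds 1: measured charge larger than the 100 % reference.")
  }
  q_x / q_100 * t_proj_ms
}

#' Ground-truth mean LOT table from a chamber charge set
#'
#' Converts every charge record into a mean LOT via the charge ratio against
#' the 100 %-LOT reference of the same chamber and jaw opening (averaged over
#' its replicate deliveries). Replicates of the test deliveries are kept
#' separate; averaging is deferred to the calibration stage. When a leakage
#' reference charge set (an all-closed delivery of the same duration) is
#' supplied, it is subtracted from both numerator and denominator, removing
#' the small-LOT bias that closed-leaf leakage otherwise introduces.
#'
#' @param charges Tibble of charge records with columns `unit_id`, `chamber`,
#'   `leaf`, `jaw_cm`, `x_fraction`, `replicate`, `plan_id`, `charge`.
#' @param t_proj_ms Projection duration in ms.
#' @param leakage_reference Optional tibble with columns `chamber`, `jaw_cm`,
#'   `charge`: charges of an all-closed delivery.
#' @return A tibble with one mean-LOT row per charge record (`method =
#'   "ion_chamber"`): `unit_id`, `plan_id`, `chamber`, `leaf`, `jaw_cm`,
#'   `x_fraction`, `replicate`, `mean_lot_ms`.
#' @export
ground_truth_table <- function(charges, t_proj_ms, leakage_reference = NULL) {
  charges <- as_tibble(charges)
  if (nrow(charges) == 0) {
    return(tibble(unit_id = character(0), plan_id = character(0),
                  chamber = integer(0), leaf = integer(0), jaw_cm = numeric(0),
                  x_fraction = numeric(0), replicate = integer(0),
                  method = character(0), mean_lot_ms = numeric(0)))
  }
  if (!is.null(leakage_reference)) {
    lk <- as_tibble(leakage_reference) |>
      select("chamber", "jaw_cm", q_leak = "charge")
    charges <- charges |>
      left_join(lk, by = c("chamber", "jaw_cm")) |>
      mutate(charge = .data$charge - dplyr::coalesce(.data$q_leak, 0)) |>
      select(-"q_leak")
  }
  refs <- charges |>
    filter(.data$x_fraction == 1) |>
    group_by(.data$unit_id, .data$chamber, .data$jaw_cm) |>
    summarise(q_100 = mean(.data$charge), .groups = "drop")
  test <- charges |> filter(.data$x_fraction != 1 | is.na(.data$x_fraction))
  joined <- test |> left_join(refs, by = c("unit_id", "chamber", "jaw_cm"))
  if (any(is.na(joined$q_100))) {
    i <- which(is.na(joined$q_100))[1]
    abort(sprintf(
      "no 100 %% reference charge for chamber %d at jaw opening %g cm (unit %s).",
      joined$chamber[i], joined$jaw_cm[i], joined$unit_id[i]))
  }
  joined |>
    mutate(method = "ion_chamber",
           mean_lot_ms = mean_lot_from_charges(.data$charge, .data$q_100,
                                               t_proj_ms)) |>
    select("unit_id", "plan_id", "chamber", "leaf", "jaw_cm", "x_fraction",
           "replicate", "method", "mean_lot_ms")
}

#' Write / read a chamber charge CSV
#'
#' @param charges Charge record tibble (see [ground_truth_table()]).
#' @param path CSV file path.
#' @return `write_charges()` returns `path` invisibly; `read_charges()` the
#'   charge tibble.
#' @export
write_charges <- function(charges, path) {
  readr::write_csv(charges, path)
  invisible(path)
}

#' @rdname write_charges
#' @export
read_charges <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    unit_id = readr::col_character(),
                    plan_id = readr::col_character()))
}
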