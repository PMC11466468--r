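#' Construct a delivery plan
#'
#' A delivery plan holds the planned leaf-open-time (LOT) sinogram of a
#' tomotherapy delivery: a 64-row matrix with one row per binary-MLC leaf and
#' one column per projection, each cell the commanded LOT in milliseconds,
#' plus the timing and jaw metadata needed to interpret it.
#'
#' @param planned_lot Numeric matrix, 64 rows (leaves) by `n_projections`
#'   columns, LOT per cell in ms. Cells must lie in `[0, t_proj_ms]`.
#' @param t_proj_ms Projection duration in ms.
#' @param jaw_opening_cm Longitudinal jaw field width: one of 1, 2.5 or 5 cm.
#' @param plan_id Character identifier.
#' @param gantry_mode `"static"` or `"helical"` (metadata only).
#' @param lot_fraction_x Optional commanded LOT as a fraction of `t_proj_ms`
#'   (set for the reference calibration plans).
#'
#' @return An object of class `delivery_plan`.
#' @seealso [reference_plans()], [read_plan()], [write_plan()]
#' @export
delivery_plan <- function(planned_lot, t_proj_ms, jaw_opening_cm = 2.5,
                          plan_id = "plan", gantry_mode = c("static", "helical"),
                          lot_fraction_x = NULL) {
  gantry_mode <- match.arg(gantry_mode)
  planned_lot <- as.matrix(planned_lot)
  storage.mode(planned_lot) <- "double"
  plan <- structure(
    list(
      plan_id = as.character(plan_id),
      n_leaves = MLC_N_LEAVES,
      n_projections = ncol(planned_lot),
      t_proj_ms = as.numeric(t_proj_ms),
      jaw_opening_cm = as.numeric(jaw_opening_cm),
      gantry_mode = gantry_mode,
      lot_fraction_x = if (is.null(lot_fraction_x)) NULL else as.numeric(lot_fraction_x),
      planned_lot = planned_lot
    ),
    class = "delivery_plan"
  )
  validate_plan(plan)
}

validate_plan <- function(plan) {
  lot <- plan$planned_lot
  if (nrow(lot) != MLC_N_LEAVES) {
    abort(sprintf("planned LOT sinogram must have %d rows (got %d).",
                  MLC_N_LEAVES, nrow(lot)))
  }
  if (ncol(lot) != plan$n_projections || plan$n_projections < 1L) {
    abort("planned LOT sinogram shape does not match `n_projections`.")
  }
  if (!plan$jaw_opening_cm %in% c(1, 2.5, 5)) {
    abort("`jaw_opening_cm` must be one of 1, 2.5 or 5.")
  }
  if (!is.finite(plan$t_proj_ms) || plan$t_proj_ms <= 0) {
    abort("`t_proj_ms` must be a positive duration.")
  }
  bad <- which(!is.finite(lot) | lot < 0 | lot > plan$t_proj_ms + 1e-9,
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "planned LOT out of [0, t_proj] at leaf %d, projection %d (value %s ms, t_proj %s ms).",
      bad[1, 1], bad[1, 2], format(lot[bad[1, , drop = FALSE]]),
      format(plan$t_proj_ms)))
  }
  plan
}

#' Leaves with any nonzero planned LOT
#' @param plan A [delivery_plan()].
#' @return Integer vector of 1-based leaf indices.
#' @export
active_leaves <- function(plan) {
  which(rowSums(plan$planned_lot) > 0)
}

#' @export
print.delivery_plan <- function(x, ...) {
  cat(sprintf(
    "<delivery_plan> %s: %d leaves x %d projections, t_proj %.1f ms, jaws %.1f cm, %s gantry\n",
    x$plan_id, x$n_leaves, x$n_projections, x$t_proj_ms, x$jaw_opening_cm,
    x$gantry_mode))
  al <- active_leaves(x)
  cat(sprintf("  active leaves: %s\n",
              if (length(al)) paste(al, collapse = ", ") else "none"))
  invisible(x)
}

#' Tidy a delivery plan into a long sinogram table
#'
#' @param x A [delivery_plan()].
#' @param ... Unused.
#' @return A tibble with columns `plan_id`, `leaf`, `projection`, `lot_ms`.
#' @method tidy delivery_plan
#' @export
tidy.delivery_plan <- function(x, ...) {
  tibble(
    plan_id = x$plan_id,
    leaf = rep(seq_len(x$n_leaves), times = x$n_projections),
    projection = rep(seq_len(x$n_projections), each = x$n_leaves),
    lot_ms = as.vector(x$planned_lot)
  )
}

#' The twelve static-gantry reference calibration plans
#'
#' Generates the reference plan set used for threshold calibration and
#' validation: static gantry and couch, 400 projections of 348 ms each, leaves
#' 27, 39 and 47 active with a constant commanded LOT of x times the
#' projection time, for every combination of jaw opening (1, 2.5, 5 cm) and
#' x (25, 50, 75, 100 %). All other leaves stay closed throughout.
#'
#' @param x_fractions Commanded LOT fractions to generate (default all four).
#' @param jaw_openings_cm Jaw openings to generate (default all three).
#' @param n_projections Number of projections per plan.
#' @param t_proj_ms Projection duration in ms.
#' @return A named list of [delivery_plan()] objects (12 with the defaults).
#' @examples
#' plans <- reference_plans()
#' length(plans)
#' plans[["jo2.5_x50"]]
#' @export
reference_plans <- function(x_fractions = c(0.25, 0.50, 0.75, 1.00),
                            jaw_openings_cm = c(1, 2.5, 5),
                            n_projections = 400L,
                            t_proj_ms = 348) {
  grid <- expand.grid(x = x_fractions, jo = jaw_openings_cm,
                      KEEP.OUT.ATTRS = FALSE)
  plans <- lapply(seq_len(nrow(grid)), function(i) {
    x <- grid$x[i]; jo <- grid$jo[i]
    lot <- matrix(0, MLC_N_LEAVES, n_projections)
    lot[CHAMBER_LEAVES, ] <- x * t_proj_ms
    delivery_plan(
      lot, t_proj_ms = t_proj_ms, jaw_opening_cm = jo,
      plan_id = sprintf("jo%g_x%g", jo, 100 * x),
      gantry_mode = "static", lot_fraction_x = x)
  })
  names(plans) <- vapply(plans, `[[`, "", "plan_id")
  plans
}

#' Write / read a delivery plan
#'
#' Plans are serialized as a small JSON metadata file pointing to a plain CSV
#' sinogram (64 rows, one per leaf; LOTs in ms with three decimals), so the
#' on-disk form is human-diffable. `write_plan()` then `read_plan()` is
#' value-identical at the serialized precision.
#'
#' @param plan A [delivery_plan()].
#' @param path Path of the JSON metadata file; the sinogram CSV is written
#'   next to it.
#' @return `write_plan()` returns `path` invisibly; `read_plan()` returns a
#'   [delivery_plan()].
#' @export
write_plan <- function(plan, path) {
  validate_plan(plan)
  csv <- paste0(sub("\\.json$", "", path), "_sinogram.csv")
  meta <- list(
    plan_id = plan$plan_id, n_leaves = plan$n_leaves,
    n_projections = plan$n_projections, t_proj_ms = plan$t_proj_ms,
    jaw_opening_cm = plan$jaw_opening_cm, gantry_mode = plan$gantry_mode,
    lot_fraction_x = plan$lot_fraction_x, sinogram_csv = basename(csv))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, null = "null")
  m <- matrix(sprintf("%.3f", plan$planned_lot), nrow = MLC_N_LEAVES)
  utils::write.table(m, csv, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("plan_id", "n_projections", "t_proj_ms", "jaw_opening_cm",
            "gantry_mode", "sinogram_csv")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    abort(sprintf("malformed plan file `%s`: missing field(s) %s.",
                  path, paste(miss, collapse = ", ")))
  }
  csv <- file.path(dirname(path), meta$sinogram_csv)
  lot <- as.matrix(utils::read.table(csv, sep = ",", header = FALSE))
  dimnames(lot) <- NULL
  if (nrow(lot) != MLC_N_LEAVES || ncol(lot) != meta$n_projections) {
    abort(sprintf(
      "sinogram `%s` has %d rows x %d columns; expected %d x %d.",
      csv, nrow(lot), ncol(lot), MLC_N_LEAVES, meta$n_projections))
  }
  delivery_plan(lot, t_proj_ms = meta$t_proj_ms,
                jaw_opening_cm = meta$jaw_opening_cm,
                plan_id = meta$plan_id, gantry_mode = meta$gantry_mode,
                lot_fraction_x = meta$lot_fraction_x)
}
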