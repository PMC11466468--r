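# Reconstructed sinograms are plain long tibbles so they compose with dplyr:
# one row per (leaf, projection) cell with method/threshold provenance columns.

new_lot_sinogram <- function(plan, method, tau, lot_matrix) {
  stopifnot(nrow(lot_matrix) == plan$n_leaves,
            ncol(lot_matrix) == plan$n_projections)
  out <- tibble(
    plan_id = plan$plan_id,
    method = method,
    tau = if (is.null(tau)) NA_real_ else as.numeric(tau),
    leaf = rep(seq_len(plan$n_leaves), times = plan$n_projections),
    projection = rep(seq_len(plan$n_projections), each = plan$n_leaves),
    lot_ms = as.vector(lot_matrix)
  )
  class(out) <- c("lot_sinogram", class(out))
  out
}

#' Reshape a long LOT sinogram into a leaf-by-projection matrix
#'
#' @param sinogram A long sinogram tibble (columns `leaf`, `projection`,
#'   `lot_ms`) as returned by [compute_lots_mv()], [compute_lots_optical()] or
#'   [tidy.delivery_plan()].
#' @return A numeric matrix, leaves in rows and projections in columns.
#' @export
sinogram_matrix <- function(sinogram) {
  n_leaf <- max(sinogram$leaf)
  n_proj <- max(sinogram$projection)
  m <- matrix(0, n_leaf, n_proj)
  m[cbind(sinogram$leaf, sinogram$projection)] <- sinogram$lot_ms
  m
}

#' Mean LOT per leaf of a reconstructed sinogram
#'
#' Averages each leaf's LOT over all projections — the time-integrated
#' quantity an ionization chamber on that leaf's beamlet path measures — and
#' is therefore the level at which reconstructions are compared with the
#' charge-ratio ground truth.
#'
#' @param sinogram A long sinogram tibble.
#' @param leaves Optional leaf subset (default: leaves with any nonzero LOT).
#' @return A tibble with one row per leaf: `plan_id`, `method`, `tau`, `leaf`,
#'   `mean_lot_ms`.
#' @export
mean_lots <- function(sinogram, leaves = NULL) {
  if (is.null(leaves)) {
    leaves <- sinogram |>
      group_by(.data$leaf) |>
      summarise(any_open = any(.data$lot_ms > 0), .groups = "drop") |>
      filter(.data$any_open) |>
      pull(.data$leaf)
  }
  sinogram |>
    filter(.data$leaf %in% leaves) |>
    group_by(across(dplyr::any_of(c("plan_id", "method", "tau", "replicate"))),
             .data$leaf) |>
    summarise(mean_lot_ms = mean(.data$lot_ms), .groups = "drop")
}

#' Write / read a reconstructed LOT sinogram
#'
#' Same JSON + CSV container as [write_plan()], with `method` and `tau`
#' provenance added to the metadata.
#'
#' @param sinogram A long sinogram tibble.
#' @param path Path of the JSON metadata file.
#' @param t_proj_ms Projection duration recorded in the metadata.
#' @return `write_sinogram()` returns `path` invisibly; `read_sinogram()`
#'   returns the long sinogram tibble.
#' @export
write_sinogram <- function(sinogram, path, t_proj_ms = NA_real_) {
  m <- sinogram_matrix(sinogram)
  csv <- paste0(sub("\\.json$", "", path), "_sinogram.csv")
  meta <- list(
    plan_id = sinogram$plan_id[1], method = sinogram$method[1],
    tau = sinogram$tau[1], n_leaves = nrow(m), n_projections = ncol(m),
    t_proj_ms = t_proj_ms, sinogram_csv = basename(csv))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(matrix(sprintf("%.3f", m), nrow = nrow(m)), csv,
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  csv <- file.path(dirname(path), meta$sinogram_csv)
  m <- as.matrix(utils::read.table(csv, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  if (any(!is.finite(m) | m < 0)) abort("sinogram contains negative or non-finite LOTs.")
  out <- tibble(
    plan_id = meta$plan_id, method = meta$method,
    tau = if (is.null(meta$tau)) NA_real_ else as.numeric(meta$tau),
    leaf = rep(seq_len(nrow(m)), times = ncol(m)),
    projection = rep(seq_len(ncol(m)), each = nrow(m)),
    lot_ms = as.vector(m))
  class(out) <- c("lot_sinogram", class(out))
  out
}

#' Sinogram heat map
#'
#' @param object A long sinogram tibble of class `lot_sinogram`.
#' @param ... Unused.
#' @return A ggplot object (projection on x, leaf on y, LOT as fill).
#' @method autoplot lot_sinogram
#' @export
autoplot.lot_sinogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$projection, .data$leaf,
                                       fill = .data$lot_ms)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "LOT [ms]") +
    ggplot2::labs(x = "projection", y = "leaf",
                  title = unique(object$plan_id)[1]) +
    ggplot2::theme_minimal()
}
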