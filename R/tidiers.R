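# broom-style tidiers for the package's result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn shared_area_slicewise Per-slice tibble (`slice`,
#'   `area_um2`).
#' @param x An `interface_measurement`.
#' @param ... Unused.
#' @export
tidy.interface_measurement <- function(x, ...) {
  tibble::tibble(slice = x$slices, area_um2 = x$per_slice_areas)
}

#' @describeIn shared_area_slicewise One-row summary tibble.
#' @export
glance.interface_measurement <- function(x, ...) {
  tibble::tibble(
    label_a = paste(x$label_a, collapse = "+"),
    label_b = paste(x$label_b, collapse = "+"),
    mode = x$mode, n_slices = x$n_slices,
    total_area_um2 = x$total_area_um2,
    mean_slice_area_um2 = mean(x$per_slice_areas))
}

#' @describeIn linear_measurement_set Samples as a tibble.
#' @param x A `linear_measurement_set`.
#' @param ... Unused.
#' @export
tidy.linear_measurement_set <- function(x, ...) {
  tibble::tibble(quantity = x$quantity, sample = x$samples,
                 units = x$units)
}

#' @describeIn linear_measurement_set One-row mean/sd/n tibble.
#' @export
glance.linear_measurement_set <- function(x, ...) {
  tibble::tibble(quantity = x$quantity, n = x$n, mean = x$mean, sd = x$sd,
                 units = x$units)
}

#' @describeIn mitochondria_stats Per-component volume tibble.
#' @param x A `mitochondria_stats` object.
#' @param ... Unused.
#' @export
tidy.mitochondria_stats <- function(x, ...) {
  tibble::tibble(cell_id = x$cell_id,
                 component = seq_along(x$component_volumes_nm3),
                 volume_nm3 = x$component_volumes_nm3)
}

#' @describeIn mitochondria_stats One-row statistics tibble.
#' @export
glance.mitochondria_stats <- function(x, ...) {
  tibble::tibble(cell_id = x$cell_id, count = x$count,
                 mean_volume_nm3 = x$mean_volume_nm3,
                 sd_volume_nm3 = x$sd_volume_nm3,
                 min_volume_nm3 = x$min_volume_nm3,
                 total_volume_nm3 = x$total_volume_nm3,
                 basal_fraction = x$basal_fraction)
}

#' @describeIn microvillus_geometry Per-measurement tibble.
#' @param x A `microvillus_geometry` object.
#' @param ... Unused.
#' @export
tidy.microvillus_geometry <- function(x, ...) {
  dplyr::mutate(x$details, cell_id = x$cell_id)
}

#' @describeIn microvillus_geometry One-row length/angle summary.
#' @export
glance.microvillus_geometry <- function(x, ...) {
  tibble::tibble(cell_id = x$cell_id,
                 n = x$length$n,
                 mean_length_um = x$length$mean, sd_length_um = x$length$sd,
                 mean_angle_deg = x$angle$mean, sd_angle_deg = x$angle$sd)
}

#' @describeIn rpe_height One-row height summary.
#' @param x An `rpe_height` object.
#' @param ... Unused.
#' @export
glance.rpe_height <- function(x, ...) {
  tibble::tibble(cell_id = x$cell_id, n = x$body_height$n,
                 body_height_um = x$body_height$mean,
                 body_height_sd_um = x$body_height$sd,
                 microvilli_length_um = x$microvilli_length_um,
                 combined_height_um = x$combined_height_um)
}
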