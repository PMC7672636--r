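#' Phantom scene specification
#'
#' Parameters of the synthetic outer-retina scene used to validate every
#' estimator in the package against analytic ground truth. The defaults
#' describe a desk-scale monolayer patch with the magnitudes reported for
#' the adult mouse central retina: rhomboid RPE cells 6.7 um tall, apical
#' microvilli 5.5 um long tilted at 143 deg from the +x apical tangent,
#' 90 supported photoreceptor outer segments per cell, Bruch's membrane
#' 524.4 +/- 200.5 nm thick, ellipsoidal (1 or 2) nuclei, basally clustered
#' mitochondria and basal infold pockets, at 50 nm isotropic spacing.
#' Cell width is scaled down (10 um) so a full scene stays tractable; a
#' full-size run only needs a different `cell_width`/`spacing`.
#'
#' @param n_cells_x,n_cells_z Cells along x and z (monolayer grid).
#' @param cell_width Cell footprint edge, um (square footprint).
#' @param cell_body_height Apical-to-basal body height excluding
#'   microvilli, um.
#' @param shear_angle Lean of the lateral cell walls from vertical, degrees
#'   (rhomboid cross-section; 0 = cuboid).
#' @param nuclei_per_cell Integer vector, one entry per cell (row-major in
#'   x then z), each 1 or 2; recycled if length 1.
#' @param nucleus_semiaxes Ellipsoid semiaxes `c(x, y, z)`, um.
#' @param microvilli_length Rod length, um.
#' @param microvilli_tilt Rod tilt measured in the slice plane from the +x
#'   apical tangent to the root-to-tip chord, degrees, in (90, 180).
#' @param microvilli_radius Rod radius, um.
#' @param rods_per_cell Microvilli rods per cell.
#' @param os_per_cell Photoreceptor outer segments per cell
#'   (<= `rods_per_cell`; each OS continues one microvillus axis so that
#'   contact is guaranteed by construction).
#' @param os_radius,os_length OS rod radius and length, um.
#' @param brm_mean_thickness,brm_thickness_sd Bruch's membrane thickness
#'   distribution (Gaussian, truncated to at least one voxel), nm.
#' @param infold_pockets_per_cell Spherical sub-RPE (basal infold) pockets
#'   carved near each cell's base.
#' @param pocket_radius Pocket radius, um.
#' @param mito_per_cell Mitochondria per cell.
#' @param mito_semiaxes Base ellipsoid semiaxes `c(x, y, z)`, um; each axis
#'   of each organelle is jittered by a factor U(0.7, 1.3).
#' @param mito_basal_fraction Fraction of mitochondria placed in the basal
#'   third of the cell height, in `[0, 1]`.
#' @param ensure_separation Guarantee that no two placed organelles
#'   (mitochondria, pockets, nuclei) intersect, so connected-component
#'   counts equal seeded counts exactly.
#' @param spacing A [voxel_spacing], nm.
#' @param seed Integer seed; the whole scene is a deterministic function of
#'   the spec (one seeded generator, fixed draw order: per cell first
#'   nuclei, then pockets, then mitochondria, then microvillus roots, then
#'   the OS subset, finally the Bruch's membrane thickness field).
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_cells_x = 2L, n_cells_z = 2L,
                         cell_width = 10, cell_body_height = 6.7,
                         shear_angle = 15,
                         nuclei_per_cell = c(1L, 2L, 1L, 2L),
                         nucleus_semiaxes = c(2.2, 1.5, 2.2),
                         microvilli_length = 5.5, microvilli_tilt = 143,
                         microvilli_radius = 0.1, rods_per_cell = 90L,
                         os_per_cell = 90L, os_radius = 0.15,
                         os_length = 2.5,
                         brm_mean_thickness = 524.4,
                         brm_thickness_sd = 200.5,
                         infold_pockets_per_cell = 6L, pocket_radius = 0.5,
                         mito_per_cell = 100L,
                         mito_semiaxes = c(0.35, 0.28, 0.28),
                         mito_basal_fraction = 0.8,
                         ensure_separation = TRUE,
                         spacing = voxel_spacing(50, 50, 50),
                         seed = 1L) {
  n_cells <- n_cells_x * n_cells_z
  nuclei_per_cell <- as.integer(rep_len(nuclei_per_cell, n_cells))
  spec <- list(
    n_cells_x = as.integer(n_cells_x), n_cells_z = as.integer(n_cells_z),
    cell_width = cell_width, cell_body_height = cell_body_height,
    shear_angle = shear_angle, nuclei_per_cell = nuclei_per_cell,
    nucleus_semiaxes = nucleus_semiaxes,
    microvilli_length = microvilli_length,
    microvilli_tilt = microvilli_tilt,
    microvilli_radius = microvilli_radius,
    rods_per_cell = as.integer(rods_per_cell),
    os_per_cell = as.integer(os_per_cell),
    os_radius = os_radius, os_length = os_length,
    brm_mean_thickness = brm_mean_thickness,
    brm_thickness_sd = brm_thickness_sd,
    infold_pockets_per_cell = as.integer(infold_pockets_per_cell),
    pocket_radius = pocket_radius,
    mito_per_cell = as.integer(mito_per_cell),
    mito_semiaxes = mito_semiaxes,
    mito_basal_fraction = mito_basal_fraction,
    ensure_separation = isTRUE(ensure_separation),
    spacing = spacing, seed = as.integer(seed)
  )
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  stopifnot(is_voxel_spacing(s$spacing))
  pos <- c(cell_width = s$cell_width,
           cell_body_height = s$cell_body_height)
  if (any(pos <= 0)) stop("cell dimensions must be positive", call. = FALSE)
  if (s$n_cells_x < 1L || s$n_cells_z < 1L) {
    stop("need at least one cell in each direction", call. = FALSE)
  }
  if (!all(s$nuclei_per_cell %in% c(1L, 2L))) {
    stop("nuclei_per_cell entries must be 1 or 2", call. = FALSE)
  }
  if (s$rods_per_cell > 0 &&
      (s$microvilli_tilt <= 90 || s$microvilli_tilt >= 180)) {
    stop("microvilli_tilt must lie in (90, 180) degrees", call. = FALSE)
  }
  if (s$rods_per_cell > 0 &&
      (s$microvilli_length <= 0 || s$microvilli_radius <= 0)) {
    stop("degenerate spec: zero-size microvilli", call. = FALSE)
  }
  if (s$os_per_cell > 0 && (s$os_radius <= 0 || s$os_length <= 0)) {
    stop("degenerate spec: zero-size outer segments", call. = FALSE)
  }
  if (s$os_per_cell > s$rods_per_cell) {
    stop("os_per_cell must not exceed rods_per_cell ",
         "(each OS continues one microvillus)", call. = FALSE)
  }
  if (s$mito_per_cell > 0 && any(s$mito_semiaxes <= 0)) {
    stop("degenerate spec: zero-size mitochondria", call. = FALSE)
  }
  if (s$mito_basal_fraction < 0 || s$mito_basal_fraction > 1) {
    stop("mito_basal_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (s$brm_mean_thickness <= 0) {
    stop("brm_mean_thickness must be positive", call. = FALSE)
  }
  invisible(s)
}
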