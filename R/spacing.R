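#' Anisotropic voxel spacing
#'
#' Voxel dimensions of a serial-section label stack, in nanometres. SBF-SEM
#' acquisitions are strongly anisotropic (small in-plane pixels, thick
#' sections), so every volume, surface-area and length computation in the
#' package is weighted by these three numbers. Spacing must always be given
#' explicitly: acquisition pixel size is routinely changed by downsampling
#' after imaging, so values embedded in TIFF tags are not trusted.
#'
#' @param dx In-plane pixel width (lateral, x), nm.
#' @param dy In-plane pixel height (apical-to-basal, y), nm.
#' @param dz Section thickness (slice step, z), nm.
#'
#' @return An object of class `voxel_spacing`: a named list with elements
#'   `dx`, `dy`, `dz` (nm).
#' @examples
#' voxel_spacing(8, 8, 50)     # 8 nm pixels, 50 nm sections
#' voxel_spacing(50, 50, 50)   # isotropic 50 nm (phantom default)
#' @export
voxel_spacing <- function(dx, dy, dz) {
  vals <- c(dx = dx, dy = dy, dz = dz)
  if (!is.numeric(vals) || length(vals) != 3L || any(!is.finite(vals)) ||
      any(vals <= 0)) {
    stop("voxel spacing components dx, dy, dz must be finite and > 0",
         call. = FALSE)
  }
  structure(list(dx = as.numeric(dx), dy = as.numeric(dy),
                 dz = as.numeric(dz)),
            class = "voxel_spacing")
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("<voxel_spacing> dx = %g nm, dy = %g nm, dz = %g nm\n",
              x$dx, x$dy, x$dz))
  invisible(x)
}

is_voxel_spacing <- function(x) inherits(x, "voxel_spacing")

# voxel volume in nm^3
voxel_volume_nm3 <- function(spacing) spacing$dx * spacing$dy * spacing$dz

# face areas (um^2) by the axis the face normal points along
face_areas_um2 <- function(spacing) {
  c(x = spacing$dy * spacing$dz,
    y = spacing$dx * spacing$dz,
    z = spacing$dx * spacing$dy) / 1e6
}

NM3_PER_UM3 <- 1e9
NM2_PER_UM2 <- 1e6
NM_PER_UM <- 1e3
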