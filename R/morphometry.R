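# Per-cell, per-compartment volumes and surface areas, photoreceptor
# support counts, and mitochondria statistics.

#' Volume of a binary mask
#'
#' Voxel count times the voxel volume `dx*dy*dz`, converted to cubic
#' micrometres.
#'
#' @param mask Logical 3D array.
#' @param spacing A [voxel_spacing] (nm).
#' @return Volume in um^3 (0 for an empty mask).
#' @export
compartment_volume <- function(mask, spacing) {
  sum(mask) * voxel_volume_nm3(spacing) / NM3_PER_UM3
}

#' Voxel-face surface area of a binary mask
#'
#' Sums the areas of all exposed voxel faces (faces between a mask voxel
#' and a non-mask voxel or the array border), weighted by orientation:
#' x-facing faces contribute `dy*dz`, y-facing `dx*dz`, z-facing `dx*dy`.
#' This is the staircase (L1) surface estimator: exact for axis-aligned
#' solids, an overestimate for oblique or curved surfaces — results carry
#' the estimator name so downstream tables can state it.
#'
#' @param mask Logical 3D array.
#' @param spacing A [voxel_spacing] (nm).
#' @return Surface area in um^2 with attribute `area_method =
#'   "voxel_face"`.
#' @export
surface_area_voxel <- function(mask, spacing) {
  d <- dim(mask)
  n_y <- sum(mask[1, , ]) + sum(mask[d[1], , ]) +
    sum(mask[-d[1], , , drop = FALSE] != mask[-1, , , drop = FALSE])
  n_x <- sum(mask[, 1, ]) + sum(mask[, d[2], ]) +
    sum(mask[, -d[2], , drop = FALSE] != mask[, -1, , drop = FALSE])
  n_z <- sum(mask[, , 1]) + sum(mask[, , d[3]]) +
    (if (d[3] > 1L) {
      sum(mask[, , -d[3], drop = FALSE] != mask[, , -1, drop = FALSE])
    } else 0L)
  fa <- face_areas_um2(spacing)
  out <- n_x * fa[["x"]] + n_y * fa[["y"]] + n_z * fa[["z"]]
  attr(out, "area_method") <- "voxel_face"
  out
}

#' Per-cell, per-compartment morphometry table
#'
#' One row per (cell, compartment) pair present in the label table:
#' volume (um^3), voxel-face surface area (um^2) and the number of labels
#' contributing (a bi-nucleate cell's nucleus row merges both nuclei).
#'
#' @param vol A [label_volume].
#' @return A tibble: `cell_id`, `compartment`, `volume_um3`,
#'   `surface_area_um2`, `n_labels`, `area_method`.
#' @export
morphometry_table <- function(vol) {
  d <- dim(vol$grid)
  vv <- voxel_volume_nm3(vol$spacing) / NM3_PER_UM3
  counts <- tabulate(vol$grid, nbins = max(vol$table$label))
  bbs <- label_bboxes(vol$grid)
  groups <- dplyr::distinct(tibble::as_tibble(vol$table[, c("cell",
                                                            "compartment")]))
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    cellg <- groups$cell[i]; comp <- groups$compartment[i]
    labs <- labels_for(vol$table, cell = cellg, compartment = comp)
    bb <- bbox_of_labels(bbs, labs)
    if (is.null(bb)) {
      sa <- 0
    } else {
      bb <- pad_bbox(bb, d, pad = 1L)
      sa <- surface_area_voxel(mask_of_labels(crop_bbox(vol$grid, bb), labs),
                               vol$spacing)
    }
    tibble::tibble(cell_id = cellg, compartment = comp,
                   volume_um3 = sum(counts[labs]) * vv,
                   surface_area_um2 = as.numeric(sa),
                   n_labels = length(labs))
  })
  out <- dplyr::bind_rows(rows)
  out$area_method <- "voxel_face"
  dplyr::arrange(out, .data$cell_id, .data$compartment)
}

#' Derived cell-summary arithmetic
#'
#' The pure arithmetic behind the per-cell summary, applicable to measured
#' or published volumes alike: nucleus-excluded cytoplasm is the cytoplasm
#' volume (nuclei included, microvilli excluded) minus the summed nucleus
#' volumes, and photoreceptor density is the supported count divided by
#' the cytoplasm volume, computed before any rounding. Densities are
#' additionally reported rounded to 2 significant figures, the convention
#' used in published tables; full precision is retained alongside.
#'
#' @param cytoplasm_volume_um3 Cell cytoplasm volume (nuclei included,
#'   microvilli and sub-RPE spaces excluded), um^3.
#' @param nuclei_volumes_um3 Numeric vector of per-nucleus volumes, um^3.
#' @param photoreceptors_supported Integer count (NA if unknown).
#' @return One-row tibble: `nucleus_excluded_volume_um3`,
#'   `photoreceptor_density_per_um3`, `photoreceptor_density_2sf`.
#' @examples
#' summarise_cell_volumes(2220.2, 141, 90)
#' @export
summarise_cell_volumes <- function(cytoplasm_volume_um3, nuclei_volumes_um3,
                                   photoreceptors_supported = NA_integer_) {
  dens <- photoreceptors_supported / cytoplasm_volume_um3
  tibble::tibble(
    nucleus_excluded_volume_um3 =
      cytoplasm_volume_um3 - sum(nuclei_volumes_um3),
    photoreceptor_density_per_um3 = dens,
    photoreceptor_density_2sf = signif(dens, 2))
}

#' Photoreceptor outer segments supported by each cell
#'
#' An outer segment is supported by a cell iff its label shares at least
#' one 6-connected voxel face with the cell's microvilli compartment. An
#' OS touching the microvilli of several cells is assigned to each of them
#' and flagged (`shared = TRUE`).
#'
#' @param vol A [label_volume].
#' @return A tibble with one row per (cell, OS) support relation:
#'   `cell_id`, `os_label`, `os_id`, `n_faces`, `contact_area_um2`,
#'   `shared`.
#' @export
os_support_table <- function(vol) {
  os_tab <- vol$table[vol$table$compartment == "outer_segment", ]
  mv_tab <- vol$table[vol$table$compartment == "microvilli", ]
  if (nrow(os_tab) == 0L) {
    warning("no outer_segment labels in volume", call. = FALSE)
    return(tibble::tibble(cell_id = character(), os_label = integer(),
                          os_id = character(), n_faces = integer(),
                          contact_area_um2 = numeric(), shared = logical()))
  }
  pairs <- label_face_pairs(vol$grid)
  fa <- face_areas_um2(vol$spacing)
  sel <- (pairs$a %in% os_tab$label & pairs$b %in% mv_tab$label) |
    (pairs$b %in% os_tab$label & pairs$a %in% mv_tab$label)
  pairs <- pairs[sel, ]
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(cell_id = character(), os_label = integer(),
                          os_id = character(), n_faces = integer(),
                          contact_area_um2 = numeric(), shared = logical()))
  }
  os_lab <- ifelse(pairs$a %in% os_tab$label, pairs$a, pairs$b)
  mv_lab <- ifelse(pairs$a %in% os_tab$label, pairs$b, pairs$a)
  mv2cell <- stats::setNames(mv_tab$cell, mv_tab$label)
  os2id <- stats::setNames(os_tab$cell, os_tab$label)
  rel <- tibble::tibble(cell_id = unname(mv2cell[as.character(mv_lab)]),
                        os_label = os_lab,
                        os_id = unname(os2id[as.character(os_lab)]),
                        n_faces = pairs$n,
                        contact_area_um2 = unname(fa[pairs$axis]) * pairs$n)
  rel <- dplyr::summarise(
    dplyr::group_by(rel, .data$cell_id, .data$os_label, .data$os_id),
    n_faces = sum(.data$n_faces),
    contact_area_um2 = sum(.data$contact_area_um2), .groups = "drop")
  shared_os <- rel$os_label[duplicated(rel$os_label)]
  rel$shared <- rel$os_label %in% shared_os
  dplyr::arrange(rel, .data$cell_id, .data$os_label)
}

#' Count photoreceptors supported by one cell
#'
#' @param vol A [label_volume].
#' @param cell_id Cell identifier.
#' @param os_assignment Optional precomputed [os_support_table] (avoids a
#'   full repeat scan when summarising several cells).
#' @return A list: `count`, `os_labels`, `n_shared` (how many of them also
#'   touch another cell's microvilli).
#' @export
count_supported_photoreceptors <- function(vol, cell_id,
                                           os_assignment = NULL) {
  if (is.null(os_assignment)) os_assignment <- os_support_table(vol)
  mine <- os_assignment[os_assignment$cell_id == cell_id, ]
  list(count = nrow(mine), os_labels = mine$os_label,
       n_shared = sum(mine$shared))
}

#' Microvilli-photoreceptor contact surface of one cell
#'
#' Voxel-face area between the cell's microvilli compartment and the union
#' of all outer-segment labels, um^2.
#'
#' @param vol A [label_volume].
#' @param cell_id Cell identifier.
#' @return Contact area in um^2 (0 when nothing touches).
#' @export
microvilli_contact_area <- function(vol, cell_id) {
  mv_labs <- labels_for(vol$table, cell = cell_id,
                        compartment = "microvilli")
  os_labs <- labels_for(vol$table, compartment = "outer_segment")
  if (length(mv_labs) == 0L || length(os_labs) == 0L) return(0)
  d <- dim(vol$grid)
  bbs <- label_bboxes(vol$grid, labels = mv_labs)
  bb <- bbox_of_labels(bbs, mv_labs)
  if (is.null(bb)) return(0)
  crop <- crop_bbox(vol$grid, pad_bbox(bb, d, pad = 1L))
  n <- .face_counts(mask_of_labels(crop, mv_labs),
                    mask_of_labels(crop, os_labs))
  sum(n * face_areas_um2(vol$spacing))
}

# --- 3D connected components --------------------------------------------

# neighbour offsets ("positive half") for a connectivity class
.cc_offsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  ord <- rowSums(abs(offs))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord >= 1 & ord <= 2,
                 "26" = ord >= 1,
                 stop("connectivity must be 6, 18 or 26", call. = FALSE))
  offs <- offs[keep, , drop = FALSE]
  # keep one of each +/- pair
  offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
         (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
       drop = FALSE]
}

# connected components of a logical 3D mask; returns a list with
# membership (integer vector over TRUE voxels), sizes, and the voxel
# coordinates (iy, jx, kz)
label_components <- function(mask, connectivity = 26) {
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) {
    return(list(n_components = 0L, sizes = integer(0),
                membership = integer(0),
                coords = matrix(integer(0), 0, 3)))
  }
  d <- dim(mask)
  iy <- as.integer((idx - 1L) %% d[1] + 1L)
  rest <- (idx - 1L) %/% d[1]
  jx <- as.integer(rest %% d[2] + 1L)
  kz <- as.integer(rest %/% d[2] + 1L)
  dt <- data.table::data.table(iy = iy, jx = jx, kz = kz,
                               vid = seq_len(n))
  data.table::setkey(dt, iy, jx, kz)
  offs <- .cc_offsets(connectivity)
  edges <- lapply(seq_len(nrow(offs)), function(r) {
    sh <- data.table::data.table(iy = iy + offs[r, 1],
                                 jx = jx + offs[r, 2],
                                 kz = kz + offs[r, 3],
                                 from = seq_len(n))
    m <- dt[sh, on = c("iy", "jx", "kz"), nomatch = NULL]
    cbind(m$from, m$vid)
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)
  list(n_components = as.integer(comp$no), sizes = as.integer(comp$csize),
       membership = as.integer(comp$membership),
       coords = cbind(iy = iy, jx = jx, kz = kz))
}

#' Mitochondria statistics for one cell
#'
#' Individual mitochondria are the connected components (26-connectivity
#' by default, matching how a human tracer merges diagonally touching
#' profiles; configurable to 18 or 6) of the cell's mitochondrion
#' compartment. Volumes are reported in nm^3, the scale on which published
#' organelle tables are printed. `basal_fraction` is the fraction of
#' mitochondrial volume lying in the basal third of the cell's own
#' y-extent (the cell solid excluding microvilli — cells are sheared, so
#' the global grid is the wrong reference frame).
#'
#' @param vol A [label_volume].
#' @param cell_id Cell identifier.
#' @param connectivity 26 (default), 18 or 6.
#' @return An object of class `mitochondria_stats`: `count`,
#'   `mean_volume_nm3`, `sd_volume_nm3`, `min_volume_nm3`,
#'   `total_volume_nm3`, `basal_fraction`, `component_volumes_nm3`,
#'   `connectivity`. Methods: `tidy()` (per-component tibble), `glance()`
#'   (one-row tibble), `autoplot()` (volume histogram).
#' @export
mitochondria_stats <- function(vol, cell_id, connectivity = 26) {
  mito_labs <- labels_for(vol$table, cell = cell_id,
                          compartment = "mitochondrion")
  vv_nm3 <- voxel_volume_nm3(vol$spacing)
  empty <- function() {
    structure(list(cell_id = cell_id, count = 0L, mean_volume_nm3 = 0,
                   sd_volume_nm3 = 0, min_volume_nm3 = 0,
                   total_volume_nm3 = 0, basal_fraction = NA_real_,
                   component_volumes_nm3 = numeric(0),
                   connectivity = connectivity),
              class = "mitochondria_stats")
  }
  if (length(mito_labs) == 0L) return(empty())
  d <- dim(vol$grid)
  solid_labs <- labels_for(vol$table, cell = cell_id,
                           compartment = .cell_solid_kinds)
  bbs <- label_bboxes(vol$grid, labels = solid_labs)
  bb_m <- bbox_of_labels(bbs, mito_labs)
  if (is.null(bb_m)) return(empty())
  bb_cell <- bbox_of_labels(bbs, solid_labs)
  bbp <- pad_bbox(bb_m, d, pad = 1L)
  crop <- crop_bbox(vol$grid, bbp)
  cc <- label_components(mask_of_labels(crop, mito_labs), connectivity)
  vols <- as.numeric(cc$sizes) * vv_nm3
  # basal third of the cell's own apical->basal extent
  y0 <- bb_cell$y[1]; y1 <- bb_cell$y[2]
  y_basal_from <- y1 - floor((y1 - y0 + 1L) / 3) + 1L
  yy <- cc$coords[, "iy"] + (bbp$y[1] - 1L)  # back to grid frame
  basal_vox <- sum(yy >= y_basal_from)
  structure(list(
    cell_id = cell_id, count = as.integer(cc$n_components),
    mean_volume_nm3 = mean(vols),
    sd_volume_nm3 = if (length(vols) > 1) stats::sd(vols) else 0,
    min_volume_nm3 = min(vols), total_volume_nm3 = sum(vols),
    basal_fraction = basal_vox / length(yy),
    component_volumes_nm3 = vols, connectivity = connectivity),
    class = "mitochondria_stats")
}

#' @export
print.mitochondria_stats <- function(x, ...) {
  cat(sprintf(
    "<mitochondria_stats> %s: %d organelles, mean %.3g nm^3, total %.3g nm^3 (%d-connectivity)\n",
    x$cell_id, x$count, x$mean_volume_nm3, x$total_volume_nm3,
    x$connectivity))
  invisible(x)
}

#' Mitochondrial volume as a fraction of cytoplasm
#'
#' The published convention for the denominator is ambiguous (cytoplasm
#' with or without nuclei, with or without microvilli yield fractions
#' differing three-fold), so the denominator volume is an explicit
#' argument rather than a hidden choice.
#'
#' @param stats A [mitochondria_stats] object.
#' @param cytoplasm_volume_um3 Denominator volume, um^3 (> 0).
#' @return Percentage (0-100).
#' @export
mito_volume_fraction <- function(stats, cytoplasm_volume_um3) {
  if (!is.numeric(cytoplasm_volume_um3) || cytoplasm_volume_um3 <= 0) {
    stop("cytoplasm_volume_um3 must be positive", call. = FALSE)
  }
  100 * (stats$total_volume_nm3 / NM3_PER_UM3) / cytoplasm_volume_um3
}

#' Full per-cell summary
#'
#' Assembles the per-cell quantities of a reconstructed-cell table:
#' cytoplasm volume (cell body plus nuclei plus mitochondria — nuclei
#' included, microvilli and sub-RPE spaces excluded), per-nucleus volumes,
#' the nucleus-excluded volume, microvilli and infold volumes,
#' photoreceptors supported, photoreceptor density (full precision and
#' 2 significant figures) and the microvilli-photoreceptor contact area.
#'
#' @param vol A [label_volume].
#' @param cell_id Cell identifier.
#' @param os_assignment Optional precomputed [os_support_table].
#' @param morpho Optional precomputed [morphometry_table].
#' @return A one-row tibble (list-column `nuclei_volumes_um3`).
#' @export
cell_summary <- function(vol, cell_id, os_assignment = NULL,
                         morpho = NULL) {
  if (!cell_id %in% vol$table$cell) {
    stop("no labels for cell '", cell_id, "'", call. = FALSE)
  }
  if (is.null(morpho)) morpho <- morphometry_table(vol)
  m <- morpho[morpho$cell_id == cell_id, ]
  vol_of <- function(comp) {
    v <- m$volume_um3[m$compartment == comp]
    if (length(v) == 0L) 0 else sum(v)
  }
  vv <- voxel_volume_nm3(vol$spacing) / NM3_PER_UM3
  nuc_labs <- labels_for(vol$table, cell = cell_id, compartment = "nucleus")
  counts <- tabulate(vol$grid, nbins = max(vol$table$label))
  nuc_vols <- counts[nuc_labs] * vv
  cyto <- vol_of("cell_body") + sum(nuc_vols) + vol_of("mitochondrion")
  supp <- count_supported_photoreceptors(vol, cell_id, os_assignment)
  arith <- summarise_cell_volumes(cyto, nuc_vols, supp$count)
  tibble::tibble(
    cell_id = cell_id,
    n_nuclei = length(nuc_labs),
    cytoplasm_volume_um3 = cyto,
    nuclei_volumes_um3 = list(as.numeric(nuc_vols)),
    nucleus_excluded_volume_um3 = arith$nucleus_excluded_volume_um3,
    microvilli_volume_um3 = vol_of("microvilli"),
    infold_volume_um3 = vol_of("basal_infold_space"),
    photoreceptors_supported = supp$count,
    photoreceptors_shared = supp$n_shared,
    photoreceptor_density_per_um3 = arith$photoreceptor_density_per_um3,
    photoreceptor_density_2sf = arith$photoreceptor_density_2sf,
    microvilli_contact_area_um2 = microvilli_contact_area(vol, cell_id))
}
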