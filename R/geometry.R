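# Linear and angular measurements under the serial-stack sampling
# protocol: every `slice_interval`-th slice is visited and a fixed number
# of seeded-random measurements is taken per visited slice.

#' Slice-sampling scheme
#'
#' @param slice_interval Visit every n-th slice (protocol default 50).
#' @param measurements_per_slice Measurements per visited slice
#'   (protocol default 10).
#' @param seed Integer seed making the sampled positions reproducible.
#' @return An object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(slice_interval = 50L,
                            measurements_per_slice = 10L, seed = 1L) {
  if (slice_interval < 1L || measurements_per_slice < 1L) {
    stop("slice_interval and measurements_per_slice must be >= 1",
         call. = FALSE)
  }
  structure(list(slice_interval = as.integer(slice_interval),
                 measurements_per_slice = as.integer(measurements_per_slice),
                 seed = as.integer(seed)),
            class = "sampling_scheme")
}

sampled_slices <- function(nz, scheme) {
  if (scheme$slice_interval > nz) {
    stop("slice_interval (", scheme$slice_interval,
         ") exceeds the stack depth (", nz, "); no slices sampled",
         call. = FALSE)
  }
  seq.int(scheme$slice_interval, nz, by = scheme$slice_interval)
}

#' A set of repeated linear measurements
#'
#' Container for repeated manual-protocol measurements of one quantity
#' (lengths, angles, thicknesses): the raw samples, their mean and sample
#' standard deviation (n-1 denominator; reported as 0 with a flag when
#' n = 1).
#'
#' @param quantity Name of the measured quantity.
#' @param samples Numeric vector (n >= 1).
#' @param units Unit string ("um", "nm", "deg").
#' @return Object of class `linear_measurement_set`. Methods: `print()`,
#'   `format()` (the "mean +/- SD" style), `tidy()`, `glance()`,
#'   `autoplot()`.
#' @export
linear_measurement_set <- function(quantity, samples, units) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("need at least one sample for '", quantity, "'", call. = FALSE)
  }
  structure(list(quantity = quantity, samples = samples, units = units,
                 mean = mean(samples),
                 sd = if (length(samples) > 1) stats::sd(samples) else 0,
                 sd_defined = length(samples) > 1,
                 n = length(samples)),
            class = "linear_measurement_set")
}

#' @export
format.linear_measurement_set <- function(x, digits = 3, ...) {
  sprintf("%s %s ± %s SD (n = %d)",
          format(signif(x$mean, digits)), x$units,
          format(signif(x$sd, digits)), x$n)
}

#' @export
print.linear_measurement_set <- function(x, ...) {
  cat("<", x$quantity, "> ", format(x), "\n", sep = "")
  invisible(x)
}

# in-plane 2D connected components of a logical matrix, 8-connected.
# (EBImage::bwlabel is 4-connected, which fragments thin oblique bands —
# a rasterised tilted rod profile is a diagonal staircase.)
.bwlabel2d <- function(m) {
  cc <- label_components(array(m, c(dim(m), 1L)), connectivity = 26)
  out <- matrix(0L, nrow(m), ncol(m))
  if (cc$n_components > 0L) {
    out[cbind(cc$coords[, 1], cc$coords[, 2])] <- cc$membership
  }
  out
}

# geodesic sweep over one in-plane component: returns the chord length
# (um) from the root pixel to the geodesically farthest pixel and the
# chord angle (degrees from +x apical tangent, apical = -y up)
.component_chord <- function(py, px, dx_um, dy_um) {
  n <- length(py)
  root <- which(py == max(py))
  root <- root[which.min(px[root])]
  if (n == 1L) return(c(length = 0, angle = NA_real_,
                        tip_y = py[1], tip_x = px[1]))
  dt <- data.table::data.table(py = py, px = px, vid = seq_len(n))
  data.table::setkey(dt, py, px)
  offs <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  w_of <- c(dx_um, dy_um, sqrt(dx_um^2 + dy_um^2), sqrt(dx_um^2 + dy_um^2))
  edges <- NULL; wts <- NULL
  for (r in seq_len(nrow(offs))) {
    sh <- data.table::data.table(py = py + offs[r, 1], px = px + offs[r, 2],
                                 from = seq_len(n))
    m <- dt[sh, on = c("py", "px"), nomatch = NULL]
    if (nrow(m) > 0) {
      edges <- rbind(edges, cbind(m$from, m$vid))
      wts <- c(wts, rep(w_of[r], nrow(m)))
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges),
                                              attr = list(weight = wts))
  dists <- igraph::distances(g, v = root)[1, ]
  dists[!is.finite(dists)] <- -1
  tip <- which.max(dists)
  dxv <- (px[tip] - px[root]) * dx_um
  dyv <- (py[root] - py[tip]) * dy_um  # +ve when the tip is apical of root
  ang <- atan2(dyv, dxv) * 180 / pi
  c(length = sqrt(dxv^2 + dyv^2), angle = ang,
    tip_y = py[tip], tip_x = px[tip])
}

#' Microvillus length and tilt angle of one cell
#'
#' On every sampled slice, the in-plane connected components of the
#' cell's microvilli mask that are rooted at the apical surface (within
#' 2 pixels of the cell solid) are candidate microvillus profiles; for up
#' to `measurements_per_slice` seeded-randomly chosen profiles the root is
#' the basal-most pixel, the tip the geodesically farthest pixel from it,
#' and the measurement is the root-to-tip chord: its Euclidean length
#' (um) and its angle (degrees) from the +x apical tangent, measured in
#' the slice plane in (0, 180) — matching a manual two-point protractor
#' measurement. Rods perpendicular to the apical plane read 90 deg; rods
#' parallel to it read near 0 or 180 depending on the chord's x direction.
#'
#' @param vol A [label_volume].
#' @param cell_id Cell identifier.
#' @param scheme A [sampling_scheme].
#' @return List of class `microvillus_geometry`: `length`
#'   (a [linear_measurement_set], um), `angle` (degrees), and `details`
#'   (per-measurement tibble).
#' @export
microvillus_geometry <- function(vol, cell_id, scheme = sampling_scheme()) {
  mv_labs <- labels_for(vol$table, cell = cell_id,
                        compartment = "microvilli")
  if (length(mv_labs) == 0L) {
    stop("cell '", cell_id, "' has no microvilli compartment",
         call. = FALSE)
  }
  solid_labs <- labels_for(vol$table, cell = cell_id,
                           compartment = .cell_solid_kinds)
  d <- dim(vol$grid)
  dx_um <- vol$spacing$dx / NM_PER_UM
  dy_um <- vol$spacing$dy / NM_PER_UM
  slices <- sampled_slices(d[3], scheme)
  rows <- withr::with_seed(scheme$seed, {
    out <- list()
    for (k in slices) {
      sl <- vol$grid[, , k]
      mv2d <- mask_of_labels(sl, mv_labs)
      if (!any(mv2d)) next
      lab2d <- .bwlabel2d(mv2d)
      body2d <- mask_of_labels(sl, solid_labs)
      near_body <- if (any(body2d)) {
        EBImage::dilate(body2d * 1, EBImage::makeBrush(5, "box")) > 0
      } else array(TRUE, dim(body2d))
      comp_ids <- setdiff(unique(as.vector(lab2d)), 0)
      rooted <- comp_ids[vapply(comp_ids, function(cid) {
        any(lab2d == cid & near_body)
      }, logical(1))]
      if (length(rooted) == 0L) next
      take <- if (length(rooted) > scheme$measurements_per_slice) {
        sample(rooted, scheme$measurements_per_slice)
      } else rooted
      for (cid in take) {
        w <- which(lab2d == cid, arr.ind = TRUE)
        ch <- .component_chord(w[, 1], w[, 2], dx_um, dy_um)
        out[[length(out) + 1L]] <- tibble::tibble(
          slice = k, component = cid,
          length_um = ch[["length"]], angle_deg = ch[["angle"]])
      }
    }
    out
  })
  if (length(rows) == 0L) {
    stop("no microvilli found on any sampled slice for cell '", cell_id,
         "'", call. = FALSE)
  }
  details <- dplyr::bind_rows(rows)
  details <- details[!is.na(details$angle_deg), ]
  structure(list(
    cell_id = cell_id,
    length = linear_measurement_set("microvillus_length",
                                    details$length_um, "um"),
    angle = linear_measurement_set("microvillus_angle",
                                   details$angle_deg, "deg"),
    details = details, scheme = scheme),
    class = "microvillus_geometry")
}

#' @export
print.microvillus_geometry <- function(x, ...) {
  cat(sprintf("<microvillus_geometry> %s\n  length: %s\n  angle:  %s\n",
              x$cell_id, format(x$length), format(x$angle)))
  invisible(x)
}

#' RPE cell height (body and combined with microvilli)
#'
#' Body height: on every sampled slice, the y-extent (in um) of the cell
#' solid (all compartments except microvilli) in sampled through-columns —
#' columns that reach both the cell's apical-most and basal-most rows in
#' that slice, so the slanted side walls of a rhomboid cell do not
#' truncate the measurement; shear leaves the through-column height equal
#' to the true apical-to-basal height. Combined height is the explicit
#' composition: mean body height plus mean microvillus length.
#'
#' @param vol A [label_volume].
#' @param cell_id Cell identifier.
#' @param scheme A [sampling_scheme].
#' @param microvilli_length Mean microvillus length (um) to compose with;
#'   if `NULL` it is measured via [microvillus_geometry] (when the cell
#'   has microvilli) or taken as 0.
#' @return List of class `rpe_height`: `body_height`
#'   (a [linear_measurement_set], um), `microvilli_length_um`,
#'   `combined_height_um` (their exact sum).
#' @export
rpe_height <- function(vol, cell_id, scheme = sampling_scheme(),
                       microvilli_length = NULL) {
  solid_labs <- labels_for(vol$table, cell = cell_id,
                           compartment = .cell_solid_kinds)
  if (length(solid_labs) == 0L) {
    stop("cell '", cell_id, "' has no body compartment", call. = FALSE)
  }
  d <- dim(vol$grid)
  dy_um <- vol$spacing$dy / NM_PER_UM
  slices <- sampled_slices(d[3], scheme)
  samples <- withr::with_seed(scheme$seed, {
    out <- numeric(0)
    for (k in slices) {
      m2d <- mask_of_labels(vol$grid[, , k], solid_labs)
      cols <- which(colSums(m2d) > 0)
      if (length(cols) == 0L) next
      ymin_c <- apply(m2d[, cols, drop = FALSE], 2,
                      function(v) which(v)[1])
      ymax_c <- apply(m2d[, cols, drop = FALSE], 2,
                      function(v) max(which(v)))
      full <- cols[ymin_c <= min(ymin_c) + 1L & ymax_c >= max(ymax_c) - 1L]
      if (length(full) == 0L) next
      pick <- if (length(full) > scheme$measurements_per_slice) {
        sample(full, scheme$measurements_per_slice)
      } else full
      i <- match(pick, cols)
      out <- c(out, (ymax_c[i] - ymin_c[i] + 1L) * dy_um)
    }
    out
  })
  if (length(samples) == 0L) {
    stop("cell '", cell_id, "' has an empty footprint on all sampled slices",
         call. = FALSE)
  }
  body <- linear_measurement_set("body_height", samples, "um")
  if (is.null(microvilli_length)) {
    has_mv <- length(labels_for(vol$table, cell = cell_id,
                                compartment = "microvilli")) > 0
    microvilli_length <- if (has_mv) {
      microvillus_geometry(vol, cell_id, scheme)$length$mean
    } else 0
  }
  structure(list(cell_id = cell_id, body_height = body,
                 microvilli_length_um = microvilli_length,
                 combined_height_um = body$mean + microvilli_length),
            class = "rpe_height")
}

#' @export
print.rpe_height <- function(x, ...) {
  cat(sprintf(
    "<rpe_height> %s: body %s; + microvilli %.3g um = %.3g um combined\n",
    x$cell_id, format(x$body_height), x$microvilli_length_um,
    x$combined_height_um))
  invisible(x)
}

#' Bruch's membrane thickness
#'
#' On every sampled slice, at seeded-random x positions under the cell
#' footprints, thickness is the length of the contiguous run of
#' Bruch's-membrane voxels along y times dy, in nm (the longest run is
#' taken should the column intersect the membrane more than once).
#' Columns without any membrane voxel are skipped and counted in the
#' `n_skipped` attribute, never zero-filled.
#'
#' @param vol A [label_volume] with a `bruchs_membrane` compartment.
#' @param scheme A [sampling_scheme].
#' @return A [linear_measurement_set] (nm) with attribute `n_skipped`.
#' @export
brm_thickness <- function(vol, scheme = sampling_scheme()) {
  brm_labs <- labels_for(vol$table, compartment = "bruchs_membrane")
  if (length(brm_labs) == 0L) {
    stop("volume has no bruchs_membrane compartment", call. = FALSE)
  }
  body_labs <- labels_for(vol$table, compartment = .cell_solid_kinds)
  d <- dim(vol$grid)
  slices <- sampled_slices(d[3], scheme)
  skipped <- 0L
  samples <- withr::with_seed(scheme$seed, {
    out <- numeric(0)
    for (k in slices) {
      sl <- vol$grid[, , k]
      brm2d <- mask_of_labels(sl, brm_labs)
      if (!any(brm2d)) next
      foot <- if (length(body_labs) > 0) {
        which(colSums(mask_of_labels(sl, body_labs)) > 0)
      } else which(colSums(brm2d) > 0)
      if (length(foot) == 0L) next
      pick <- if (length(foot) > scheme$measurements_per_slice) {
        sample(foot, scheme$measurements_per_slice)
      } else foot
      for (jx in pick) {
        r <- rle(brm2d[, jx])
        runs <- r$lengths[r$values]
        if (length(runs) == 0L) {
          skipped <- skipped + 1L
          next
        }
        out <- c(out, max(runs) * vol$spacing$dy)
      }
    }
    out
  })
  if (length(samples) == 0L) {
    stop("no Bruch's membrane found under any sampled column", call. = FALSE)
  }
  if (skipped > 0L) {
    message(skipped, " sampled column(s) had no Bruch's membrane; skipped")
  }
  out <- linear_measurement_set("brm_thickness", samples, "nm")
  attr(out, "n_skipped") <- skipped
  out
}
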