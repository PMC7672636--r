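# Synthetic outer-retina phantom: rasterisation primitives and the scene
# generator. All physical coordinates are in um; the voxel with index
# (iy, jx, kz) has its centre at ((iy-0.5)*dy, (jx-0.5)*dx, (kz-0.5)*dz).
# Rasterisation rule throughout: a voxel belongs to a solid iff its centre
# lies inside the solid (unbiased under sub-voxel placement jitter).

# index range of voxel centres falling in [lo, hi] (um) along an axis
.idx_range <- function(lo, hi, d_um, n) {
  i0 <- max(1L, as.integer(ceiling(lo / d_um + 0.5 - 1e-9)))
  i1 <- min(n, as.integer(floor(hi / d_um + 0.5 + 1e-9)))
  c(i0, i1)
}

# linear indices of voxels whose centre is within `radius` of segment p0-p1.
# p0, p1 are c(x, y, z) in um; dims = c(ny, nx, nz); sp_um = c(dx,dy,dz) um.
.capsule_indices <- function(p0, p1, radius, sp_um, dims) {
  lo <- pmin(p0, p1) - radius
  hi <- pmax(p0, p1) + radius
  rx <- .idx_range(lo[1], hi[1], sp_um[1], dims[2])
  ry <- .idx_range(lo[2], hi[2], sp_um[2], dims[1])
  rz <- .idx_range(lo[3], hi[3], sp_um[3], dims[3])
  if (rx[1] > rx[2] || ry[1] > ry[2] || rz[1] > rz[2]) return(integer(0))
  xs <- (rx[1]:rx[2] - 0.5) * sp_um[1]
  ys <- (ry[1]:ry[2] - 0.5) * sp_um[2]
  zs <- (rz[1]:rz[2] - 0.5) * sp_um[3]
  nxl <- length(xs); nyl <- length(ys); nzl <- length(zs)
  # local coordinates, y fastest (matches array layout)
  Y <- rep(ys, times = nxl * nzl)
  X <- rep(rep(xs, each = nyl), times = nzl)
  Z <- rep(zs, each = nyl * nxl)
  v <- p1 - p0
  L2 <- sum(v^2)
  wx <- X - p0[1]; wy <- Y - p0[2]; wz <- Z - p0[3]
  if (L2 == 0) {
    d2 <- wx^2 + wy^2 + wz^2
  } else {
    t <- pmin(pmax((wx * v[1] + wy * v[2] + wz * v[3]) / L2, 0), 1)
    d2 <- (wx - t * v[1])^2 + (wy - t * v[2])^2 + (wz - t * v[3])^2
  }
  keep <- which(d2 <= radius^2)
  if (length(keep) == 0L) return(integer(0))
  iy <- ry[1] + (keep - 1L) %% nyl
  rest <- (keep - 1L) %/% nyl
  jx <- rx[1] + rest %% nxl
  kz <- rz[1] + rest %/% nxl
  iy + (jx - 1L) * dims[1] + (kz - 1L) * dims[1] * dims[2]
}

# linear indices of voxels inside an axis-aligned ellipsoid
.ellipsoid_indices <- function(centre, semiaxes, sp_um, dims) {
  lo <- centre - semiaxes
  hi <- centre + semiaxes
  rx <- .idx_range(lo[1], hi[1], sp_um[1], dims[2])
  ry <- .idx_range(lo[2], hi[2], sp_um[2], dims[1])
  rz <- .idx_range(lo[3], hi[3], sp_um[3], dims[3])
  if (rx[1] > rx[2] || ry[1] > ry[2] || rz[1] > rz[2]) return(integer(0))
  xs <- ((rx[1]:rx[2] - 0.5) * sp_um[1] - centre[1]) / semiaxes[1]
  ys <- ((ry[1]:ry[2] - 0.5) * sp_um[2] - centre[2]) / semiaxes[2]
  zs <- ((rz[1]:rz[2] - 0.5) * sp_um[3] - centre[3]) / semiaxes[3]
  nxl <- length(xs); nyl <- length(ys); nzl <- length(zs)
  Y2 <- rep(ys^2, times = nxl * nzl)
  X2 <- rep(rep(xs^2, each = nyl), times = nzl)
  Z2 <- rep(zs^2, each = nyl * nxl)
  keep <- which(X2 + Y2 + Z2 <= 1)
  if (length(keep) == 0L) return(integer(0))
  iy <- ry[1] + (keep - 1L) %% nyl
  rest <- (keep - 1L) %/% nyl
  jx <- rx[1] + rest %% nxl
  kz <- rz[1] + rest %/% nxl
  iy + (jx - 1L) * dims[1] + (kz - 1L) * dims[1] * dims[2]
}

capsule_volume_um3 <- function(L, r) pi * r^2 * L + 4 / 3 * pi * r^3

ellipsoid_volume_um3 <- function(semiaxes) 4 / 3 * pi * prod(semiaxes)

# volume of the lens a wider collinear rod (radius ro) bites out of the
# shaft of a thinner rod (radius rm) behind the junction plane
.collinear_lens_volume <- function(rm, ro) {
  if (ro <= 0 || rm <= 0) return(0)
  if (ro <= rm) return(2 / 3 * pi * ro^3)
  ds <- sqrt(ro^2 - rm^2)
  pi * rm^2 * ds + pi * (ro^2 * (ro - ds) - (ro^3 - ds^3) / 3)
}

#' Rasterise a capsule (rod) into a voxel grid
#'
#' A rod is modelled as a capsule: all points within `radius` of the axis
#' segment. A voxel is set iff its centre lies inside the capsule. The
#' analytic solid volume, `pi r^2 L + (4/3) pi r^3`, is attached as the
#' `analytic_volume_um3` attribute; a zero-length axis degenerates to a
#' sphere.
#'
#' @param p0,p1 Axis endpoints, `c(x, y, z)` in um.
#' @param radius Rod radius, um.
#' @param spacing A [voxel_spacing] (nm).
#' @param dim Grid dimensions `c(ny, nx, nz)`.
#' @return Logical array of dimension `dim` with attribute
#'   `analytic_volume_um3`.
#' @examples
#' sp <- voxel_spacing(50, 50, 50)
#' m <- rasterise_rod(c(1, 6, 1), c(1, 1, 1), radius = 0.2, sp,
#'                    dim = c(140, 40, 40))
#' sum(m) * 50^3 / 1e9                  # close to
#' attr(m, "analytic_volume_um3")       # the capsule volume
#' @export
rasterise_rod <- function(p0, p1, radius, spacing, dim) {
  stopifnot(is_voxel_spacing(spacing), length(dim) == 3L)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  sp_um <- c(spacing$dx, spacing$dy, spacing$dz) / NM_PER_UM
  half_diag <- 0.5 * sqrt(sum(sp_um^2))
  if (radius < half_diag) {
    warning(sprintf(
      "rod radius %.3g um is below the voxel half-diagonal %.3g um; ",
      radius, half_diag), "rasterisation is unreliable at this spacing",
      call. = FALSE)
  }
  idx <- .capsule_indices(as.numeric(p0), as.numeric(p1), radius, sp_um,
                          as.integer(dim))
  m <- array(FALSE, dim)
  m[idx] <- TRUE
  L <- sqrt(sum((as.numeric(p1) - as.numeric(p0))^2))
  attr(m, "analytic_volume_um3") <- capsule_volume_um3(L, radius)
  m
}

# conservative separation test: point p vs ellipsoid (centre, semiaxes),
# with every semiaxis inflated by `inflate`
.outside_inflated_ellipsoid <- function(p, centre, semiaxes, inflate) {
  s <- semiaxes + inflate
  sum(((p - centre) / s)^2) > 1
}

#' Generate a synthetic outer-retina scene
#'
#' Builds a monolayer of rhomboid RPE cells with ellipsoidal nuclei,
#' basally clustered ellipsoidal mitochondria, spherical basal infold
#' pockets, slanted apical microvilli rods, collinear photoreceptor outer
#' segment (OS) rods touching them, and a Bruch's membrane slab of
#' Gaussian-varying thickness underneath — together with the analytic
#' ground truth every rasterised quantity should recover.
#'
#' Overlaps are resolved by fixed precedence (later layers win):
#' Bruch's membrane < cell body < infold pocket < nucleus < mitochondrion <
#' microvilli < OS; carved voxel counts are recorded in
#' `truth$overlaps`. Ground-truth volumes are the analytic solid volumes
#' after this carving (e.g. a microvillus loses the exactly-computable cap
#' its OS claims), so rasterised and true volumes are directly comparable.
#'
#' @param spec A [phantom_spec].
#' @return A list with elements `volume` (a [label_volume]) and `truth`
#'   (class `phantom_truth`): per-cell analytic volumes and counts
#'   (`truth$cells`), per-organelle mitochondria (`truth$mitochondria`),
#'   OS ownership (`truth$os`), the Bruch's membrane thickness field
#'   (`truth$brm`), analytic flat-interface areas for adjacent cell pairs
#'   (`truth$interfaces`) and the overlap ledger (`truth$overlaps`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, .generate_phantom_impl(spec))
}

.generate_phantom_impl <- function(spec) {
  sp <- spec$spacing
  dxu <- sp$dx / NM_PER_UM; dyu <- sp$dy / NM_PER_UM
  dzu <- sp$dz / NM_PER_UM
  sp_um <- c(dxu, dyu, dzu)
  W <- spec$cell_width; H <- spec$cell_body_height
  shear <- tan(spec$shear_angle * pi / 180)
  theta <- spec$microvilli_tilt * pi / 180
  mvL <- spec$microvilli_length
  os_overlap <- 0.1  # axial overlap guaranteeing OS-microvilli contact, um
  have_rods <- spec$rods_per_cell > 0L

  # --- scene extents (grid-aligned margins) ------------------------------
  u_dir <- c(cos(theta), -sin(theta), 0)  # root->tip, tip is apical (-y)
  # rods carrying an OS get their axis extended by the interdigitation
  # allowance the OS carves away, so `microvilli_length` is the visible
  # (measurable) microvillus length after carving
  os_allow <- os_overlap + spec$os_radius
  axis_reach <- if (have_rods) {
    mvL + (if (spec$os_per_cell > 0) spec$os_radius + spec$os_length else 0)
  } else 0
  lx_reach <- if (have_rods) {
    axis_reach * abs(cos(theta)) +
      max(spec$microvilli_radius, spec$os_radius) + 0.3
  } else 0.3
  rise <- if (have_rods) {
    axis_reach * sin(theta) +
      max(spec$microvilli_radius, spec$os_radius) + 0.15
  } else 0.2
  t_cap_nm <- max(sp$dy, spec$brm_mean_thickness +
                    3.5 * spec$brm_thickness_sd)
  mx0 <- ceiling((if (cos(theta) < 0 || !have_rods) lx_reach else 0.3) /
                   dxu) * dxu
  mx1 <- max(shear, 0) * H + 0.3 +
    (if (cos(theta) > 0 && have_rods) lx_reach else 0)
  my0 <- ceiling(rise / dyu) * dyu
  my1 <- t_cap_nm / NM_PER_UM + 0.15
  mz <- ceiling(0.3 / dzu) * dzu
  nx <- as.integer(ceiling((mx0 + spec$n_cells_x * W + mx1) / dxu))
  ny <- as.integer(ceiling((my0 + H + my1) / dyu))
  nz <- as.integer(ceiling((2 * mz + spec$n_cells_z * W) / dzu))
  dims <- c(ny, nx, nz)
  if (prod(as.numeric(dims)) > 6e8) {
    stop("scene overflow: requested grid has ",
         format(prod(as.numeric(dims)), big.mark = ","),
         " voxels; reduce cell count/size or coarsen spacing",
         call. = FALSE)
  }
  y_ap <- my0; y_base <- my0 + H

  # --- geometric feasibility checks --------------------------------------
  nuc <- spec$nucleus_semiaxes
  if (any(spec$nuclei_per_cell >= 1L)) {
    if (2 * nuc[2] + 0.9 > H) {
      stop("scene overflow: nucleus does not fit cell height", call. = FALSE)
    }
    if (nuc[1] + abs(shear) * nuc[2] > W / 2 - 0.2) {
      stop("scene overflow: nucleus does not fit cell width", call. = FALSE)
    }
  }
  if (any(spec$nuclei_per_cell == 2L)) {
    if ((nuc[3] + 0.2) + nuc[3] > W / 2 - 0.25) {
      stop("scene overflow: two nuclei do not fit cell depth", call. = FALSE)
    }
  }
  if (spec$infold_pockets_per_cell > 0L &&
      2 * spec$pocket_radius + 0.35 > H) {
    stop("scene overflow: infold pockets do not fit cell height",
         call. = FALSE)
  }

  # --- label bookkeeping --------------------------------------------------
  lab_env <- new.env(parent = emptyenv())
  lab_env$next_id <- 1L
  lab_env$rows <- list()
  new_label <- function(cell, compartment) {
    id <- lab_env$next_id
    lab_env$next_id <- id + 1L
    lab_env$rows[[length(lab_env$rows) + 1L]] <-
      list(label = id, cell = cell, compartment = compartment)
    id
  }

  n_cells <- spec$n_cells_x * spec$n_cells_z
  cell_id_of <- function(c) sprintf("cell_%d", c)
  brm_label <- new_label("brm", "bruchs_membrane")
  body_labels <- integer(n_cells)
  nucleus_labels <- vector("list", n_cells)
  pocket_labels <- rep(NA_integer_, n_cells)
  mito_labels <- rep(NA_integer_, n_cells)
  mv_labels <- rep(NA_integer_, n_cells)
  for (c in seq_len(n_cells)) {
    body_labels[c] <- new_label(cell_id_of(c), "cell_body")
    nucleus_labels[[c]] <- vapply(seq_len(spec$nuclei_per_cell[c]),
                                  function(i) new_label(cell_id_of(c),
                                                        "nucleus"),
                                  integer(1))
    if (spec$infold_pockets_per_cell > 0L) {
      pocket_labels[c] <- new_label(cell_id_of(c), "basal_infold_space")
    }
    if (spec$mito_per_cell > 0L) {
      mito_labels[c] <- new_label(cell_id_of(c), "mitochondrion")
    }
    if (have_rods) mv_labels[c] <- new_label(cell_id_of(c), "microvilli")
  }

  # cell footprints at apical depth; shear shifts +x with depth
  cell_x0 <- function(c, y) {
    ix <- (c - 1L) %% spec$n_cells_x
    mx0 + ix * W + shear * (y - y_ap)
  }
  cell_z0 <- function(c) {
    iz <- (c - 1L) %/% spec$n_cells_x
    mz + iz * W
  }

  # --- per-cell random placements (fixed draw order) ----------------------
  nuclei <- list(); pockets <- list(); mitos <- list()
  mv_roots <- list(); os_rods <- list()
  os_counter <- 0L
  for (c in seq_len(n_cells)) {
    z0 <- cell_z0(c); zc <- z0 + W / 2
    # nuclei: deterministic placement (mid footprint; bi-nucleate split in z)
    ny_c <- spec$nuclei_per_cell[c]
    cy_n <- y_base - (nuc[2] + 0.7)
    cx_n <- cell_x0(c, cy_n) + W / 2
    offs <- if (ny_c == 1L) 0 else c(-(nuc[3] + 0.2), nuc[3] + 0.2)
    nuclei[[c]] <- lapply(seq_len(ny_c), function(i) {
      list(centre = c(cx_n, cy_n, zc + offs[i]), semiaxes = nuc)
    })
    # infold pockets: uniform in basal footprint, separated
    pk <- list()
    if (spec$infold_pockets_per_cell > 0L) {
      rp <- spec$pocket_radius
      cy_p <- y_base - rp - 0.15
      x0p <- cell_x0(c, cy_p)
      tries <- 0L
      while (length(pk) < spec$infold_pockets_per_cell) {
        tries <- tries + 1L
        if (tries > 1000L * spec$infold_pockets_per_cell) {
          stop("could not place infold pockets without overlap; ",
               "reduce count or radius", call. = FALSE)
        }
        p <- c(stats::runif(1, x0p + rp + 0.2, x0p + W - rp - 0.2), cy_p,
               stats::runif(1, z0 + rp + 0.2, z0 + W - rp - 0.2))
        ok <- all(vapply(nuclei[[c]], function(nu) {
          .outside_inflated_ellipsoid(p, nu$centre, nu$semiaxes, rp + 0.05)
        }, logical(1)))
        if (ok && spec$ensure_separation && length(pk) > 0) {
          dmin <- min(vapply(pk, function(q) {
            sqrt(sum((p - q$centre)^2))
          }, numeric(1)))
          ok <- dmin >= 2 * rp + 0.1
        }
        if (ok) pk[[length(pk) + 1L]] <- list(centre = p, radius = rp)
      }
    }
    pockets[[c]] <- pk
    # mitochondria: jittered ellipsoids, mito_basal_fraction in basal third
    mt <- list()
    if (spec$mito_per_cell > 0L) {
      n_basal <- round(spec$mito_basal_fraction * spec$mito_per_cell)
      tries <- 0L
      while (length(mt) < spec$mito_per_cell) {
        k <- length(mt) + 1L
        semi <- spec$mito_semiaxes * stats::runif(3, 0.7, 1.3)
        ms <- max(semi)
        basal <- k <= n_basal
        ylo <- if (basal) y_base - H / 3 + ms + 0.05 else y_ap + ms + 0.05
        yhi <- if (basal) y_base - ms - 0.05 else y_base - H / 3 - ms - 0.05
        if (yhi <= ylo) {
          stop("scene overflow: mitochondria do not fit the ",
               if (basal) "basal third" else "apical two-thirds",
               call. = FALSE)
        }
        placed <- FALSE
        while (!placed) {
          tries <- tries + 1L
          if (tries > 2000L * spec$mito_per_cell) {
            stop("could not place mitochondria without overlap; reduce ",
                 "mito_per_cell or mito_semiaxes", call. = FALSE)
          }
          cy <- stats::runif(1, ylo, yhi)
          x0m <- cell_x0(c, cy)
          p <- c(stats::runif(1, x0m + ms + 0.1, x0m + W - ms - 0.1), cy,
                 stats::runif(1, z0 + ms + 0.1, z0 + W - ms - 0.1))
          ok <- all(vapply(nuclei[[c]], function(nu) {
            .outside_inflated_ellipsoid(p, nu$centre, nu$semiaxes, ms + 0.05)
          }, logical(1)))
          if (ok && length(pk) > 0) {
            dmin <- min(vapply(pk, function(q) sqrt(sum((p - q$centre)^2)),
                               numeric(1)))
            ok <- dmin >= ms + spec$pocket_radius + 0.05
          }
          if (ok && spec$ensure_separation && length(mt) > 0) {
            dmin <- min(vapply(mt, function(q) {
              sqrt(sum((p - q$centre)^2)) - max(q$semiaxes)
            }, numeric(1)))
            ok <- dmin >= ms + 0.05
          }
          if (ok) {
            mt[[k]] <- list(centre = p, semiaxes = semi, basal = basal)
            placed <- TRUE
          }
        }
      }
    }
    mitos[[c]] <- mt
    # microvillus roots: jittered grid on the apical plane
    if (have_rods) {
      # roots on a jittered square grid; each x-column's z positions are
      # staggered by a golden-ratio offset (wrapped within the footprint,
      # so the circular z-lattice and its minimum spacing survive across
      # cell boundaries) — without the stagger all rods would share a few
      # discrete z-bands and interval-sampled slices could miss them all
      n_side <- ceiling(sqrt(spec$rods_per_cell))
      spg <- W / n_side
      pos <- expand.grid(ui = seq_len(n_side), vi = seq_len(n_side))
      sel <- if (nrow(pos) > spec$rods_per_cell) {
        sort(sample.int(nrow(pos), spec$rods_per_cell))
      } else seq_len(nrow(pos))
      jit <- min(0.05, spg / 8)
      x0a <- cell_x0(c, y_ap)
      zoff <- (pos$ui[sel] * 0.6180339887) %% 1 * spg
      roots <- cbind(
        x = x0a + (pos$ui[sel] - 0.5) * spg +
          stats::runif(length(sel), -jit, jit),
        y = y_ap,
        z = z0 + ((pos$vi[sel] - 0.5) * spg + zoff) %% W +
          stats::runif(length(sel), -jit, jit))
      mv_roots[[c]] <- roots
      if (spec$os_per_cell > 0L) {
        os_sel <- if (spec$os_per_cell < nrow(roots)) {
          sort(sample.int(nrow(roots), spec$os_per_cell))
        } else seq_len(nrow(roots))
        os_rods[[c]] <- os_sel
      } else os_rods[[c]] <- integer(0)
    } else {
      mv_roots[c] <- list(NULL)
      os_rods[[c]] <- integer(0)
    }
  }

  # OS labels (after all cell labels; one label per outer segment)
  os_table <- list()
  os_labels <- vector("list", n_cells)
  for (c in seq_len(n_cells)) {
    os_labels[[c]] <- vapply(seq_along(os_rods[[c]]), function(i) {
      os_counter <<- os_counter + 1L
      id <- new_label(sprintf("os_%03d", os_counter), "outer_segment")
      os_table[[os_counter]] <<- list(label = id, owner = cell_id_of(c))
      id
    }, integer(1))
  }

  # Bruch's membrane thickness field (drawn after placements); the slab
  # spans the full sheared footprint so every cell column has membrane
  bx0 <- mx0 + min(0, shear * H)
  bx1 <- mx0 + spec$n_cells_x * W + max(0, shear * H)
  bx_range <- .idx_range(bx0, bx1, dxu, nx)
  bz_range <- .idx_range(mz, mz + spec$n_cells_z * W, dzu, nz)
  nbx <- bx_range[2] - bx_range[1] + 1L
  nbz <- bz_range[2] - bz_range[1] + 1L
  t_nm <- matrix(stats::rnorm(nbx * nbz, spec$brm_mean_thickness,
                              spec$brm_thickness_sd), nbx, nbz)
  t_nm <- pmin(pmax(t_nm, sp$dy), t_cap_nm)
  t_vox <- pmax(1L, as.integer(round(t_nm / sp$dy)))

  # --- rasterise (precedence: later layers win; overlaps recorded) --------
  grid <- array(0L, dims)
  overlap_rows <- list()
  record_overlap <- function(prev, label) {
    prev <- prev[prev != 0L]
    if (length(prev) == 0L) return(invisible())
    tb <- table(prev)
    overlap_rows[[length(overlap_rows) + 1L]] <<- tibble::tibble(
      label = label, prior_label = as.integer(names(tb)),
      n_vox = as.integer(tb))
  }

  # Bruch's membrane slab
  iy_b0 <- as.integer(round(y_base / dyu))  # first BrM row index - 1
  col_jx <- rep(bx_range[1]:bx_range[2], times = nbz)
  col_kz <- rep(bz_range[1]:bz_range[2], each = nbx)
  for (r in seq_len(max(t_vox))) {
    onc <- which(t_vox >= r)
    if (length(onc) == 0L) break
    iy <- iy_b0 + r
    if (iy > ny) break
    idx <- iy + (col_jx[onc] - 1L) * ny + (col_kz[onc] - 1L) * ny * nx
    grid[idx] <- brm_label
  }

  # cell bodies (sheared prisms), row by row
  iy_ap <- as.integer(round(y_ap / dyu))
  body_rows <- (iy_ap + 1L):as.integer(round(y_base / dyu))
  for (c in seq_len(n_cells)) {
    z0 <- cell_z0(c)
    kzr <- .idx_range(z0, z0 + W, dzu, nz)
    for (iy in body_rows) {
      yc <- (iy - 0.5) * dyu
      x0 <- cell_x0(c, yc)
      jxr <- .idx_range(x0, x0 + W, dxu, nx)
      if (jxr[1] > jxr[2]) next
      grid[iy, jxr[1]:jxr[2], kzr[1]:kzr[2]] <- body_labels[c]
    }
  }

  # pockets, nuclei, mitochondria (in precedence order)
  for (c in seq_len(n_cells)) {
    for (pkt in pockets[[c]]) {
      idx <- .ellipsoid_indices(pkt$centre, rep(pkt$radius, 3), sp_um, dims)
      record_overlap(grid[idx], pocket_labels[c])
      grid[idx] <- pocket_labels[c]
    }
  }
  for (c in seq_len(n_cells)) {
    for (i in seq_along(nuclei[[c]])) {
      nu <- nuclei[[c]][[i]]
      idx <- .ellipsoid_indices(nu$centre, nu$semiaxes, sp_um, dims)
      record_overlap(grid[idx], nucleus_labels[[c]][i])
      grid[idx] <- nucleus_labels[[c]][i]
    }
  }
  for (c in seq_len(n_cells)) {
    if (length(mitos[[c]]) == 0L) next
    idx_all <- lapply(mitos[[c]], function(m) {
      .ellipsoid_indices(m$centre, m$semiaxes, sp_um, dims)
    })
    idx <- unlist(idx_all)
    record_overlap(grid[idx], mito_labels[c])
    grid[idx] <- mito_labels[c]
  }

  # microvilli, then outer segments (topmost layers)
  mv_tips <- vector("list", n_cells)
  for (c in seq_len(n_cells)) {
    roots <- mv_roots[[c]]
    if (is.null(roots) || nrow(roots) == 0L) next
    axis_len <- rep(mvL, nrow(roots))
    axis_len[os_rods[[c]]] <- mvL + os_allow  # OS carves this back to mvL
    tips <- roots + outer(axis_len, u_dir)
    mv_tips[[c]] <- tips
    idx <- unlist(lapply(seq_len(nrow(roots)), function(i) {
      .capsule_indices(roots[i, ], tips[i, ], spec$microvilli_radius,
                       sp_um, dims)
    }))
    record_overlap(grid[idx], mv_labels[c])
    grid[idx] <- mv_labels[c]
  }
  for (c in seq_len(n_cells)) {
    sel <- os_rods[[c]]
    for (i in seq_along(sel)) {
      tip <- mv_tips[[c]][sel[i], ]
      s0 <- tip - os_overlap * u_dir
      s1 <- s0 + spec$os_length * u_dir
      idx <- .capsule_indices(s0, s1, spec$os_radius, sp_um, dims)
      record_overlap(grid[idx], os_labels[[c]][i])
      grid[idx] <- os_labels[[c]][i]
    }
  }

  # --- assemble volume ----------------------------------------------------
  rows <- lab_env$rows
  tab <- label_table(
    label = vapply(rows, `[[`, integer(1), "label"),
    cell = vapply(rows, `[[`, character(1), "cell"),
    compartment = vapply(rows, `[[`, character(1), "compartment"))
  vol <- label_volume(grid, sp, tab)

  # --- ground truth -------------------------------------------------------
  mv_full <- capsule_volume_um3(mvL, spec$microvilli_radius)
  mv_full_ext <- capsule_volume_um3(mvL + os_allow, spec$microvilli_radius)
  mv_carve <- pi * spec$microvilli_radius^2 * os_overlap +
    2 / 3 * pi * spec$microvilli_radius^3 +
    .collinear_lens_volume(spec$microvilli_radius, spec$os_radius)
  root_cap <- 2 / 3 * pi * spec$microvilli_radius^3
  cells_truth <- lapply(seq_len(n_cells), function(c) {
    nuc_vols <- vapply(nuclei[[c]], function(nu) {
      ellipsoid_volume_um3(nu$semiaxes)
    }, numeric(1))
    pocket_vol <- sum(vapply(pockets[[c]], function(p) {
      4 / 3 * pi * p$radius^3
    }, numeric(1)))
    mito_vols <- vapply(mitos[[c]], function(m) {
      ellipsoid_volume_um3(m$semiaxes)
    }, numeric(1))
    n_rods <- if (is.null(mv_roots[[c]])) 0L else nrow(mv_roots[[c]])
    n_os <- length(os_rods[[c]])
    mv_vol <- n_os * (mv_full_ext - mv_carve) + (n_rods - n_os) * mv_full
    tibble::tibble(
      cell_id = cell_id_of(c),
      n_nuclei = spec$nuclei_per_cell[c],
      cytoplasm_volume_um3 = W * W * H - pocket_vol - n_rods * root_cap,
      nucleus_volumes_um3 = list(nuc_vols),
      nucleus_total_um3 = sum(nuc_vols),
      infold_volume_um3 = pocket_vol,
      mito_count = length(mito_vols),
      mito_total_um3 = sum(mito_vols),
      microvilli_volume_um3 = mv_vol,
      microvilli_total_length_um = n_rods * mvL,
      microvilli_tilt_deg = spec$microvilli_tilt,
      os_count = n_os,
      body_height_um = H)
  })
  mito_truth <- dplyr::bind_rows(lapply(seq_len(n_cells), function(c) {
    if (length(mitos[[c]]) == 0L) return(NULL)
    tibble::tibble(
      cell_id = cell_id_of(c),
      index = seq_along(mitos[[c]]),
      volume_um3 = vapply(mitos[[c]], function(m) {
        ellipsoid_volume_um3(m$semiaxes)
      }, numeric(1)),
      volume_nm3 = vapply(mitos[[c]], function(m) {
        ellipsoid_volume_um3(m$semiaxes)
      }, numeric(1)) * NM3_PER_UM3,
      basal = vapply(mitos[[c]], `[[`, logical(1), "basal"))
  }))
  os_truth <- if (length(os_table) > 0) {
    tibble::tibble(
      label = vapply(os_table, `[[`, integer(1), "label"),
      owner_cell = vapply(os_table, `[[`, character(1), "owner"),
      volume_um3 = capsule_volume_um3(spec$os_length, spec$os_radius))
  } else tibble::tibble(label = integer(), owner_cell = character(),
                        volume_um3 = numeric())
  # adjacent-pair analytic interface areas (planar faces)
  iface <- list()
  for (c in seq_len(n_cells)) {
    ix <- (c - 1L) %% spec$n_cells_x; iz <- (c - 1L) %/% spec$n_cells_x
    if (ix + 1L < spec$n_cells_x) {
      iface[[length(iface) + 1L]] <- tibble::tibble(
        cell_a = cell_id_of(c), cell_b = cell_id_of(c + 1L),
        orientation = "x",
        area_um2 = W * H / cos(spec$shear_angle * pi / 180))
    }
    if (iz + 1L < spec$n_cells_z) {
      iface[[length(iface) + 1L]] <- tibble::tibble(
        cell_a = cell_id_of(c),
        cell_b = cell_id_of(c + spec$n_cells_x),
        orientation = "z", area_um2 = W * H)
    }
  }
  truth <- structure(list(
    spec = spec,
    cells = dplyr::bind_rows(cells_truth),
    mitochondria = mito_truth,
    os = os_truth,
    brm = list(mean_nm = spec$brm_mean_thickness,
               sd_nm = spec$brm_thickness_sd,
               thickness_nm = as.vector(t_nm),
               thickness_rasterised_nm = as.vector(t_vox) * sp$dy),
    interfaces = dplyr::bind_rows(iface),
    overlaps = if (length(overlap_rows) > 0) {
      dplyr::bind_rows(overlap_rows)
    } else tibble::tibble(label = integer(), prior_label = integer(),
                          n_vox = integer()),
    layout = list(y_apical_um = y_ap, y_base_um = y_base,
                  dims = dims)
  ), class = "phantom_truth")
  list(volume = vol, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d cells, %d mitochondria, %d OS\n",
              nrow(x$cells), nrow(x$mitochondria), nrow(x$os)))
  invisible(x)
}
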