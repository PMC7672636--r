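# fixtures built in code: analytic micro-scenes and small phantom specs

sp50 <- function() voxel_spacing(50, 50, 50)
sp_aniso <- function() voxel_spacing(8, 8, 50)

make_vol <- function(grid, table, spacing = sp50()) {
  storage.mode(grid) <- "integer"
  label_volume(grid, spacing, table)
}

# two 20(x) x 20(y) x 10(z)-voxel cuboids abutting on a flat x-face at
# 8 x 8 x 50 nm: corrected slice-wise area = 10 * 20 * 0.008 * 0.05
two_cuboid_volume <- function(gap = 0L) {
  g <- array(0L, c(24, 46, 10))
  g[3:22, 3:22, ] <- 1L
  g[3:22, (23 + gap):(42 + gap), ] <- 2L
  make_vol(g, label_table(label = 1:2, cell = c("cell_a", "cell_b"),
                          compartment = rep("cell_body", 2)),
           spacing = sp_aniso())
}

# n cuboid cells in a row along x, each 10 x 20 x 8 voxels
row_of_cells <- function(n = 3) {
  g <- array(0L, c(24, 10 * n + 4, 8))
  for (i in seq_len(n)) g[3:22, (3 + (i - 1) * 10):(2 + i * 10), ] <- i
  make_vol(g, label_table(label = seq_len(n),
                          cell = sprintf("cell_%d", seq_len(n)),
                          compartment = rep("cell_body", n)))
}

# 2 x 2 grid of cuboid cells tiled in x and z
grid_cells_2x2 <- function() {
  g <- array(0L, c(20, 28, 24))
  lab <- 0L
  for (iz in 0:1) for (ix in 0:1) {
    lab <- lab + 1L
    g[3:18, (3 + ix * 12):(14 + ix * 12), (1 + iz * 12):(12 + iz * 12)] <- lab
  }
  make_vol(g, label_table(label = 1:4,
                          cell = sprintf("cell_%d", 1:4),
                          compartment = rep("cell_body", 4)))
}

# centre cuboid surrounded by six face-adjacent neighbours
cross_of_cells <- function() {
  g <- array(0L, c(18, 18, 18))
  b <- function(i) (7:12) + i * 6
  g[b(0), b(0), b(0)] <- 1L
  g[b(-1), b(0), b(0)] <- 2L; g[b(1), b(0), b(0)] <- 3L
  g[b(0), b(-1), b(0)] <- 4L; g[b(0), b(1), b(0)] <- 5L
  g[b(0), b(0), b(-1)] <- 6L; g[b(0), b(0), b(1)] <- 7L
  make_vol(g, label_table(label = 1:7,
                          cell = sprintf("cell_%d", 1:7),
                          compartment = rep("cell_body", 7)))
}

# small, fast phantom spec; override any field
tiny_spec <- function(...) {
  defaults <- list(
    n_cells_x = 2L, n_cells_z = 1L, cell_width = 4, cell_body_height = 3,
    shear_angle = 10, nuclei_per_cell = c(1L, 2L),
    nucleus_semiaxes = c(0.7, 0.5, 0.7),
    microvilli_length = 2, microvilli_radius = 0.1, rods_per_cell = 9L,
    os_per_cell = 9L, os_radius = 0.15, os_length = 1,
    brm_mean_thickness = 500, brm_thickness_sd = 0,
    infold_pockets_per_cell = 2L, pocket_radius = 0.3,
    mito_per_cell = 8L, mito_semiaxes = c(0.25, 0.2, 0.2),
    seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(phantom_spec, args)
}

# a volume holding one labelled rod over a thin cell-body slab, for
# angle/length recovery tests. Returns the volume; the rod roots at the
# slab's apical surface.
rod_test_volume <- function(tilt_deg, length_um = 5.5, radius = 0.1,
                            spacing = sp50()) {
  th <- tilt_deg * pi / 180
  dxu <- spacing$dx / 1e3; dyu <- spacing$dy / 1e3; dzu <- spacing$dz / 1e3
  rise <- length_um * sin(th) + radius + 0.2
  run_x <- abs(length_um * cos(th)) + radius + 0.3
  y_ap <- ceiling(rise / dyu) * dyu
  ny <- as.integer(round((y_ap + 1) / dyu))
  nx <- as.integer(ceiling((2 * run_x + 1) / dxu))
  nz <- as.integer(ceiling(1 / dzu))
  root <- c(if (cos(th) < 0) nx * dxu - 0.4 else 0.4, y_ap, nz * dzu / 2)
  tip <- root + length_um * c(cos(th), -sin(th), 0)
  g <- array(0L, c(ny, nx, nz))
  body_rows <- (as.integer(round(y_ap / dyu)) + 1L):ny
  g[body_rows, , ] <- 1L
  rod <- rasterise_rod(root, tip, radius, spacing, dim = c(ny, nx, nz))
  g[rod] <- 2L
  make_vol(g, label_table(label = 1:2, cell = c("c1", "c1"),
                          compartment = c("cell_body", "microvilli")),
           spacing = spacing)
}
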