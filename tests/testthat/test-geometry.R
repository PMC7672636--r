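# microvillus length/angle, cell heights, membrane thickness, sampling

scheme_all <- function(per = 10, seed = 1) sampling_scheme(1, per, seed)

test_that("a vertical rod reads 90 degrees", {
  v <- rod_test_volume(90, length_um = 3)
  mg <- microvillus_geometry(v, "c1", scheme_all())
  expect_equal(mg$angle$mean, 90, tolerance = 0.02)
  expect_equal(mg$length$mean, 3, tolerance = 0.05 * 3)
})

test_that("chord angle recovers analytic tilts within 2 degrees", {
  for (tilt in c(100, 120, 143, 160)) {
    v <- rod_test_volume(tilt)
    mg <- microvillus_geometry(v, "c1", scheme_all())
    expect_lt(abs(mg$angle$mean - tilt), 2)
    expect_lt(abs(mg$length$mean - 5.5) / 5.5, 0.05)
  }
})

test_that("a rod parallel to the apical plane reads a limiting angle", {
  # rod lying flat on the apical surface, pointing +x
  sp <- sp50()
  g <- array(0L, c(30, 80, 10))
  g[21:30, , ] <- 1L
  rod <- rasterise_rod(c(0.5, 0.95, 0.25), c(3.5, 0.95, 0.25), 0.1, sp,
                       dim = c(30, 80, 10))
  g[rod] <- 2L
  v <- make_vol(g, label_table(1:2, c("c1", "c1"),
                               c("cell_body", "microvilli")))
  mg <- microvillus_geometry(v, "c1", scheme_all())
  expect_lt(min(mg$angle$mean, 180 - mg$angle$mean), 8)
})

test_that("sampling is deterministic in the scheme seed", {
  ph <- generate_phantom(tiny_spec(brm_thickness_sd = 150))
  s1 <- microvillus_geometry(ph$volume, "cell_1", sampling_scheme(5, 1, 11))
  s2 <- microvillus_geometry(ph$volume, "cell_1", sampling_scheme(5, 1, 11))
  expect_identical(s1$length$samples, s2$length$samples)
  expect_identical(s1$details, s2$details)
  # a different seed draws different columns from the varying-thickness slab
  b1 <- brm_thickness(ph$volume, sampling_scheme(5, 5, 11))
  b2 <- brm_thickness(ph$volume, sampling_scheme(5, 5, 11))
  b3 <- brm_thickness(ph$volume, sampling_scheme(5, 5, 12))
  expect_identical(b1$samples, b2$samples)
  expect_false(identical(b1$samples, b3$samples))
})

test_that("missing microvilli raise a clear error", {
  ph <- generate_phantom(tiny_spec(rods_per_cell = 0L, os_per_cell = 0L))
  expect_error(microvillus_geometry(ph$volume, "cell_1", scheme_all()),
               "no microvilli")
})

test_that("body height is exact on a cuboid cell of whole-voxel height", {
  # 7.0 um = 140 rows at 50 nm
  ph <- generate_phantom(tiny_spec(
    n_cells_x = 1L, cell_width = 5, cell_body_height = 7, shear_angle = 0,
    nuclei_per_cell = 1L, rods_per_cell = 0L, os_per_cell = 0L,
    mito_per_cell = 0L, infold_pockets_per_cell = 0L,
    nucleus_semiaxes = c(1, 0.8, 1)))
  ht <- rpe_height(ph$volume, "cell_1", sampling_scheme(5, 10, 1))
  expect_equal(ht$body_height$mean, 7)
  expect_equal(ht$body_height$sd, 0)
})

test_that("shear leaves the through-column height unchanged", {
  ph <- generate_phantom(tiny_spec(
    n_cells_x = 1L, cell_width = 5, cell_body_height = 3, shear_angle = 25,
    nuclei_per_cell = 1L, rods_per_cell = 0L, os_per_cell = 0L,
    mito_per_cell = 0L, infold_pockets_per_cell = 0L))
  ht <- rpe_height(ph$volume, "cell_1", sampling_scheme(5, 10, 1))
  # within one voxel of the true height
  expect_lt(abs(ht$body_height$mean - 3), 0.05)
})

test_that("combined height is the exact sum of its parts", {
  ph <- generate_phantom(tiny_spec())
  ht <- rpe_height(ph$volume, "cell_1", sampling_scheme(5, 5, 1),
                   microvilli_length = 5.5)
  expect_equal(ht$combined_height_um, ht$body_height$mean + 5.5)
})

test_that("membrane thickness is exact on a constant slab", {
  # 500 nm = 10 rows at dy = 50 nm
  ph <- generate_phantom(tiny_spec(brm_mean_thickness = 500,
                                   brm_thickness_sd = 0))
  bt <- brm_thickness(ph$volume, sampling_scheme(5, 10, 1))
  expect_equal(bt$mean, 500)
  expect_equal(bt$sd, 0)
})

test_that("Gaussian slab thickness is recovered within 5%", {
  ph <- generate_phantom(tiny_spec(
    cell_width = 6, brm_mean_thickness = 524.4, brm_thickness_sd = 200.5,
    rods_per_cell = 0L, os_per_cell = 0L, mito_per_cell = 0L,
    infold_pockets_per_cell = 0L, seed = 3L))
  bt <- brm_thickness(ph$volume, sampling_scheme(1, 10, 2))
  expect_gt(bt$n, 100)
  expect_lt(abs(bt$mean - 524.4) / 524.4, 0.05)
})

test_that("sample count follows the slice-interval arithmetic", {
  ph <- generate_phantom(tiny_spec(brm_thickness_sd = 0))
  nz <- dim(ph$volume$grid)[3]
  interval <- 20L
  bt <- brm_thickness(ph$volume, sampling_scheme(interval, 10, 1))
  expect_equal(bt$n, length(seq(interval, nz, interval)) * 10)
})

test_that("an interval larger than the stack is rejected", {
  ph <- generate_phantom(tiny_spec())
  expect_error(brm_thickness(ph$volume, sampling_scheme(10000, 10, 1)),
               "no slices sampled")
})

test_that("measurement sets summarise and format like published values", {
  lm <- linear_measurement_set("microvillus_length", c(5, 5.5, 6), "um")
  expect_equal(lm$mean, 5.5)
  expect_equal(lm$n, 3L)
  expect_match(format(lm), "5.5 um ± 0.5 SD")
  expect_equal(nrow(tidy(lm)), 3L)
  expect_equal(glance(lm)$sd, 0.5)
  single <- linear_measurement_set("x", 4.2, "nm")
  expect_equal(single$sd, 0)
  expect_false(single$sd_defined)
})
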