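# volumes, surface areas, cell summaries, photoreceptor support,
# mitochondria statistics

test_that("mask volume is voxel count times voxel volume", {
  m <- array(FALSE, c(20, 10, 10))
  expect_equal(compartment_volume(m, sp_aniso()), 0)
  m[seq_len(1000)] <- TRUE
  # 1000 voxels at 8 x 8 x 50 nm = 3.2e-3 um^3
  expect_equal(compartment_volume(m, sp_aniso()), 3.2e-3, tolerance = 1e-12)
})

test_that("voxel-face surface area matches closed forms", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  # single voxel at 8 x 8 x 50 nm: 2*(8*8) + 4*(8*50) = 1728 nm^2
  expect_equal(as.numeric(surface_area_voxel(m, sp_aniso())), 1728 / 1e6,
               tolerance = 1e-12)
  expect_equal(as.numeric(surface_area_voxel(array(FALSE, c(4, 4, 4)),
                                             sp50())), 0)
  # solid cuboid a x b x c voxels: 2(ab dxdy + ac dxdz + bc dydz)
  m2 <- array(FALSE, c(12, 14, 9)); m2[2:7, 3:9, 2:5] <- TRUE
  a <- 7; b <- 6; c <- 4  # x, y, z voxel extents
  s <- sp_aniso()
  analytic <- 2 * (a * b * s$dx * s$dy + a * c * s$dx * s$dz +
                     b * c * s$dy * s$dz) / 1e6
  expect_equal(as.numeric(surface_area_voxel(m2, s)), analytic,
               tolerance = 1e-12)
})

test_that("surface area is invariant under in-plane rotation when dx == dy", {
  set.seed(5)
  m <- array(stats::runif(14 * 14 * 6) < 0.3, c(14, 14, 6))
  rot <- aperm(m, c(2, 1, 3))[, dim(m)[1]:1, , drop = FALSE]  # 90 deg
  expect_equal(as.numeric(surface_area_voxel(m, sp50())),
               as.numeric(surface_area_voxel(rot, sp50())))
})

test_that("volume is additive over disjoint masks", {
  set.seed(9)
  a <- array(stats::runif(10 * 10 * 4) < 0.3, c(10, 10, 4))
  b <- array(stats::runif(10 * 10 * 4) < 0.3, c(10, 10, 4)) & !a
  expect_equal(compartment_volume(a | b, sp50()),
               compartment_volume(a, sp50()) +
                 compartment_volume(b, sp50()))
})

test_that("compartment volumes account for every foreground voxel exactly", {
  ph <- generate_phantom(tiny_spec())
  v <- ph$volume
  m <- morphometry_table(v)
  vv <- v$spacing$dx * v$spacing$dy * v$spacing$dz / 1e9
  expect_equal(sum(m$volume_um3), sum(v$grid > 0L) * vv, tolerance = 1e-12)
})

test_that("nucleus-excluded arithmetic reproduces published whole-cell values", {
  mono <- summarise_cell_volumes(2220.2, 141, 90)
  expect_equal(mono$nucleus_excluded_volume_um3, 2079.2)
  bi_1 <- summarise_cell_volumes(2360, c(146.8, 144), 132)
  bi_2 <- summarise_cell_volumes(2649, c(123.6, 131.6), 108)
  expect_equal(mean(c(bi_1$nucleus_excluded_volume_um3,
                      bi_2$nucleus_excluded_volume_um3)), 2231.5)
})

test_that("photoreceptor densities round to 2 significant figures", {
  expect_equal(summarise_cell_volumes(2220.2, 141, 90)$
                 photoreceptor_density_2sf, 0.041)
  expect_equal(summarise_cell_volumes(1803, 138.1, 216)$
                 photoreceptor_density_2sf, 0.12)
  expect_equal(summarise_cell_volumes(1733, c(126.5, 128.2), 102)$
                 photoreceptor_density_2sf, 0.059)
  # full precision is retained alongside the rounded figure
  expect_equal(summarise_cell_volumes(2220.2, 141, 90)$
                 photoreceptor_density_per_um3, 90 / 2220.2)
})

test_that("an OS counts as supported only through microvilli face contact", {
  g <- array(0L, c(12, 16, 4))
  g[9:11, 2:14, ] <- 1L          # body
  g[5:8, 3:4, ] <- 2L            # microvilli tuft
  g[3:4, 3:4, ] <- 10L           # OS touching the tuft (y-faces)
  g[3:6, 9:10, ] <- 11L          # OS separated by background
  tab <- label_table(c(1L, 2L, 10L, 11L),
                     c("c1", "c1", "os_1", "os_2"),
                     c("cell_body", "microvilli", rep("outer_segment", 2)))
  v <- make_vol(g, tab)
  supp <- count_supported_photoreceptors(v, "c1")
  expect_equal(supp$count, 1L)
  expect_equal(supp$os_labels, 10L)
  expect_equal(supp$n_shared, 0L)
})

test_that("an OS straddling two cells' microvilli is counted for both, flagged", {
  g <- array(0L, c(12, 20, 4))
  g[9:11, 2:9, ] <- 1L;  g[5:8, 4:5, ] <- 2L    # cell A body + microvilli
  g[9:11, 10:18, ] <- 3L; g[5:8, 8:9, ] <- 4L   # cell B body + microvilli
  g[3:4, 4:9, ] <- 10L                          # OS spanning both tufts
  tab <- label_table(c(1:4, 10L),
                     c("cA", "cA", "cB", "cB", "os_1"),
                     c("cell_body", "microvilli", "cell_body",
                       "microvilli", "outer_segment"))
  v <- make_vol(g, tab)
  tabres <- os_support_table(v)
  expect_equal(nrow(tabres), 2L)
  expect_true(all(tabres$shared))
  expect_equal(count_supported_photoreceptors(v, "cA", tabres)$count, 1L)
  expect_equal(count_supported_photoreceptors(v, "cB", tabres)$count, 1L)
})

test_that("missing OS labels yield a zero count with a warning", {
  g <- array(0L, c(8, 8, 2)); g[5:7, 2:6, ] <- 1L; g[2:4, 2:6, ] <- 2L
  v <- make_vol(g, label_table(1:2, c("c1", "c1"),
                               c("cell_body", "microvilli")))
  expect_warning(res <- os_support_table(v), "no outer_segment")
  expect_equal(nrow(res), 0L)
})

test_that("microvilli-OS contact area equals face count times face area", {
  g <- array(0L, c(10, 10, 3))
  g[6:8, 2:8, ] <- 1L
  g[4:5, 3:6, ] <- 2L      # microvilli
  g[2:3, 3:6, ] <- 10L     # OS: 4 x 3 y-facing faces
  tab <- label_table(c(1L, 2L, 10L), c("c1", "c1", "os_1"),
                     c("cell_body", "microvilli", "outer_segment"))
  v <- make_vol(g, tab)
  expect_equal(microvilli_contact_area(v, "c1"),
               4 * 3 * (0.05 * 0.05), tolerance = 1e-12)
  # additivity over a second OS with x-facing contact
  g[4:5, 7, ] <- 11L
  tab2 <- label_table(c(1L, 2L, 10L, 11L), c("c1", "c1", "os_1", "os_2"),
                      c("cell_body", "microvilli", rep("outer_segment", 2)))
  v2 <- make_vol(g, tab2)
  expect_equal(microvilli_contact_area(v2, "c1"),
               (4 * 3 + 2 * 3) * (0.05 * 0.05), tolerance = 1e-12)
})

test_that("connected-component counting honours the connectivity choice", {
  g <- array(0L, c(10, 10, 4))
  g[7:9, 2:8, ] <- 1L
  # L-shaped blob: one 26-connected component
  g[2, 2:5, 2] <- 2L; g[3:4, 5, 2] <- 2L
  # second blob touching the first only at a corner
  g[5, 6, 3] <- 2L
  tab <- label_table(1:2, c("c1", "c1"),
                     c("cell_body", "mitochondrion"))
  v <- make_vol(g, tab)
  expect_equal(mitochondria_stats(v, "c1", connectivity = 26)$count, 1L)
  expect_equal(mitochondria_stats(v, "c1", connectivity = 6)$count, 2L)
})

test_that("mitochondria statistics are internally consistent", {
  ph <- generate_phantom(tiny_spec())
  ms <- mitochondria_stats(ph$volume, "cell_1")
  expect_equal(ms$count, sum(ph$truth$mitochondria$cell_id == "cell_1"))
  expect_equal(ms$mean_volume_nm3 * ms$count, ms$total_volume_nm3)
  expect_lte(ms$min_volume_nm3, ms$mean_volume_nm3)
  expect_equal(sum(ms$component_volumes_nm3), ms$total_volume_nm3)
  gl <- glance(ms)
  expect_equal(gl$count, ms$count)
  expect_equal(nrow(tidy(ms)), ms$count)
})

test_that("zero mitochondria give zeroed statistics", {
  ph <- generate_phantom(tiny_spec(mito_per_cell = 0L))
  ms <- mitochondria_stats(ph$volume, "cell_1")
  expect_equal(ms$count, 0L)
  expect_equal(ms$total_volume_nm3, 0)
})

test_that("basal fraction uses the cell's own y-extent", {
  g <- array(0L, c(32, 10, 4))
  g[2:31, 2:9, ] <- 1L                 # body spans rows 2..31 (30 rows)
  g[25:28, 4:6, 2:3] <- 2L             # blob wholly in the basal third
  v <- make_vol(g, label_table(1:2, c("c1", "c1"),
                               c("cell_body", "mitochondrion")))
  expect_equal(mitochondria_stats(v, "c1")$basal_fraction, 1)
  g[25:28, 4:6, 2:3] <- 1L
  g[4:7, 4:6, 2:3] <- 2L               # apical blob instead
  v2 <- make_vol(g, label_table(1:2, c("c1", "c1"),
                                c("cell_body", "mitochondrion")))
  expect_equal(mitochondria_stats(v2, "c1")$basal_fraction, 0)
})

test_that("mitochondrial volume fraction arithmetic and guards", {
  ms <- structure(list(total_volume_nm3 = 1.17e11),
                  class = "mitochondria_stats")
  expect_equal(mito_volume_fraction(ms, 2220.2), 100 * 117 / 2220.2,
               tolerance = 1e-9)
  expect_error(mito_volume_fraction(ms, 0), "positive")
})

test_that("cell_summary assembles the whole-cell table row", {
  ph <- generate_phantom(tiny_spec())
  v <- ph$volume
  cs <- cell_summary(v, "cell_2")
  expect_equal(cs$n_nuclei, 2L)
  expect_equal(cs$photoreceptors_supported, 9L)
  expect_equal(cs$nucleus_excluded_volume_um3,
               cs$cytoplasm_volume_um3 - sum(cs$nuclei_volumes_um3[[1]]))
  expect_equal(cs$photoreceptor_density_per_um3,
               cs$photoreceptors_supported / cs$cytoplasm_volume_um3)
  expect_gt(cs$microvilli_contact_area_um2, 0)
  expect_error(cell_summary(v, "cell_99"), "no labels")
})
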