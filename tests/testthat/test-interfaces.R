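# slice-wise shared-area estimator, voxel-face oracle, contact tables

test_that("flat two-cuboid interface: slice-wise equals the analytic area", {
  v <- two_cuboid_volume()
  im <- shared_area_slicewise(v, 1L, 2L, mode = "corrected")
  expect_equal(im$total_area_um2, 0.0800, tolerance = 1e-12)
  expect_equal(im$n_slices, 10L)
  expect_equal(sum(im$per_slice_areas), im$total_area_um2)  # exact identity
  expect_true(all(im$per_slice_areas >= 0))
})

test_that("fidelity mode reproduces the original loop bound (skips slice N)", {
  v <- two_cuboid_volume()
  fid <- shared_area_slicewise(v, 1L, 2L, mode = "fidelity")
  expect_equal(fid$n_slices, 9L)
  expect_equal(fid$total_area_um2, 0.0720, tolerance = 1e-12)
  corr <- shared_area_slicewise(v, 1L, 2L, mode = "corrected")
  # fidelity total = corrected total minus the final slice's contribution
  expect_equal(fid$total_area_um2,
               corr$total_area_um2 - corr$per_slice_areas[10])
})

test_that("voxel-face oracle agrees exactly on the flat x-facing interface", {
  v <- two_cuboid_volume()
  vf <- shared_area_voxel_faces(v, 1L, 2L)
  expect_equal(vf$total_area_um2, 0.0800, tolerance = 1e-12)
  expect_equal(vf$area_x_um2, vf$total_area_um2)   # purely x-facing
  expect_equal(vf$n_faces_x, 200L)
  corr <- shared_area_slicewise(v, 1L, 2L, "corrected")
  expect_equal(corr$total_area_um2, vf$area_x_um2)
})

test_that("a two-pixel gap yields zero shared area in every mode", {
  v <- two_cuboid_volume(gap = 2L)
  expect_equal(shared_area_slicewise(v, 1L, 2L, "corrected")$total_area_um2,
               0)
  expect_equal(shared_area_slicewise(v, 1L, 2L, "fidelity")$total_area_um2,
               0)
  expect_equal(shared_area_voxel_faces(v, 1L, 2L)$total_area_um2, 0)
})

test_that("diagonal-only adjacency carries no voxel faces", {
  g <- array(0L, c(6, 6, 2))
  g[2:3, 2:3, ] <- 1L
  g[4:5, 4:5, ] <- 2L   # touches label 1 only along an edge
  v <- make_vol(g, label_table(1:2, c("a", "b"), rep("cell_body", 2)))
  expect_equal(shared_area_voxel_faces(v, 1L, 2L)$total_area_um2, 0)
})

test_that("a fully enclosed voxel exposes exactly six faces", {
  g <- array(0L, c(5, 5, 5))
  g[2:4, 2:4, 2:4] <- 1L
  g[3, 3, 3] <- 2L
  v <- make_vol(g, label_table(1:2, c("a", "b"),
                               c("cell_body", "mitochondrion")),
                spacing = sp_aniso())
  vf <- shared_area_voxel_faces(v, 1L, 2L)
  s <- sp_aniso()
  expect_equal(vf$total_area_um2,
               (2 * s$dy * s$dz + 2 * s$dx * s$dz + 2 * s$dx * s$dy) / 1e6)
})

test_that("swapping the dilated object leaves flat interfaces unchanged", {
  v <- two_cuboid_volume()
  ab <- shared_area_slicewise(v, 1L, 2L, "corrected")$total_area_um2
  ba <- shared_area_slicewise(v, 2L, 1L, "corrected")$total_area_um2
  expect_equal(ab, ba)
})

test_that("growing object B never decreases the slice-wise area", {
  set.seed(31)
  for (rep in 1:8) {
    g <- array(0L, c(10, 14, 4))
    g[3:8, 3:7, ] <- 1L
    # random B blob to the right of A
    g[sample(3:8, 1) + 0:1, 8:10, sample(1:4, 2)] <- 2L
    v <- make_vol(g, label_table(1:2, c("a", "b"), rep("cell_body", 2)))
    base <- shared_area_slicewise(v, 1L, 2L, "corrected")$total_area_um2
    bg <- which(g == 0L)
    g2 <- g
    g2[sample(bg, 5)] <- 2L   # add voxels to B
    v2 <- make_vol(g2, label_table(1:2, c("a", "b"), rep("cell_body", 2)))
    grown <- shared_area_slicewise(v2, 1L, 2L, "corrected")$total_area_um2
    expect_gte(grown, base)
  }
})

test_that("single-slice stacks are rejected in fidelity mode only", {
  g <- array(0L, c(6, 8, 1))
  g[2:5, 2:4, 1] <- 1L; g[2:5, 5:7, 1] <- 2L
  v <- make_vol(g, label_table(1:2, c("a", "b"), rep("cell_body", 2)))
  expect_error(shared_area_slicewise(v, 1L, 2L, "fidelity"), "2 slices")
  expect_gt(shared_area_slicewise(v, 1L, 2L, "corrected")$total_area_um2, 0)
})

test_that("absent or equal labels are rejected", {
  v <- two_cuboid_volume()
  expect_error(shared_area_slicewise(v, 1L, 9L), "absent")
  expect_error(shared_area_slicewise(v, 1L, 1L), "differ")
  expect_error(shared_area_voxel_faces(v, 1L, 9L), "absent")
})

test_that("a row of three equal cells gives two identical pair entries", {
  v <- row_of_cells(3)
  cc <- cell_contact_areas(v)
  expect_equal(nrow(cc), 2L)
  expect_equal(cc$cell_a, c("cell_1", "cell_2"))
  expect_equal(cc$cell_b, c("cell_2", "cell_3"))
  # analytic flat face: 20 y-px * 8 z-px at 50 nm
  analytic <- 20 * 8 * (0.05 * 0.05)
  expect_equal(cc$total_area_um2, rep(analytic, 2), tolerance = 1e-12)
  expect_equal(cc$face_area_um2, rep(analytic, 2), tolerance = 1e-12)
  smry <- attr(cc, "summary")
  expect_equal(smry$mean, analytic)
  expect_equal(smry$sd, 0)
})

test_that("2x2 cell grid: four edge-sharing pairs, no diagonal pairs", {
  v <- grid_cells_2x2()
  cc <- cell_contact_areas(v)
  expect_equal(nrow(cc), 4L)
  pairs <- paste(cc$cell_a, cc$cell_b)
  expect_setequal(pairs, c("cell_1 cell_2", "cell_3 cell_4",
                           "cell_1 cell_3", "cell_2 cell_4"))
  expect_false("cell_1 cell_4" %in% pairs)   # diagonal
  expect_true(all(cc$face_area_um2 > 0))
  # x-facing pairs are measured by the slice-wise estimator;
  # z-facing pairs are invisible to its in-plane dilation
  xp <- cc$total_area_um2[pairs %in% c("cell_1 cell_2", "cell_3 cell_4")]
  zp <- cc$total_area_um2[pairs %in% c("cell_1 cell_3", "cell_2 cell_4")]
  expect_true(all(xp > 0))
  expect_true(all(zp == 0))
})

test_that("contact analysis requires at least two cells", {
  g <- array(0L, c(6, 6, 3)); g[2:5, 2:5, ] <- 1L
  v <- make_vol(g, label_table(1L, "only", "cell_body"))
  expect_error(cell_contact_areas(v), "at least 2 cells")
  expect_error(adjacency_graph(v), "at least 2 cells")
})

test_that("adjacency graph topology matches the scene", {
  path <- adjacency_graph(row_of_cells(3))
  expect_equal(igraph::vcount(path), 3L)
  expect_equal(igraph::ecount(path), 2L)
  expect_equal(unname(sort(igraph::degree(path))), c(1, 1, 2))

  cross <- adjacency_graph(cross_of_cells())
  expect_equal(igraph::degree(cross)[["cell_1"]], 6)

  # isolated cells: an edgeless graph
  g <- array(0L, c(8, 12, 3))
  g[2:4, 2:4, ] <- 1L; g[6:7, 8:10, ] <- 2L
  v <- make_vol(g, label_table(1:2, c("a", "b"), rep("cell_body", 2)))
  iso <- adjacency_graph(v)
  expect_equal(igraph::vcount(iso), 2L)
  expect_equal(igraph::ecount(iso), 0L)
})

test_that("interface measurements tidy, glance and export like the macro", {
  v <- two_cuboid_volume()
  im <- shared_area_slicewise(v, 1L, 2L, "corrected")
  td <- tidy(im)
  expect_equal(nrow(td), 10L)
  expect_equal(sum(td$area_um2), im$total_area_um2)
  gl <- glance(im)
  expect_equal(gl$total_area_um2, 0.08)
  expect_equal(gl$mode, "corrected")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_shared_area_csv(im, csv)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_named(back, c("Slice", "Pixel_Unit", "Surf.Area_stack",
                       "Surf.Area_slices"))
  expect_equal(back$Surf.Area_stack[1], 0.08)
  expect_equal(sum(back$Surf.Area_slices), 0.08)
})
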