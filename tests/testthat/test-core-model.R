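# data model and I/O: spacing, label tables, label volumes, TIFF round trip

test_that("voxel spacing validates and label tables enforce their contract", {
  expect_error(voxel_spacing(0, 8, 50), "> 0")
  expect_error(voxel_spacing(-1, 8, 50), "> 0")
  s <- voxel_spacing(8, 8, 50)
  expect_equal(s$dz, 50)
  expect_error(label_table(0L, "c", "cell_body"), "positive")
  expect_error(label_table(c(1L, 1L), c("a", "b"),
                           rep("cell_body", 2)), "unique")
  expect_error(label_table(1L, "a", "lysosome"), "unknown compartment")
})

test_that("label volumes reject unknown labels and non-integer data", {
  tab <- label_table(1L, "c1", "cell_body")
  g <- array(0L, c(4, 4, 3)); g[2, 2, 1] <- 7L
  expect_error(label_volume(g, sp50(), tab), "unknown label")
  g2 <- array(0.5, c(4, 4, 3))
  expect_error(label_volume(g2, sp50(), tab), "non-integer")
  # all-background volume with an empty table is fine
  v <- label_volume(array(0L, c(4, 4, 3)), sp50(), label_table())
  expect_equal(sum(v$grid), 0)
})

test_that("TIFF write/read round trip is the identity on grids and tables", {
  ph <- generate_phantom(tiny_spec(mito_per_cell = 0L,
                                   infold_pockets_per_cell = 0L))
  tif <- withr::local_tempfile(fileext = ".tif")
  js <- withr::local_tempfile(fileext = ".json")
  write_label_stack(ph$volume, tif, table_path = js)
  back <- read_label_stack(tif, table_path = js)   # spacing from JSON
  expect_identical(back$grid, ph$volume$grid)
  expect_equal(back$spacing, ph$volume$spacing)
  expect_equal(back$table$label, ph$volume$table$label)
  expect_equal(back$table$compartment, ph$volume$table$compartment)
})

test_that("16-bit labels survive the round trip; larger labels are refused", {
  g <- array(0L, c(3, 3, 2)); g[1, 1, 1] <- 65535L; g[3, 3, 2] <- 1L
  tab <- label_table(c(1L, 65535L), c("c1", "c2"),
                     c("cell_body", "cell_body"))
  v <- make_vol(g, tab)
  tif <- withr::local_tempfile(fileext = ".tif")
  js <- withr::local_tempfile(fileext = ".json")
  write_label_stack(v, tif, table_path = js)
  expect_identical(read_label_stack(tif, sp50(), js)$grid, g)
  g[1, 1, 1] <- 70000L
  tab2 <- label_table(c(1L, 70000L), c("c1", "c2"),
                      c("cell_body", "cell_body"))
  expect_error(write_label_stack(make_vol(g, tab2), tif), "65535")
})

test_that("a single-slice volume writes a single-page TIFF", {
  g <- array(1L, c(4, 5, 1))
  v <- make_vol(g, label_table(1L, "c1", "cell_body"))
  tif <- withr::local_tempfile(fileext = ".tif")
  js <- withr::local_tempfile(fileext = ".json")
  write_label_stack(v, tif, table_path = js)
  pages <- tiff::readTIFF(tif, all = TRUE, as.is = TRUE)
  expect_length(if (is.list(pages)) pages else list(pages), 1L)
  expect_identical(read_label_stack(tif, sp50(), js)$grid, g)
})

test_that("reading a stack with a label missing from the table errors", {
  g <- array(0L, c(4, 4, 2)); g[2, 2, ] <- 7L
  v <- make_vol(g, label_table(7L, "c1", "cell_body"))
  tif <- withr::local_tempfile(fileext = ".tif")
  js <- withr::local_tempfile(fileext = ".json")
  write_label_stack(v, tif, table_path = js)
  write_label_table(label_table(1L, "c1", "cell_body"), js,
                    spacing = sp50())
  expect_error(read_label_stack(tif, table_path = js), "unknown label")
})

test_that("compartment masks are unions over labels, empty with warning", {
  g <- array(0L, c(6, 6, 4))
  g[2:3, 2:3, 1:2] <- 2L          # nucleus A: 8 voxels
  g[4:5, 4:5, 3:4] <- 3L          # nucleus B: 8 voxels
  g[1, 1, ] <- 1L
  tab <- label_table(1:3, c("c1", "c1", "c1"),
                     c("cell_body", "nucleus", "nucleus"))
  v <- make_vol(g, tab)
  m <- compartment_mask(v, "c1", "nucleus")
  expect_equal(sum(m), 16)                       # union of both nuclei
  expect_true(all(v$grid[m] %in% c(2L, 3L)))
  expect_warning(m0 <- compartment_mask(v, "c1", "basal_infold_space"),
                 "empty mask")
  expect_equal(sum(m0), 0)
})

test_that("masks of all (cell, kind) pairs plus background partition the grid", {
  ph <- generate_phantom(tiny_spec())
  v <- ph$volume
  groups <- unique(v$table[, c("cell", "compartment")])
  total <- 0L
  for (i in seq_len(nrow(groups))) {
    total <- total + sum(compartment_mask(v, groups$cell[i],
                                          groups$compartment[i]))
  }
  expect_identical(total + sum(v$grid == 0L), length(v$grid))
})

test_that("label table JSON round-trips entries and spacing", {
  tab <- label_table(c(3L, 8L), c("c1", "os_1"),
                     c("nucleus", "outer_segment"))
  js <- withr::local_tempfile(fileext = ".json")
  write_label_table(tab, js, spacing = sp_aniso())
  back <- read_label_table(js)
  expect_equal(back$label, tab$label)
  expect_equal(back$cell, tab$cell)
  expect_equal(back$compartment, tab$compartment)
  expect_equal(attr(back, "spacing"), sp_aniso())
})
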