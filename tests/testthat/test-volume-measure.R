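# direct measurement of labeled voxel volumes

digitize_ball <- function(r, spacing = c(1, 1, 1), margin = 3) {
  half <- r + margin * max(spacing)
  nx <- 2 * ceiling(half / spacing[1]) + 1
  ny <- 2 * ceiling(half / spacing[2]) + 1
  nz <- 2 * ceiling(half / spacing[3]) + 1
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  cz <- (nz + 1) / 2
  g <- expand.grid(i = 1:nx, j = 1:ny, k = 1:nz)
  d2 <- ((g$i - cx) * spacing[1])^2 + ((g$j - cy) * spacing[2])^2 +
    ((g$k - cz) * spacing[3])^2
  labeled_volume(array(as.integer(d2 <= r^2), dim = c(nx, ny, nz)), spacing)
}

test_that("a digitized ball measures close to the analytic sphere", {
  vol <- digitize_ball(20)
  g <- measure_labels_3d(vol, f_R = TRUE)
  expect_equal(g$V, 4 / 3 * pi * 20^3, tolerance = 0.01)
  expect_equal(g$S, 4 * pi * 20^2, tolerance = 0.03)
  expect_equal(g$p3D, (36 * pi)^(1 / 3), tolerance = 0.05)
  expect_false(g$boundary_clipped)
  expect_gt(g$f_R, 0.85)
  expect_lte(g$f_R, 1)
})

test_that("doubling the resolution moves p3D toward the analytic value", {
  # refinement: the smoothing length must shrink relative to the object
  # while still spanning several voxels, hence sigma ~ sqrt(scale)
  e <- vapply(c(8, 16), function(r) {
    abs(measure_labels_3d(digitize_ball(r, margin = 5),
                          smooth_sigma = sqrt(r / 8))$p3D - (36 * pi)^(1 / 3))
  }, 0)
  expect_lt(e[2], e[1])
})

test_that("anisotropic sampling agrees with isotropic within tolerance", {
  iso <- measure_labels_3d(digitize_ball(12, c(1, 1, 1)))
  ani <- measure_labels_3d(digitize_ball(12, c(1, 1, 2)))
  expect_equal(ani$p3D, iso$p3D, tolerance = 0.05)
})

test_that("a whole-array label has exact volume and is boundary flagged", {
  vol <- labeled_volume(array(1L, c(6, 5, 4)), spacing = c(1, 1, 2))
  g <- measure_labels_3d(vol)
  expect_equal(g$V, 6 * 5 * 4 * 2)
  expect_true(g$boundary_clipped)
  expect_warning(
    measure_labels_3d(labeled_volume(array(c(1L, 2L, rep(1L, 342)),
                                           c(7, 7, 7))), min_voxels = 32),
    "skipped")
})

test_that("slicing a ball through the center yields a circle", {
  vol <- digitize_ball(20)
  mid <- (dim(vol$labels)[3] + 1) / 2
  ms <- slice_labels(vol, axis = 3, index = mid)
  expect_equal(nrow(ms), 1)
  expect_equal(ms$p2D, 2 * sqrt(pi), tolerance = 0.03)
  expect_equal(ms$a, pi * 20^2, tolerance = 0.02)
  expect_lt(ms$m, 0.05)
})

test_that("an axis-aligned cuboid slices to an exact rectangle", {
  labs <- array(0L, c(80, 50, 12))
  labs[11:70, 11:40, 4:9] <- 1L  # 60 x 30 x 6 voxels
  vol <- labeled_volume(labs, spacing = c(1, 1, 1))
  ms <- slice_labels(vol, axis = 3, index = 6, smooth_sigma = 0)
  expect_equal(ms$L, 2 * (60 + 30), tolerance = 0.01)
  expect_equal(ms$a, 1800, tolerance = 0.01)
  expect_equal(ms$m, (60^2 - 30^2) / (60^2 + 30^2), tolerance = 0.02)
})

test_that("voxel pathway cross-validates against exact polyhedral cells", {
  res <- generate_packing(64, 5.7, seed = 31)
  p <- res$packing
  vol <- voxelize_packing(p, voxels_per_unit = 24)
  meas <- measure_labels_3d(vol, min_voxels = 200)
  interior <- meas[!meas$boundary_clipped, ]
  expect_gt(nrow(interior), 0)
  exact <- measure_cells(periodic_voronoi(p))
  cmp <- merge(interior, exact, by.x = "label", by.y = "cell_id",
               suffixes = c("_vox", "_exact"))
  expect_lt(max(abs(cmp$p3D_vox / cmp$p3D_exact - 1)), 0.03)
  expect_lt(max(abs(cmp$V_vox / cmp$V_exact - 1)), 0.03)
})

test_that("labeled volumes round-trip through the text format", {
  vol <- digitize_ball(6)
  path <- file.path(tempdir(), "ball.csv")
  write_labeled_volume(vol, path)
  back <- read_labeled_volume(path)
  expect_identical(back$labels, vol$labels)
  expect_identical(back$spacing, vol$spacing)
})
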