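# Periodic Voronoi tessellation and 3D shape descriptors

test_that("lattice symmetries give exact cells", {
  # one center in the unit box: the cell is the unit cube
  cells <- periodic_voronoi(packing(matrix(0.5, 1, 3), box = 1))
  expect_length(cells, 1)
  g <- measure_cell(cells[[1]])
  expect_equal(g$V, 1, tolerance = 1e-12)
  expect_equal(g$S, 6, tolerance = 1e-12)
  expect_equal(g$p3D, 6, tolerance = 1e-12)

  # BCC: two congruent cells of volume 1/2 (truncated octahedra)
  cells <- periodic_voronoi(packing(rbind(c(0.25, 0.25, 0.25),
                                          c(0.75, 0.75, 0.75)), box = 1))
  expect_equal(cells[[1]]$V, 0.5, tolerance = 1e-10)
  expect_equal(cells[[2]]$V, 0.5, tolerance = 1e-10)
  expect_equal(cells[[1]]$S, cells[[2]]$S, tolerance = 1e-10)
})

test_that("cells tile the box and neighbor relations are symmetric", {
  set.seed(31)
  L <- 64^(1 / 3)
  p <- packing(matrix(runif(64 * 3) * L, ncol = 3), box = L)
  cells <- periodic_voronoi(p)
  expect_equal(sum(vapply(cells, `[[`, 0, "V")), 64, tolerance = 1e-8)

  # face-area multisets must match between each neighbor pair
  for (i in c(1, 17, 52)) {
    for (f in seq_along(cells[[i]]$faces)) {
      j <- cells[[i]]$neighbor_ids[f]
      back <- which(cells[[j]]$neighbor_ids == i)
      expect_true(length(back) >= 1)
      expect_true(min(abs(cells[[j]]$face_areas[back] -
                            cells[[i]]$face_areas[f])) < 1e-8)
    }
  }
})

test_that("tessellation matches an independent brute-force oracle", {
  set.seed(7)
  L <- 8^(1 / 3)
  cen <- matrix(runif(8 * 3) * L, ncol = 3)
  p <- packing(cen, box = L)
  cells <- periodic_voronoi(p)
  for (i in c(2, 5)) {
    oracle <- brute_voronoi_cell(p$centers, p$box, i)
    expect_equal(cells[[i]]$V, oracle$V, tolerance = 1e-7)
    expect_equal(cells[[i]]$S, oracle$S, tolerance = 1e-7)
  }
})

test_that("coincident centers raise a degenerate-geometry error", {
  cen <- rbind(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5) + 1e-12)
  expect_error(periodic_voronoi(packing(cen, box = 1)), "degenerate")
})

test_that("measure_cell reproduces closed-form polyhedron descriptors", {
  # regular tetrahedron: S = sqrt(3) a^2, V = a^3 / (6 sqrt(2))
  for (a in c(1, 2.7)) {
    tet <- regular_tetrahedron(a)
    g <- measure_cell(tet)
    expect_equal(g$S, sqrt(3) * a^2, tolerance = 1e-12)
    expect_equal(g$V, a^3 / (6 * sqrt(2)), tolerance = 1e-12)
    expect_equal(g$p3D, sqrt(3) * (6 * sqrt(2))^(2 / 3), tolerance = 1e-12)
  }

  # scale invariance of p3D for a cube
  cube <- periodic_voronoi(packing(matrix(1, 1, 3), box = 2))[[1]]
  expect_equal(measure_cell(cube)$p3D, 6, tolerance = 1e-12)

  # scaling a whole packing leaves every p3D unchanged
  set.seed(11)
  L <- 8^(1 / 3)
  cen <- matrix(runif(8 * 3) * L, ncol = 3)
  p1 <- measure_cells(periodic_voronoi(packing(cen, L)))
  p2 <- measure_cells(periodic_voronoi(packing(cen * 3.7, L * 3.7)))
  expect_equal(p1$p3D, p2$p3D, tolerance = 1e-9)
})

test_that("non-watertight input is rejected", {
  cube <- periodic_voronoi(packing(matrix(0.5, 1, 3), box = 1))[[1]]
  broken <- list(vertices = cube$vertices, faces = cube$faces[-1])
  expect_error(measure_cell(broken), "watertight")
})

test_that("isoperimetric bounds hold for every cell of a random packing", {
  set.seed(5)
  L <- 27^(1 / 3)
  ms <- measure_cells(periodic_voronoi(
    packing(matrix(runif(27 * 3) * L, ncol = 3), L)), f_R = TRUE)
  expect_true(all(ms$p3D >= (36 * pi)^(1 / 3) - 1e-9))
  expect_true(all(ms$f_R > 0 & ms$f_R <= 1))
})

test_that("inscribed-sphere fractions match closed forms and refine to 1", {
  cube <- periodic_voronoi(packing(matrix(0.5, 1, 3), box = 1))[[1]]
  expect_equal(inscribed_sphere_fraction(cube), pi / 6, tolerance = 1e-9)

  tet <- regular_tetrahedron(2)
  expect_equal(inscribed_sphere_fraction(tet), pi / (6 * sqrt(3)),
               tolerance = 1e-9)

  fr <- vapply(0:2, function(k) inscribed_sphere_fraction(icosphere(k)), 0)
  expect_true(all(diff(fr) > 0))
  expect_gt(fr[3], 0.97)
  expect_lt(fr[3], 1)
})
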