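# plane slicing and 2D shape descriptors

test_that("slicing the unit-cube cell gives the unit square", {
  p <- packing(matrix(0.5, 1, 3), box = 1)
  ms <- slice_packing(p, list(normal = c(0, 0, 1), offset = 0.5))
  expect_equal(nrow(ms), 1)
  expect_equal(ms$L, 4, tolerance = 1e-12)
  expect_equal(ms$a, 1, tolerance = 1e-12)
  expect_equal(ms$p2D, 4, tolerance = 1e-12)
  expect_equal(ms$m, 0, tolerance = 1e-12)
})

test_that("clip-mode cross-sections tile the box section exactly", {
  set.seed(13)
  L <- 48^(1 / 3)
  p <- packing(matrix(runif(48 * 3) * L, ncol = 3), L)
  for (k in 1:3) {
    pl <- random_plane(p)
    ms <- slice_packing(p, pl, boundary = "clip")
    oracle <- box_section_area(p$box, pl$normal, pl$offset)
    expect_equal(sum(ms$a), oracle, tolerance = 1e-8)
  }
  # plane missing the box: empty result
  ms0 <- slice_packing(p, list(normal = c(0, 0, 1), offset = 2 * L))
  expect_equal(nrow(ms0), 0)
})

test_that("cross-sections near a polyhedral edge have divergent shape index", {
  p <- packing(matrix(0.5, 1, 3), box = 1)
  nrm <- c(1, 1, 0) / sqrt(2)
  # the cube's edge x = y = 1 projects to offset sqrt(2); approach it
  p2d <- vapply(c(1e-2, 1e-3, 1e-4), function(eps) {
    slice_packing(p, list(normal = nrm, offset = sqrt(2) * (1 - eps)))$p2D[1]
  }, 0)
  expect_true(all(diff(p2d) > 0))
  expect_gt(p2d[3], 50)
})

test_that("2D shape index has the circle as infimum and is scale invariant", {
  expect_equal(shape_index_2d(2 * pi, pi), 2 * sqrt(pi), tolerance = 1e-12)
  expect_equal(shape_index_2d(10, 4), 5)
  expect_equal(shape_index_2d(10 * 7, 4 * 49), 5)
  expect_error(shape_index_2d(-1, 1), "positive")
  expect_error(shape_index_2d(1, 0), "positive")
  # regular n-gons decrease monotonically to the circle value
  ngon <- function(n) 2 * sqrt(n * tan(pi / n))
  p <- vapply(c(3, 4, 6, 12, 96, 3000), ngon, 0)
  expect_true(all(diff(p) < 0))
  expect_equal(p[6], 2 * sqrt(pi), tolerance = 1e-6)
})

test_that("anisotropy index matches closed forms and symmetries", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(anisotropy_index(sq), 0, tolerance = 1e-12)
  rect <- rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1))
  expect_equal(anisotropy_index(rect), (4 - 1) / (4 + 1), tolerance = 1e-12)
  hexa <- t(vapply(0:5, function(k) c(cos(k * pi / 3), sin(k * pi / 3)),
                   numeric(2)))
  expect_equal(anisotropy_index(hexa), 0, tolerance = 1e-12)
  expect_error(anisotropy_index(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")

  # invariance under rotation, translation, uniform scaling
  set.seed(2)
  th <- runif(1) * 2 * pi
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  poly <- rbind(c(0, 0), c(3, 0.2), c(2.5, 1.7), c(0.5, 2.1))
  m0 <- anisotropy_index(poly)
  expect_equal(anisotropy_index(sweep(poly %*% t(R) * 4.2, 2, c(5, -3), `+`)),
               m0, tolerance = 1e-10)
})

test_that("random planes are isotropic and cover the box support", {
  set.seed(14)
  pl1 <- random_plane(c(2, 2, 2))
  set.seed(14)
  pl2 <- random_plane(c(2, 2, 2))
  expect_identical(pl1, pl2)

  set.seed(15)
  draws <- replicate(8000, {
    pl <- random_plane(c(2, 2, 2))
    sup <- cellslice:::box_support(c(2, 2, 2), pl$normal)
    c(pl$normal[3], (pl$offset - sup[1]) / diff(sup))
  })
  # Archimedes: z-component of a uniform direction is uniform on [-1, 1]
  expect_gt(stats::ks.test(draws[1, ], "punif", -1, 1)$p.value, 0.01)
  # offsets uniform over the support, no gaps
  expect_gt(stats::ks.test(draws[2, ], "punif")$p.value, 0.01)
})

test_that("slice statistics do not depend on plane orientation", {
  p <- relaxed_packing()
  fixed <- do.call(rbind, lapply(1:60, function(k) {
    sup <- cellslice:::box_support(p$box, c(0, 0, 1))
    slice_packing(p, list(normal = c(0, 0, 1),
                          offset = runif(1, sup[1], sup[2])))
  }))
  set.seed(88)
  rand <- do.call(rbind, lapply(1:60, function(k) slice_packing(p, random_plane(p))))
  set.seed(99)
  x <- sample(fixed$p2D, 300)
  y <- sample(rand$p2D, 300)
  expect_gt(suppressWarnings(stats::ks.test(x, y)$p.value), 0.01)
})

test_that("cut probability is proportional to cell extent along the normal", {
  # unrelaxed random centers give a broad spread of cell extents
  set.seed(321)
  L <- 32^(1 / 3)
  p <- packing(matrix(runif(96) * L, ncol = 3), L)
  nrm <- c(0, 0, 1)
  cells <- periodic_voronoi(p)
  extent <- vapply(cells, function(cl) diff(range(cl$vertices %*% nrm)), 0)
  sup <- cellslice:::box_support(p$box, nrm)
  set.seed(123)
  counts <- integer(length(cells))
  for (r in 1:600) {
    ms <- slice_packing(p, list(normal = nrm, offset = runif(1, sup[1], sup[2])))
    tb <- table(ms$cell_id)
    counts[as.integer(names(tb))] <- counts[as.integer(names(tb))] + as.integer(tb)
  }
  expect_gt(cor(counts, extent), 0.9)
})
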