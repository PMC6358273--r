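# reference-library construction, summaries, persistence

test_that("library builds are deterministic and meet the sample contract", {
  fp <- fire_params(max_steps = 1200)
  a <- build_library(5.8, cells_per_point = 120, seed = 71, n_cells = 24,
                     slices_per_packing = 20, fp = fp)
  b <- build_library(5.8, cells_per_point = 120, seed = 71, n_cells = 24,
                     slices_per_packing = 20, fp = fp)
  expect_identical(a$distributions[[1]]$samples, b$distributions[[1]]$samples)
  expect_gte(a$distributions[[1]]$n, 120)
  expect_error(build_library(5.0, 200, seed = 1), "validity")
  expect_error(build_library(5.8, 50, seed = 1), "at least 100")
})

test_that("KDE summaries match Gaussian closed forms and are equivariant", {
  set.seed(42)
  x <- rnorm(1e5)
  s <- summarize_distribution(x)
  # the mode of a flat-topped density is intrinsically noisy; 0.1 ~ 3 KDE
  # bandwidths
  expect_lt(abs(s$peak), 0.1)
  expect_equal(s$hwhm, sqrt(2 * log(2)), tolerance = 0.03)
  s2 <- summarize_distribution(x + 3.5)
  expect_equal(s2$peak - s$peak, 3.5, tolerance = 0.01)
  expect_equal(s2$hwhm, s$hwhm, tolerance = 1e-6)
  expect_error(summarize_distribution(rnorm(20)), "at least 50")
  # competing modes are flagged
  expect_warning(summarize_distribution(c(rnorm(5000), rnorm(5000, 8))),
                 "multimodal")
})

test_that("libraries round-trip exactly through disk", {
  lib <- mini_library()
  path <- file.path(tempdir(), "libtest")
  save_library(lib, path)
  back <- load_library(path)
  expect_identical(back$grid, lib$grid)
  for (i in seq_along(lib$grid)) {
    expect_identical(back$distributions[[i]]$samples,
                     lib$distributions[[i]]$samples)
  }

  # truncated member file: format error, no partial library
  bad <- file.path(tempdir(), "libtrunc")
  save_library(lib, bad)
  f <- file.path(bad, "samples_02.csv")
  writeLines(head(readLines(f), 50), f)
  expect_error(load_library(bad), "truncated")

  # unknown descriptor tag is named in the error
  bad2 <- file.path(tempdir(), "libtag")
  save_library(lib, bad2)
  mf <- file.path(bad2, "manifest.json")
  txt <- sub('"p2D"', '"q9X"', readLines(mf))
  writeLines(txt, mf)
  expect_error(load_library(bad2), "q9X")

  expect_error(load_library(file.path(tempdir(), "no-such-dir")), "missing")
})

test_that("f_R binning: a cube lattice occupies exactly one bin", {
  # 8 centers on a perfect cubic lattice: every Voronoi cell is a unit cube
  g <- as.matrix(expand.grid(c(0.5, 1.5), c(0.5, 1.5), c(0.5, 1.5)))
  p <- packing(g, box = 2)
  edges <- seq(0.15, 0.65, by = 0.1)
  expect_warning(lib <- build_fr_library(list(p), edges, seed = 5,
                                         slices_per_packing = 15),
                 "empty")
  expect_equal(length(lib$grid), 1)
  # pi/6 = 0.5236 falls in the (0.45, 0.55] bin, center 0.5
  expect_equal(lib$grid, 0.5)

  # one wide bin reproduces the unbinned slice distribution
  wide <- build_fr_library(list(p), c(0.01, 0.99), seed = 5,
                           slices_per_packing = 15)
  direct <- cellslice:::slice_measurements(p, 15, cellslice:::subseed(5, 1))
  expect_equal(sort(wide$distributions[[1]]$samples), sort(direct$p2D))
})

test_that("higher inscribed-sphere fraction shifts cross-sections to lower p2D", {
  packs <- list(generate_packing(32, 5.5, seed = 81)$packing,
                generate_packing(32, 6.3, seed = 82)$packing)
  lib <- suppressWarnings(build_fr_library(packs, seq(0.1, 0.7, by = 0.15),
                                           seed = 9, slices_per_packing = 30))
  expect_gte(length(lib$grid), 2)
  med <- vapply(lib$distributions, function(d) stats::median(d$samples), 0)
  # compact cells (high f_R) produce more circular sections
  expect_lt(med[length(med)], med[1])
})
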