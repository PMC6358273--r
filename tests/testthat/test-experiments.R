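# scripted study drivers (full-scale quantitative checks live in the
# acceptance suite; these exercise the machinery at small scale)

test_that("sample-size study returns sane error curves", {
  lib <- mini_library()
  ec <- sample_size_study(lib, 5.9, N_values = c(25, 100), reps = 60, seed = 2)
  expect_s3_class(ec, "error_curve")
  expect_true(all(ec$sigma_frac >= 0))
  expect_lte(ec$sigma_frac[2], ec$sigma_frac[1] + 0.005)
  expect_lt(abs(ec$delta_frac[2]), 0.02)
  est <- attr(ec, "estimates")
  expect_equal(dim(est), c(60, 2))
  expect_true(all(est %in% lib$grid))
  expect_error(sample_size_study(lib, 5.9, 10, reps = 5), "at least 30")
})

test_that("zero-magnitude error models reproduce the clean study", {
  lib <- mini_library()
  clean <- sample_size_study(lib, 5.9, 100, reps = 100, seed = 3)
  zero <- error_propagation_study(lib, "a_m", 0, 100, true_p3d = 5.9,
                                  reps = 100, seed = 3)
  expect_lt(abs(zero$sigma_frac - clean$sigma_frac), 0.005)
  expect_lt(abs(zero$delta_frac - clean$delta_frac), 0.005)
})

test_that("error propagation responds to large perimeter mis-measurement", {
  lib <- mini_library()
  tab <- error_propagation_study(lib, "delta_L", c(0, 0.15), N_values = 100,
                                 true_p3d = 5.9, reps = 60, seed = 4)
  # a 15% perimeter inflation must bias the estimate upward strongly
  expect_gt(tab$delta_frac[tab$error_value == 0.15],
            tab$delta_frac[tab$error_value == 0] + 0.02)
})

test_that("a lattice of unit cubes gives c1 = 1 under axis-aligned slicing", {
  g <- as.matrix(expand.grid(c(0.5, 1.5), c(0.5, 1.5), c(0.5, 1.5)))
  p <- packing(g, box = 2)
  ms <- slice_packing(p, list(normal = c(0, 0, 1), offset = 0.73))
  expect_true(all(abs(ms$a - 1) < 1e-9))
  V_mean <- mean(measure_cells(periodic_voronoi(p))$V)
  expect_equal(V_mean / mean(ms$a)^(3 / 2), 1, tolerance = 1e-9)
})

test_that("volume calibration machinery produces plausible c1 at small scale", {
  vc <- volume_calibration(5.9, packings_per_point = 1, seed = 7, n_cells = 24,
                           slices_per_packing = 25)
  expect_gt(vc$c1, 1.3)
  expect_lt(vc$c1, 2.1)
  expect_equal(vc$V_mean, 1, tolerance = 0.01)
})

test_that("heterogeneity study tabulates peak and width per (mu, sigma)", {
  tab <- heterogeneity_study(5.7, c(0, 0.1), seed = 12, n_cells = 24,
                             packings_per_point = 1, slices_per_packing = 30)
  expect_equal(nrow(tab), 2)
  expect_true(all(!tab$excluded))
  # the peak summarizes the same underlying mean shape: small shift only
  expect_lt(abs(tab$peak[1] - tab$peak[2]), 0.1)
})
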