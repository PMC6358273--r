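# model energy, gradients, FIRE minimization, packing generation

test_that("energy evaluates the quadratic penalty exactly", {
  p <- packing(matrix(0.5, 1, 3), box = 1)
  expect_equal(voronoi_energy(p, model_targets(S0 = 6, V0 = 1)), 0)
  expect_equal(voronoi_energy(p, model_targets(S0 = 5, V0 = 1)), 1)
  expect_equal(voronoi_energy(p, model_targets(S0 = 5, V0 = 2, kV = 3)), 4)

  # targets set to achieved values => E = 0 for any packing
  set.seed(3)
  L <- 8^(1 / 3)
  pr <- packing(matrix(runif(24) * L, ncol = 3), L)
  ms <- measure_cells(periodic_voronoi(pr))
  expect_equal(voronoi_energy(pr, model_targets(S0 = ms$S, V0 = ms$V)), 0,
               tolerance = 1e-20)
})

test_that("energy is invariant under rigid translation (mod box)", {
  set.seed(9)
  L <- 8^(1 / 3)
  cen <- matrix(runif(24) * L, ncol = 3)
  tg <- model_targets(p0 = 5.8, n = 8)
  E1 <- voronoi_energy(packing(cen, L), tg)
  E2 <- voronoi_energy(packing(cen + rep(c(0.31, -0.12, 0.77), each = 8), L), tg)
  expect_equal(E1, E2, tolerance = 1e-9)
})

test_that("analytic gradient agrees with central finite differences", {
  set.seed(21)
  L <- 8^(1 / 3)
  p <- packing(matrix(runif(24) * L, ncol = 3), L,
               targets = model_targets(p0 = 5.8, n = 8))
  ga <- voronoi_energy_gradient(p, method = "analytic")
  gf <- voronoi_energy_gradient(p, method = "fd")
  expect_lt(max(abs(ga - gf)) / max(abs(gf)), 1e-4)

  # single periodic cell: E is independent of the center position
  p1 <- packing(matrix(0.3, 1, 3), box = 1, targets = model_targets(S0 = 5, V0 = 1))
  expect_equal(max(abs(voronoi_energy_gradient(p1, method = "fd"))), 0,
               tolerance = 1e-8)
})

test_that("FIRE terminates immediately for a single cell and relaxes fluids", {
  p1 <- packing(matrix(0.3, 1, 3), box = 1, targets = model_targets(S0 = 5, V0 = 1))
  r1 <- fire_minimize(p1)
  expect_true(r1$converged)
  expect_equal(r1$n_steps, 1)
  expect_equal(r1$E_final, 1, tolerance = 1e-12)

  set.seed(77)
  L <- 32^(1 / 3)
  p <- packing(matrix(runif(96) * L, ncol = 3), L,
               targets = model_targets(p0 = 5.8, n = 32))
  res <- fire_minimize(p)
  expect_true(res$converged)
  expect_true(all(abs(res$achieved$p3D - 5.8) < 0.01))
  expect_true(all(abs(res$achieved$V - 1) < 0.01))
  # non-increasing energy envelope
  expect_lt(res$E_final, res$E_trace[1])
  expect_equal(res$E_final, min(res$E_trace), tolerance = 1e-10)
})

test_that("generation is deterministic under seed and hits targets", {
  a <- generate_packing(16, 5.9, seed = 123)
  b <- generate_packing(16, 5.9, seed = 123)
  expect_identical(a$packing$centers, b$packing$centers)
  expect_true(all(abs(a$achieved$p3D - 5.9) < 0.02))
})

test_that("heterogeneous generation realizes requested moments", {
  res <- generate_packing(48, list(mu_p3d = 5.8, sigma_p3d = 0.08),
                          seed = 55, tol_mean = 0.02, tol_sd = 0.03)
  p3 <- res$achieved$p3D
  expect_lt(abs(mean(p3) - 5.8), 0.02)
  expect_lt(abs(sd(p3) - 0.08), 0.03)

  # Gaussian volumes, homogeneous shape: cells attain target volumes
  res2 <- generate_packing(32, list(mu_p3d = 5.9, sigma_p3d = 0,
                                    mu_v = 1, sigma_v = 0.15), seed = 66)
  expect_lt(max(abs(res2$achieved$V - res2$packing$targets$V0)), 0.02)
})

test_that("targets above the validity bound are rejected", {
  expect_error(generate_packing(16, 6.7, seed = 1), "6.4")
})
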