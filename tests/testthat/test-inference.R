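# Kolmogorov-Smirnov fitting, error-model transforms, mixtures, sensitivity

test_that("K-S distance satisfies its axioms and simple exact cases", {
  set.seed(1)
  x <- rnorm(400)
  expect_equal(ks_distance(x, x), 0)
  expect_true(ks_distance(x, rnorm(300, 2)) <= 1)
  # symmetry
  y <- rnorm(250, 0.3)
  expect_equal(ks_distance(x, y), ks_distance(y, x))
  # single observation at the median of a uniform reference
  expect_equal(ks_distance(0.5, seq(0.0005, 0.9995, length.out = 1000)), 0.5,
               tolerance = 1e-3)
  expect_error(ks_distance(numeric(0), x), "empty")
})

test_that("K-S distance equals the stats::ks.test statistic", {
  set.seed(10)
  for (r in 1:15) {
    x <- rnorm(sample(5:80, 1))
    y <- rnorm(sample(5:200, 1), mean = runif(1, -1, 1))
    expect_equal(ks_distance(x, y),
                 unname(suppressWarnings(stats::ks.test(x, y)$statistic)),
                 tolerance = 1e-12)
  }
  # with heavy ties
  x <- sample(1:4, 60, replace = TRUE)
  y <- sample(2:5, 45, replace = TRUE)
  expect_equal(ks_distance(x, y),
               unname(suppressWarnings(stats::ks.test(x, y)$statistic)),
               tolerance = 1e-12)
})

test_that("sqrt(N) D under the null sits at the Kolmogorov scale", {
  set.seed(77)
  ref <- rnorm(20000)
  stat <- replicate(200, sqrt(100) * ks_distance(rnorm(100), ref))
  # median of the Kolmogorov distribution is about 0.83
  expect_gt(stats::median(stat), 0.65)
  expect_lt(stats::median(stat), 1.05)
})

test_that("perimeter-scale transform is the exact change of variables", {
  ref <- mini_library()$distributions[[2]]
  expect_identical(apply_perimeter_scale(ref, 0), ref)
  tr <- apply_perimeter_scale(ref, 0.08)
  expect_equal(mean(tr$samples), 1.08 * mean(ref$samples), tolerance = 1e-12)
  # EDF(x) of the transform equals EDF(x / (1 + dL)) of the original
  for (x in c(3.9, 4.2, 5)) {
    expect_equal(mean(tr$samples <= x), mean(ref$samples <= x / 1.08))
  }
  expect_error(apply_perimeter_scale(ref, -1), "exceed")
})

test_that("perimeter-noise transform convolves at the delta-method scale", {
  ref <- mini_library()$distributions[[1]]
  expect_identical(apply_perimeter_noise(ref, 0), ref)
  tr1 <- apply_perimeter_noise(ref, 0.04, seed = 5)
  tr2 <- apply_perimeter_noise(ref, 0.04, seed = 5)
  expect_identical(tr1$samples, tr2$samples)
  added <- var(tr1$samples) - var(ref$samples)
  expect_equal(added, (0.04 * mean(ref$samples))^2, tolerance = 0.35)
  expect_equal(tr1$n, ref$n)
})

test_that("area filter drops exactly the sub-threshold entries", {
  df <- data.frame(p2D = c(4, 4.1, 4.2, 4.3), a = c(0.05, 0.5, 1.0, 1.45))
  out <- apply_area_filter(df, 0.1)
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "removed_fraction"), 0.25)
  expect_identical(apply_area_filter(df, 0)$a, df$a)
  expect_error(apply_area_filter(df, 1), "a_m must lie")
  big <- data.frame(p2D = rep(4, 100), a = c(rep(0.001, 95), rep(1, 5)))
  expect_error(apply_area_filter(big, 0.5), "implausible")
})

test_that("estimator recovers library members and validates domains", {
  lib <- mini_library()
  mem <- library_member(lib, 5.9)
  set.seed(6)
  est <- estimate_p3d(sample(mem$samples, 1000, replace = TRUE), lib)
  expect_equal(est$index_estimate, 5.9)
  expect_equal(est$D_min, min(est$D_profile))
  expect_equal(est$ks_statistic, sqrt(est$N) * est$D_min)
  expect_true(all(est$D_profile >= 0 & est$D_profile <= 1))

  # samples from the extreme low tail only: poor fit is flagged by D
  low <- mem$samples[mem$samples < quantile(mem$samples, 0.05)]
  est_low <- estimate_p3d(low, lib)
  expect_gt(est_low$D_min, 0.3)

  expect_error(estimate_p3d(c(4, 3.0), lib), "outside the p2D domain")
  mlib <- as_descriptor_library(lib, "m")
  expect_error(estimate_p3d(c(0.3, 1.2), mlib), "outside the m domain")
})

test_that("exact ties in the D profile resolve to the lower grid value", {
  d <- data.frame(p2D = 4 + (1:200) / 100, a = 1)
  dists <- list(
    reference_distribution(d, 5.5),
    reference_distribution(d, 6.0)
  )
  lib2 <- cellslice:::new_library(dists, "p2D", "p3D")
  expect_warning(est <- estimate_p3d(c(4.5, 5.1, 5.7), lib2), "tie")
  expect_equal(est$index_estimate, 5.5)
})

test_that("mixture weights follow the cross-section abundance rule", {
  lib <- mini_library()
  spec <- data.frame(index_value = c(5.6, 6.2), f_V = c(0.5, 0.5),
                     a_mean = c(1, 2))
  mix <- mixture_distribution(spec, lib)
  expect_equal(attr(mix, "weights"), c(2 / 3, 1 / 3), tolerance = 1e-12)
  # single component is the identity
  one <- mixture_distribution(data.frame(index_value = 5.9, f_V = 1), lib)
  expect_identical(one$samples, library_member(lib, 5.9)$samples)
  expect_error(mixture_distribution(data.frame(index_value = 5.9, f_V = 0.7), lib),
               "sum to 1")
})

test_that("a binary 50/50 tissue is fit better by the superposition than by
           any homogeneous member", {
  lib <- acc_library()
  # relax packings whose cells target 5.6 and 6.2 half-and-half
  n <- 32
  ms <- NULL
  for (s in 1:2) {
    set.seed(5150 + s)
    tg <- model_targets(S0 = rep(c(5.6, 6.2), each = n / 2), V0 = rep(1, n))
    L <- n^(1 / 3)
    res <- fire_minimize(packing(matrix(runif(3 * n) * L, ncol = 3), L,
                                 targets = tg),
                         fp = fire_params(max_steps = 2000))
    ms <- rbind(ms, cellslice:::slice_measurements(res$packing, 80, 616 + s))
  }
  mix <- mixture_distribution(data.frame(index_value = c(5.6, 6.2),
                                         f_V = c(0.5, 0.5)), lib)
  D_mix <- ks_distance(ms$p2D, mix)
  D_hom <- vapply(lib$distributions, function(d) ks_distance(ms$p2D, d), 0)
  expect_lt(D_mix, min(D_hom))
  # the nearest homogeneous member sits near the mixture mean of 5.9
  expect_true(abs(lib$grid[which.min(D_hom)] - 5.9) <= 0.1)
})

test_that("sensitivity is zero for identical members and warns on nonlinearity", {
  d <- data.frame(p2D = 4 + (1:500) / 100, a = 1)
  same <- cellslice:::new_library(list(reference_distribution(d, 5.5),
                                       reference_distribution(d, 5.6)),
                                  "p2D", "p3D")
  expect_equal(suppressWarnings(ks_sensitivity(same, 5.5, 0.1)), 0)

  # strongly curved response: members at v, v + d/2, v + d
  set.seed(8)
  mk <- function(mu, v) reference_distribution(
    data.frame(p2D = 4 + abs(rnorm(10000, mu, 0.2)), a = 1), v)
  curved <- cellslice:::new_library(list(mk(0, 5.5), mk(0.8, 5.55), mk(0.85, 5.6)),
                                    "p2D", "p3D")
  expect_warning(ks_sensitivity(curved, 5.5, 0.1), "nonlinear")
})
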