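#' Kolmogorov-Smirnov distance between a sample and a reference
#'
#' The K-S distance is the maximum separation between the empirical
#' cumulative distribution of the data and the reference cumulative
#' distribution, \eqn{D = \max_x |C_{emp}(x) - C(x)|}. The reference CDF is
#' the EDF of the stored reference samples (no smoothing inside the
#' statistic), and the supremum is evaluated exactly over the step
#' discontinuities of both functions.
#'
#' @param samples numeric data sample (nonempty).
#' @param reference a `"reference_distribution"` or numeric vector.
#' @return scalar `D` in \[0, 1\].
#' @examples
#' ks_distance(0.5, runif(100))  # about 0.5 against uniform samples
#' @export
ks_distance <- function(samples, reference) {
  y <- if (inherits(reference, "reference_distribution")) reference$samples
       else sort(as.numeric(reference))
  x <- sort(as.numeric(samples))
  if (length(x) < 1 || length(y) < 1) stopf("empty sample in K-S distance")
  if (inherits(reference, "reference_distribution") && length(y) < length(x)) {
    warnf("reference (n = %d) smaller than data sample (N = %d); D is noisy",
          length(y), length(x))
  }
  ks_dist_sorted(x, y)
}

# exact two-sample sup over jump points of pre-sorted samples
ks_dist_sorted <- function(x, y) {
  jumps <- c(x, y)
  Fx <- findInterval(jumps, x) / length(x)
  Fy <- findInterval(jumps, y) / length(y)
  dplus <- max(abs(Fx - Fy))
  # left limits matter only when a jump point is shared; findInterval at the
  # jump handles right limits, so also test just-below via counts of strict <
  Fxm <- (findInterval(jumps, x, left.open = TRUE)) / length(x)
  Fym <- (findInterval(jumps, y, left.open = TRUE)) / length(y)
  max(dplus, max(abs(Fxm - Fym)))
}

#' Measurement error model for 2D shape tracing
#'
#' Three experimentally motivated distortions of traced cell outlines:
#' a systematic fractional perimeter overestimate `delta_L` (scales `p2D`
#' samples by `1 + delta_L`), a random fractional perimeter error of standard
#' deviation `sigma_L` (multiplies each sample by an independent Gaussian
#' factor, i.e. convolves the distribution), and a small-area cutoff `a_m`
#' (shapes below `a_m` times the mean cross-section area are discarded).
#'
#' @param delta_L systematic fractional perimeter error, > -1.
#' @param sigma_L relative s.d. of the random perimeter error, >= 0.
#' @param a_m small-area cutoff as a fraction of the mean area, in \[0, 1).
#' @param seed seed for the stochastic `sigma_L` transform (part of the call
#'   contract: the convolution is realized by sampling).
#' @return list of class `"error_model"`.
#' @export
error_model <- function(delta_L = 0, sigma_L = 0, a_m = 0, seed = 1L) {
  if (delta_L <= -1) stopf("delta_L must exceed -1")
  if (sigma_L < 0) stopf("sigma_L must be non-negative")
  if (a_m < 0 || a_m >= 1) stopf("a_m must lie in [0, 1)")
  structure(list(delta_L = delta_L, sigma_L = sigma_L, a_m = a_m,
                 seed = as.integer(seed)),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("Tracing error model: delta_L = %g, sigma_L = %g, a_m = %g\n",
              x$delta_L, x$sigma_L, x$a_m))
  invisible(x)
}

#' Systematic perimeter-scale transform of a reference distribution
#'
#' A fractional perimeter overestimate `delta_L` maps the density
#' `P(p2D)` to `P(p2D / (1 + delta_L)) / (1 + delta_L)`; at sample level
#' every stored `p2D` value is multiplied by `1 + delta_L` (and perimeters
#' `L` likewise), which induces exactly that law.
#'
#' @param reference a `"reference_distribution"`.
#' @param delta_L fractional perimeter error, > -1.
#' @return transformed `"reference_distribution"`.
#' @export
apply_perimeter_scale <- function(reference, delta_L) {
  stopifnot(inherits(reference, "reference_distribution"))
  if (delta_L <= -1) stopf("delta_L must exceed -1")
  if (delta_L == 0) return(reference)
  data <- reference$data
  data[[reference$descriptor_2d]] <- data[[reference$descriptor_2d]] * (1 + delta_L)
  if ("L" %in% names(data)) data$L <- data$L * (1 + delta_L)
  reference_distribution(data, reference$index_value, reference$descriptor_2d,
                         reference$index_3d, reference$provenance)
}

#' Random perimeter-noise transform of a reference distribution
#'
#' Random tracing error of relative s.d. `sigma_L` multiplies each perimeter
#' by an independent Gaussian factor `1 + eps`, `eps ~ N(0, sigma_L)`; on the
#' distribution this is a (multiplicative) Gaussian convolution. Seeded and
#' reproducible; `sigma_L = 0` is the identity.
#'
#' @param reference a `"reference_distribution"`.
#' @param sigma_L relative standard deviation, >= 0.
#' @param seed RNG seed for the noise draws.
#' @return transformed `"reference_distribution"`.
#' @export
apply_perimeter_noise <- function(reference, sigma_L, seed = 1L) {
  stopifnot(inherits(reference, "reference_distribution"))
  if (sigma_L < 0) stopf("sigma_L must be non-negative")
  if (sigma_L == 0) return(reference)
  set.seed(seed)
  fac <- 1 + stats::rnorm(reference$n, 0, sigma_L)
  data <- reference$data
  data[[reference$descriptor_2d]] <- data[[reference$descriptor_2d]] * fac
  if ("L" %in% names(data)) data$L <- data$L * fac
  reference_distribution(data, reference$index_value, reference$descriptor_2d,
                         reference$index_3d, reference$provenance)
}

#' Small-area cutoff filter
#'
#' Removes entries whose cross-section area is below `a_m` times the mean
#' area of the set, emulating small shapes overlooked during tracing.
#' Refuses thresholds that would discard more than 90% of the set.
#'
#' @param x a `"reference_distribution"` whose data carry areas, or a data
#'   frame with an `a` column.
#' @param a_m cutoff as a fraction of the mean area, in \[0, 1).
#' @return filtered object of the same type; the removed fraction is in
#'   attribute `removed_fraction`.
#' @export
apply_area_filter <- function(x, a_m) {
  if (a_m < 0 || a_m >= 1) stopf("a_m must lie in [0, 1)")
  df <- if (inherits(x, "reference_distribution")) x$data else x
  if (!"a" %in% names(df)) stopf("area filtering needs paired areas ('a' column)")
  if (a_m == 0) {
    out <- x
    attr(out, "removed_fraction") <- 0
    return(out)
  }
  keep <- df$a >= a_m * mean(df$a)
  removed <- 1 - mean(keep)
  if (removed > 0.9) {
    stopf("area cutoff a_m = %g would remove %.0f%% of entries (implausible threshold)",
          a_m, 100 * removed)
  }
  if (inherits(x, "reference_distribution")) {
    out <- reference_distribution(df[keep, , drop = FALSE], x$index_value,
                                  x$descriptor_2d, x$index_3d, x$provenance)
  } else {
    out <- df[keep, , drop = FALSE]
  }
  attr(out, "removed_fraction") <- removed
  out
}

apply_error_model_reference <- function(reference, em) {
  if (em$a_m > 0) reference <- apply_area_filter(reference, em$a_m)
  if (em$delta_L != 0) reference <- apply_perimeter_scale(reference, em$delta_L)
  if (em$sigma_L > 0) {
    reference <- apply_perimeter_noise(reference, em$sigma_L,
                                       subseed(em$seed, round(1e6 * reference$index_value)))
  }
  reference
}

# the same distortions applied to measured data (for error-propagation
# studies that corrupt synthetic "experimental" samples against a clean
# library); x is a data frame of measurement rows
apply_error_model_data <- function(x, em, descriptor = "p2D", seed = NULL) {
  if (em$a_m > 0) x <- apply_area_filter(x, em$a_m)
  if (em$delta_L != 0) x[[descriptor]] <- x[[descriptor]] * (1 + em$delta_L)
  if (em$sigma_L > 0) {
    set.seed(seed %||% em$seed)
    x[[descriptor]] <- x[[descriptor]] * (1 + stats::rnorm(nrow(x), 0, em$sigma_L))
  }
  x
}

#' Estimate the 3D shape descriptor from 2D measurements
#'
#' Fits the sample of 2D descriptor values against every member of a
#' reference library by the Kolmogorov-Smirnov distance and returns the grid
#' value minimizing it (no inter-grid interpolation, matching the discrete
#' estimates of the reference method). With an [error_model()], the model's
#' transforms are applied to the reference distributions (the recommended
#' direction: the data stay untouched) before the fit.
#'
#' @param samples numeric vector of descriptor values, or a data frame with
#'   the descriptor column (plus `a` if area filtering is to act on data).
#' @param library a `"shape_library"`.
#' @param error_mod optional [error_model()]; identity when `NULL`.
#' @param direction `"reference"` (default) applies the error model to the
#'   library; `"data"` corrupts the data sample instead (for error studies).
#' @param validate reject samples outside the descriptor domain
#'   (`p2D < 2*sqrt(pi)`, `m` outside \[0, 1)). Disable when feeding
#'   deliberately noise-corrupted data.
#' @return object of class `"estimate_result"`: `index_estimate`, `D_min`,
#'   `ks_statistic` (`sqrt(N) * D_min`), `N`, `D_profile`, `grid`.
#' @export
estimate_p3d <- function(samples, library, error_mod = NULL,
                         direction = c("reference", "data"), validate = TRUE) {
  stopifnot(inherits(library, "shape_library"))
  direction <- match.arg(direction)
  desc <- library$descriptor_2d
  df <- NULL
  if (is.data.frame(samples)) {
    df <- samples
    if (!desc %in% names(df)) stopf("samples lack the descriptor column '%s'", desc)
  } else {
    df <- stats::setNames(data.frame(x = as.numeric(samples)), desc)
  }
  if (nrow(df) < 1) stopf("no samples to estimate from")

  if (!is.null(error_mod) && direction == "data") {
    df <- apply_error_model_data(df, error_mod, desc)
  }
  x <- df[[desc]]
  if (validate) {
    bad <- if (desc == "p2D") which(x < 2 * sqrt(pi) - 1e-9) else
      which(x < 0 | x >= 1)
    if (length(bad)) {
      stopf("%d sample(s) outside the %s domain (first offenders: %s)",
            length(bad), desc,
            paste(sprintf("%.4g", utils::head(x[bad], 5)), collapse = ", "))
    }
  }

  xs <- sort(x)
  D <- vapply(library$distributions, function(ref) {
    if (!is.null(error_mod) && direction == "reference") {
      ref <- apply_error_model_reference(ref, error_mod)
    }
    ks_dist_sorted(xs, ref$samples)
  }, 0)
  imin <- which(D == min(D))
  if (length(imin) > 1) {
    warnf("K-S tie between grid values %s; taking the lower",
          paste(sprintf("%.4g", library$grid[imin]), collapse = ", "))
  }
  imin <- imin[1]
  structure(list(index_estimate = library$grid[imin], D_min = D[imin],
                 ks_statistic = sqrt(length(xs)) * D[imin], N = length(xs),
                 D_profile = stats::setNames(D, sprintf("%.4g", library$grid)),
                 grid = library$grid, index_3d = library$index_3d),
            class = "estimate_result")
}

#' @export
print.estimate_result <- function(x, ...) {
  cat(sprintf("Estimated %s = %.4g (K-S D = %.4f, sqrt(N) D = %.3f, N = %d)\n",
              x$index_3d, x$index_estimate, x$D_min, x$ks_statistic, x$N))
  invisible(x)
}

# samples of the library at an arbitrary index value; exact member if on the
# grid, otherwise quantile-wise linear interpolation between neighbors
samples_at <- function(library, value, tol = 1e-8) {
  i <- which(abs(library$grid - value) <= tol)
  if (length(i) == 1) return(library$distributions[[i]]$samples)
  if (value < min(library$grid) || value > max(library$grid)) {
    stopf("index value %g outside the library grid range", value)
  }
  warnf("index value %g not on the library grid; interpolating between members", value)
  hi <- which(library$grid > value)[1]
  lo <- hi - 1
  w <- (value - library$grid[lo]) / (library$grid[hi] - library$grid[lo])
  slo <- library$distributions[[lo]]$samples
  shi <- library$distributions[[hi]]$samples
  np <- min(length(slo), length(shi))
  probs <- (seq_len(np) - 0.5) / np
  (1 - w) * stats::quantile(slo, probs, names = FALSE, type = 7) +
    w * stats::quantile(shi, probs, names = FALSE, type = 7)
}

#' Predicted 2D distribution of a heterogeneous (mixture) tissue
#'
#' A tissue with subpopulations at different 3D shape indices produces a 2D
#' distribution close to the weighted superposition
#' \deqn{P_{mix} = \sum_\beta f_\beta P_{p^{3D}_\beta},}
#' where the cross-section abundance weights account for larger cells being
#' cut more often:
#' \deqn{f_\beta = \frac{f^V_\beta / \langle a \rangle_\beta}{\sum_\alpha f^V_\alpha / \langle a \rangle_\alpha},}
#' with `f_V` the volume fraction and `<a>` the mean cross-section area of
#' each subpopulation.
#'
#' @param spec data frame with columns `index_value`, `f_V` and optionally
#'   `a_mean` (defaults to each member's mean stored area).
#' @param library a `"shape_library"`.
#' @param n_total pooled sample size (default: sum of member sizes).
#' @return a `"reference_distribution"` holding the pooled sample set; the
#'   weights are in attribute `weights`.
#' @export
mixture_distribution <- function(spec, library, n_total = NULL) {
  stopifnot(inherits(library, "shape_library"), is.data.frame(spec))
  if (!all(c("index_value", "f_V") %in% names(spec))) {
    stopf("mixture spec needs columns index_value and f_V")
  }
  if (abs(sum(spec$f_V) - 1) > 1e-6) {
    stopf("volume fractions f_V must sum to 1 (got %.6g)", sum(spec$f_V))
  }
  a_mean <- spec$a_mean
  if (is.null(a_mean)) {
    a_mean <- vapply(spec$index_value, function(v) {
      mem <- library_member(library, v)
      if (!"a" %in% names(mem$data)) stopf("library lacks stored areas for the mixture weights")
      mean(mem$data$a)
    }, 0)
  }
  if (any(a_mean <= 0)) stopf("mean cross-section areas must be positive")
  w <- (spec$f_V / a_mean) / sum(spec$f_V / a_mean)

  if (nrow(spec) == 1) {  # single component: exact identity
    out <- library_member(library, spec$index_value)
    attr(out, "weights") <- 1
    return(out)
  }
  member_samples <- lapply(spec$index_value, samples_at, library = library)
  n_total <- n_total %||% sum(vapply(member_samples, length, 0L))
  pooled <- unlist(Map(function(s, wk) {
    nk <- max(1L, round(wk * n_total))
    stats::quantile(s, (seq_len(nk) - 0.5) / nk, names = FALSE, type = 7)
  }, member_samples, w))
  out <- reference_distribution(
    stats::setNames(data.frame(x = pooled), library$descriptor_2d),
    index_value = sum(w * spec$index_value),
    descriptor_2d = library$descriptor_2d, index_3d = library$index_3d,
    provenance = list(mixture = spec))
  attr(out, "weights") <- w
  out
}

#' Sensitivity of the 2D distribution to the 3D descriptor
#'
#' How fast the reference distribution moves when the 3D descriptor changes:
#' the K-S distance between the members at `at_value` and `at_value + delta`,
#' divided by `delta`. When the library also holds a member at
#' `at_value + delta/2`, linearity is checked by halving the step and a
#' warning is attached if the two slopes disagree by more than 20%.
#'
#' @param library a `"shape_library"`.
#' @param at_value base grid value.
#' @param delta descriptor increment (both ends must be on the grid).
#' @return scalar `dD/ddelta`, with attribute `nonlinearity` when checked.
#' @export
ks_sensitivity <- function(library, at_value, delta) {
  a <- library_member(library, at_value)
  b <- library_member(library, at_value + delta)
  if (min(a$n, b$n) < 1e4) {
    warnf("sensitivity estimated from fewer than 10^4 samples per member; noisy")
  }
  dDdd <- ks_dist_sorted(a$samples, b$samples) / delta
  half <- tryCatch(library_member(library, at_value + delta / 2),
                   error = function(e) NULL)
  if (!is.null(half)) {
    dDdd2 <- ks_dist_sorted(a$samples, half$samples) / (delta / 2)
    nl <- abs(dDdd2 - dDdd) / max(dDdd, 1e-12)
    attr(dDdd, "nonlinearity") <- nl
    if (nl > 0.2) warnf("K-S response nonlinear over delta = %g (%.0f%% change on halving)",
                        delta, 100 * nl)
  }
  dDdd
}
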