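#' Random and systematic estimation error versus sample size
#'
#' Repeatedly draws `N` descriptor values from a test pool at a known 3D
#' shape index, estimates the index against the library, and summarizes the
#' spread: the fractional random error `sigma_frac = sd(p_est)/p3D` and the
#' fractional systematic error `delta_frac = (mean(p_est) - p3D)/p3D`.
#'
#' @param library a `"shape_library"`.
#' @param true_p3d the generating grid value.
#' @param N_values sample sizes to test.
#' @param reps repetitions per sample size (>= 30).
#' @param seed integer seed.
#' @param test_samples optional independent pool of descriptor values (or
#'   measurement data frame) drawn from packings at `true_p3d`; defaults to
#'   bootstrap resampling of the library member itself (fast, slightly
#'   favorable to the true member).
#' @return data frame of class `"error_curve"`: `N`, `sigma_frac`,
#'   `delta_frac`, plus attribute `estimates` (reps x length(N) matrix).
#' @export
sample_size_study <- function(library, true_p3d, N_values, reps = 200, seed = 1L,
                              test_samples = NULL) {
  if (reps < 30) stopf("reps must be at least 30 for a meaningful spread")
  pool <- if (is.null(test_samples)) {
    library_member(library, true_p3d)$samples
  } else if (is.data.frame(test_samples)) {
    test_samples[[library$descriptor_2d]]
  } else {
    as.numeric(test_samples)
  }
  set.seed(seed)
  est <- matrix(NA_real_, reps, length(N_values))
  for (j in seq_along(N_values)) {
    for (r in seq_len(reps)) {
      x <- sample(pool, N_values[j], replace = TRUE)
      est[r, j] <- estimate_p3d(x, library, validate = FALSE)$index_estimate
    }
  }
  out <- data.frame(
    N = N_values,
    sigma_frac = apply(est, 2, stats::sd) / true_p3d,
    delta_frac = (colMeans(est) - true_p3d) / true_p3d
  )
  attr(out, "estimates") <- est
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  attr(out, "true_p3d") <- true_p3d
  class(out) <- c("error_curve", "data.frame")
  out
}

#' Error propagation under tracing-error models
#'
#' Replicates the measurement-noise studies: data samples drawn from a test
#' pool at a known shape index are corrupted by one error type at a time
#' (systematic perimeter scale `delta_L`, random perimeter noise `sigma_L`,
#' or small-area dropout `a_m`) and fitted against the clean library; the
#' random and systematic errors of the estimate are tabulated per error
#' magnitude and sample size.
#'
#' @param library a `"shape_library"` (with stored areas for `a_m`).
#' @param error_type one of `"delta_L"`, `"sigma_L"`, `"a_m"`.
#' @param error_values magnitudes of that error to scan.
#' @param N_values sample sizes.
#' @param true_p3d generating grid value.
#' @param reps repetitions per grid cell.
#' @param seed integer seed.
#' @param test_samples independent measurement data frame at `true_p3d`
#'   (defaults to the library member's own rows).
#' @return tidy data frame: `error_type`, `error_value`, `N`, `sigma_frac`,
#'   `delta_frac`.
#' @export
error_propagation_study <- function(library, error_type = c("delta_L", "sigma_L", "a_m"),
                                    error_values, N_values, true_p3d, reps = 200,
                                    seed = 1L, test_samples = NULL) {
  error_type <- match.arg(error_type)
  pool <- test_samples %||% library_member(library, true_p3d)$data
  if (!is.data.frame(pool)) {
    pool <- stats::setNames(data.frame(x = as.numeric(pool)), library$descriptor_2d)
  }
  desc <- library$descriptor_2d
  rows <- list()
  for (ev in error_values) {
    em <- switch(error_type,
      delta_L = error_model(delta_L = ev),
      sigma_L = error_model(sigma_L = ev),
      a_m = error_model(a_m = ev))
    # area dropout biases WHICH rows can be drawn; apply it to the pool once
    pool_ev <- if (error_type == "a_m" && ev > 0) apply_area_filter(pool, ev) else pool
    for (N in N_values) {
      set.seed(subseed(seed, round(1e6 * ev), N))
      est <- numeric(reps)
      for (r in seq_len(reps)) {
        rows_r <- pool_ev[sample.int(nrow(pool_ev), N, replace = TRUE), , drop = FALSE]
        if (error_type != "a_m") {
          rows_r <- apply_error_model_data(rows_r, em, desc,
                                           seed = subseed(seed, round(1e6 * ev), N, r))
        }
        est[r] <- estimate_p3d(rows_r[[desc]], library, validate = FALSE)$index_estimate
      }
      rows[[length(rows) + 1]] <- data.frame(
        error_type = error_type, error_value = ev, N = N,
        sigma_frac = stats::sd(est) / true_p3d,
        delta_frac = (mean(est) - true_p3d) / true_p3d)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "true_p3d") <- true_p3d
  out
}

#' Calibration of mean volume against mean cross-section area
#'
#' Dimensional analysis gives `<V> = c1 <a>^(3/2)` for confluent tissue; the
#' dimensionless `c1` still depends on cell shape. This study measures
#' `c1 = <V> / <a>^(3/2)` on homogeneous packings over a grid of shape
#' indices and fits a line `c1 ~ p3D`.
#'
#' @param p3d_grid shape-index grid values.
#' @param packings_per_point independent packings per grid value.
#' @param seed integer seed.
#' @param n_cells cells per packing.
#' @param slices_per_packing random planes per packing.
#' @param target_spec_fun optional function(p3d) -> target spec, to rerun the
#'   calibration under Gaussian heterogeneity.
#' @param fp [fire_params()] for generation.
#' @return data frame of class `"volume_calibration"` with `p3D`, `a_mean`,
#'   `V_mean`, `c1`; the linear fit is attribute `fit` (slope, intercept).
#' @export
volume_calibration <- function(p3d_grid, packings_per_point = 2, seed = 1L,
                               n_cells = 48, slices_per_packing = 40,
                               target_spec_fun = NULL,
                               fp = fire_params(max_steps = 2000, target_tol = 0.002)) {
  rows <- list()
  for (gi in seq_along(p3d_grid)) {
    a_all <- numeric(0)
    V_all <- numeric(0)
    for (pk in seq_len(packings_per_point)) {
      spec <- if (is.null(target_spec_fun)) p3d_grid[gi] else target_spec_fun(p3d_grid[gi])
      res <- generate_packing(n_cells, spec, seed = subseed(seed, gi, pk), fp = fp)
      ms <- slice_measurements(res$packing, slices_per_packing,
                               subseed(seed, gi, pk, 13))
      a_all <- c(a_all, ms$a)
      V_all <- c(V_all, res$achieved$V)
    }
    rows[[gi]] <- data.frame(p3D = p3d_grid[gi], a_mean = mean(a_all),
                             V_mean = mean(V_all),
                             c1 = mean(V_all) / mean(a_all)^(3 / 2))
  }
  out <- do.call(rbind, rows)
  if (nrow(out) >= 2) {
    attr(out, "fit") <- stats::coef(stats::lm(c1 ~ p3D, data = out))
  }
  class(out) <- c("volume_calibration", "data.frame")
  out
}

#' @rdname volume_calibration
#' @param library a `"shape_library"` built with stored areas; `c1` is
#'   computed from each member's mean cross-section area, with the mean cell
#'   volume taken as 1 (exact in the fluid regime, where every cell attains
#'   its unit target volume).
#' @export
volume_calibration_from_library <- function(library) {
  stopifnot(inherits(library, "shape_library"))
  out <- do.call(rbind, lapply(library$distributions, function(d) {
    if (!"a" %in% names(d$data)) stopf("library lacks stored areas")
    data.frame(p3D = d$index_value, a_mean = mean(d$data$a), V_mean = 1,
               c1 = 1 / mean(d$data$a)^(3 / 2))
  }))
  if (nrow(out) >= 2) {
    attr(out, "fit") <- stats::coef(stats::lm(c1 ~ p3D, data = out))
  }
  class(out) <- c("volume_calibration", "data.frame")
  out
}

#' Peak/HWHM response to tissue heterogeneity
#'
#' Generates packings with Gaussian-distributed target shape indices
#' (mean `mu`, s.d. `sigma`; `sigma = 0` falls back to homogeneous targets),
#' slices them, and summarizes the 2D distribution peak and half-width for
#' every (mu, sigma) combination. Combinations the generator cannot realize
#' (accept/reject exhaustion near the validity edges) are reported as
#' excluded rows with `NA` summaries.
#'
#' @param mu_grid means of the target shape-index distribution.
#' @param sigma_grid standard deviations (0 allowed).
#' @param seed integer seed.
#' @param n_cells cells per packing.
#' @param packings_per_point packings per combination.
#' @param slices_per_packing random planes per packing.
#' @param sigma_v relative s.d. of Gaussian target volumes (0 = homogeneous
#'   volumes).
#' @param fp [fire_params()] for generation.
#' @return tidy data frame: `mu`, `sigma`, `peak`, `hwhm`, `n`, `excluded`.
#' @export
heterogeneity_study <- function(mu_grid, sigma_grid, seed = 1L, n_cells = 48,
                                packings_per_point = 2, slices_per_packing = 40,
                                sigma_v = 0, fp = fire_params(max_steps = 2000, target_tol = 0.002)) {
  rows <- list()
  for (mu in mu_grid) {
    for (sg in sigma_grid) {
      spec <- if (sg == 0 && sigma_v == 0) mu else
        list(mu_p3d = mu, sigma_p3d = sg, mu_v = 1, sigma_v = sigma_v)
      ms <- NULL
      excluded <- FALSE
      for (pk in seq_len(packings_per_point)) {
        res <- tryCatch(
          generate_packing(n_cells, spec, seed = subseed(seed, round(1e3 * mu),
                                                         round(1e3 * sg), pk),
                           fp = fp),
          error = function(e) NULL)
        if (is.null(res)) {
          excluded <- TRUE
          break
        }
        ms <- rbind(ms, slice_measurements(res$packing, slices_per_packing,
                                           subseed(seed, round(1e3 * mu),
                                                   round(1e3 * sg), pk, 17)))
      }
      if (excluded || is.null(ms)) {
        rows[[length(rows) + 1]] <- data.frame(mu = mu, sigma = sg, peak = NA,
                                               hwhm = NA, n = 0, excluded = TRUE)
      } else {
        sm <- summarize_distribution(ms$p2D)
        rows[[length(rows) + 1]] <- data.frame(mu = mu, sigma = sg,
                                               peak = sm$peak, hwhm = sm$hwhm,
                                               n = nrow(ms), excluded = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  out
}
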