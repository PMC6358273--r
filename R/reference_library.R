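#' Reference distribution of a 2D shape descriptor
#'
#' One member of a reference library: the sample set of a 2D descriptor
#' (`p2D` or `m`) accumulated from slices of packings at a single value of a
#' 3D descriptor (`p3D` or `f_R`). Raw sorted samples are stored (not
#' histograms) because the K-S statistic needs the empirical distribution
#' function exactly; the paired measurement rows (perimeter, area, both
#' descriptors) are retained for error-model transforms such as small-area
#' filtering.
#'
#' @param data data frame of slice measurements with at least the descriptor
#'   column; typically columns `p2D`, `m`, `a`.
#' @param index_value value of the 3D descriptor the samples correspond to.
#' @param descriptor_2d `"p2D"` or `"m"`.
#' @param index_3d `"p3D"` or `"f_R"`.
#' @param provenance free-form list (packings, slices, seeds).
#' @return object of class `"reference_distribution"` with sorted `samples`,
#'   sample count `n`, and the aligned `data`.
#' @export
reference_distribution <- function(data, index_value, descriptor_2d = "p2D",
                                   index_3d = "p3D", provenance = list()) {
  descriptor_2d <- match.arg(descriptor_2d, c("p2D", "m"))
  index_3d <- match.arg(index_3d, c("p3D", "f_R"))
  if (is.numeric(data)) data <- stats::setNames(data.frame(x = data), descriptor_2d)
  if (!descriptor_2d %in% names(data)) {
    stopf("measurement data lacks the descriptor column '%s'", descriptor_2d)
  }
  if (nrow(data) < 1) stopf("a reference distribution needs at least one sample")
  ord <- order(data[[descriptor_2d]])
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  structure(list(samples = data[[descriptor_2d]], n = nrow(data),
                 index_value = index_value, descriptor_2d = descriptor_2d,
                 index_3d = index_3d, data = data, provenance = provenance),
            class = "reference_distribution")
}

#' @export
print.reference_distribution <- function(x, ...) {
  cat(sprintf("Reference distribution: %s at %s = %.4g, n = %d, median %s = %.4g\n",
              x$descriptor_2d, x$index_3d, x$index_value, x$n,
              x$descriptor_2d, stats::median(x$samples)))
  invisible(x)
}

new_library <- function(distributions, descriptor_2d, index_3d, config = list()) {
  grid <- vapply(distributions, `[[`, 0, "index_value")
  if (is.unsorted(grid, strictly = TRUE)) {
    ord <- order(grid)
    distributions <- distributions[ord]
    grid <- grid[ord]
  }
  if (any(diff(grid) <= 0)) stopf("library grid values must be distinct")
  structure(list(grid = grid, distributions = distributions,
                 descriptor_2d = descriptor_2d, index_3d = index_3d,
                 config = config),
            class = "shape_library")
}

#' @export
print.shape_library <- function(x, ...) {
  ns <- vapply(x$distributions, `[[`, 0, "n")
  cat(sprintf(
    "Reference library: %s indexed by %s, %d grid points in [%.4g, %.4g], %d-%d samples each\n",
    x$descriptor_2d, x$index_3d, length(x$grid), min(x$grid), max(x$grid),
    min(ns), max(ns)))
  invisible(x)
}

#' Fetch a library member by 3D-descriptor value
#'
#' @param lib a `"shape_library"`.
#' @param index_value grid value (matched within `tol`).
#' @param tol matching tolerance.
#' @return the `"reference_distribution"` at that grid point.
#' @export
library_member <- function(lib, index_value, tol = 1e-8) {
  stopifnot(inherits(lib, "shape_library"))
  i <- which(abs(lib$grid - index_value) <= tol)
  if (length(i) != 1) stopf("no unique library member at %s = %g",
                            lib$index_3d, index_value)
  lib$distributions[[i]]
}

# repeatedly slice a packing with seeded random planes
slice_measurements <- function(p, n_slices, seed, boundary = "centroid") {
  set.seed(seed)
  out <- vector("list", n_slices)
  for (s in seq_len(n_slices)) {
    ms <- slice_packing(p, random_plane(p$box), boundary = boundary)
    ms$slice <- rep(s, nrow(ms))
    out[[s]] <- ms
  }
  do.call(rbind, out)
}

#' Build a reference library over a grid of target shape indices
#'
#' For each grid value, homogeneous packings are generated
#' ([generate_packing()]) and sliced with seeded random planes
#' ([slice_packing()], associated-point rule) until at least `cells_per_point`
#' cross-section measurements accumulate. Deterministic under `seed`.
#'
#' The per-measurement rows keep `p2D`, `m` and the cross-section area `a`,
#' so one build serves either descriptor and supports area-cutoff error
#' models.
#'
#' @param grid target 3D shape indices, within the model validity range
#'   \[5.4, 6.4\].
#' @param cells_per_point minimum measurements per grid value (>= 100).
#' @param seed integer seed.
#' @param n_cells cells per packing (the reference scale uses a few dozen
#'   cells per packing and many independent packings/slices).
#' @param descriptor_2d which descriptor the library is indexed for
#'   (`"p2D"` or `"m"`); both are stored either way.
#' @param slices_per_packing random planes taken per packing before a fresh
#'   packing is generated (spaced draws keep inter-slice correlation modest).
#' @param fp [fire_params()] used for generation.
#' @param keep_packings retain the relaxed packings in each member's
#'   provenance (needed for [build_fr_library()] reuse).
#' @return a `"shape_library"`.
#' @export
build_library <- function(grid, cells_per_point, seed, n_cells = 48,
                          descriptor_2d = "p2D", slices_per_packing = 40,
                          fp = fire_params(max_steps = 2000, target_tol = 0.002),
                          keep_packings = FALSE) {
  if (any(grid < 5.4 - 1e-9) || any(grid > 6.4 + 1e-9)) {
    stopf("grid values must lie in the model validity range [5.4, 6.4]")
  }
  if (cells_per_point < 100) stopf("cells_per_point must be at least 100")
  dists <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    acc <- list()
    n_acc <- 0
    pk <- 0
    packings <- list()
    while (n_acc < cells_per_point) {
      pk <- pk + 1
      res <- tryCatch(
        generate_packing(n_cells, grid[gi], seed = subseed(seed, gi, pk), fp = fp),
        error = function(e) stopf("library generation failed at grid value %g: %s",
                                  grid[gi], conditionMessage(e)))
      ms <- slice_measurements(res$packing, slices_per_packing,
                               subseed(seed, gi, pk, 7))
      ms$packing <- pk
      acc[[pk]] <- ms
      n_acc <- n_acc + nrow(ms)
      if (keep_packings) packings[[pk]] <- res$packing
    }
    data <- do.call(rbind, acc)
    prov <- list(n_packings = pk, n_cells = n_cells, seed = seed,
                 slices_per_packing = slices_per_packing)
    if (keep_packings) prov$packings <- packings
    dists[[gi]] <- reference_distribution(data, grid[gi], descriptor_2d,
                                          "p3D", provenance = prov)
  }
  new_library(dists, descriptor_2d, "p3D",
              config = list(cells_per_point = cells_per_point,
                            n_cells = n_cells, seed = seed))
}

#' Build a library indexed by inscribed-sphere fraction
#'
#' Uses existing packings: every 3D cell is measured for `f_R` (largest
#' inscribed sphere over cell volume), cells are binned by `f_R`, and each
#' bin collects the 2D descriptors of the cross-sections of its member cells
#' from seeded random slices. Empty bins are dropped with a warning.
#'
#' @param packings list of [packing()]s or `"minimization_result"`s.
#' @param bin_edges ascending bin edges within (0, 1).
#' @param seed integer seed for the slicing planes.
#' @param slices_per_packing random planes per packing.
#' @param descriptor_2d `"p2D"` (default) or `"m"`.
#' @return a `"shape_library"` indexed by bin-center `f_R`.
#' @export
build_fr_library <- function(packings, bin_edges, seed, slices_per_packing = 40,
                             descriptor_2d = "p2D") {
  if (any(bin_edges <= 0) || any(bin_edges >= 1) || is.unsorted(bin_edges, strictly = TRUE)) {
    stopf("bin edges must be strictly increasing within (0, 1)")
  }
  packings <- lapply(packings, function(p) if (inherits(p, "minimization_result")) p$packing else p)
  per_bin <- vector("list", length(bin_edges) - 1)
  for (pi in seq_along(packings)) {
    p <- packings[[pi]]
    fr <- measure_cells(periodic_voronoi(p), f_R = TRUE)$f_R
    ms <- slice_measurements(p, slices_per_packing, subseed(seed, pi))
    ms$f_R <- fr[ms$cell_id]
    bin <- findInterval(ms$f_R, bin_edges, rightmost.closed = TRUE)
    keep <- bin >= 1 & bin <= length(per_bin)
    ms <- ms[keep, , drop = FALSE]
    bin <- bin[keep]
    for (b in unique(bin)) {
      per_bin[[b]] <- rbind(per_bin[[b]], ms[bin == b, , drop = FALSE])
    }
  }
  centers <- (bin_edges[-length(bin_edges)] + bin_edges[-1]) / 2
  occupied <- !vapply(per_bin, is.null, TRUE)
  if (any(!occupied)) {
    warnf("dropping %d empty f_R bin(s): %s", sum(!occupied),
          paste(sprintf("%.3g", centers[!occupied]), collapse = ", "))
  }
  dists <- Map(function(df, ctr) {
    reference_distribution(df, ctr, descriptor_2d, "f_R",
                           provenance = list(n_obs = nrow(df)))
  }, per_bin[occupied], centers[occupied])
  new_library(dists, descriptor_2d, "f_R",
              config = list(bin_edges = bin_edges, seed = seed))
}

#' Peak and half-width of a reference distribution
#'
#' Kernel-density summary of a sample set: the peak location (mode of the
#' Gaussian-kernel KDE, Silverman's bandwidth by default) and the half-width
#' at half maximum of the contiguous region around the peak where the density
#' stays above half its peak value. These are the tail-robust summaries used
#' in place of mean and variance, which the divergent large-`p2D` tail would
#' dominate.
#'
#' @param dist a `"reference_distribution"` or a numeric sample vector
#'   (`n >= 50`).
#' @param bw bandwidth rule or value, as in [stats::density()].
#' @return list of class `"distribution_summary"`: `peak`, `hwhm`, `bw`.
#' @export
summarize_distribution <- function(dist, bw = "nrd0") {
  x <- if (inherits(dist, "reference_distribution")) dist$samples else as.numeric(dist)
  if (length(x) < 50) stopf("need at least 50 samples to summarize a distribution")
  d <- stats::density(x, bw = bw, n = 2048)
  ipk <- which.max(d$y)
  # competing peaks: other local maxima within 5% of the global one
  loc_max <- which(diff(sign(diff(d$y))) == -2) + 1
  rivals <- loc_max[d$y[loc_max] >= 0.95 * d$y[ipk] & abs(loc_max - ipk) > 3]
  if (length(rivals)) {
    warnf("multimodal density: %d competing peak(s) within 5%% of the maximum; returning the global mode",
          length(rivals))
  }
  half <- d$y[ipk] / 2
  il <- ipk
  while (il > 1 && d$y[il - 1] >= half) il <- il - 1
  ir <- ipk
  while (ir < length(d$y) && d$y[ir + 1] >= half) ir <- ir + 1
  # linear interpolation to the exact half-height crossings
  xl <- if (il == 1) d$x[1] else {
    stats::approx(d$y[c(il - 1, il)], d$x[c(il - 1, il)], xout = half)$y
  }
  xr <- if (ir == length(d$y)) d$x[length(d$x)] else {
    stats::approx(d$y[c(ir + 1, ir)], d$x[c(ir + 1, ir)], xout = half)$y
  }
  structure(list(peak = d$x[ipk], hwhm = (xr - xl) / 2, bw = d$bw),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("peak %.4f, HWHM %.4f (bw %.4g)\n", x$peak, x$hwhm, x$bw))
  invisible(x)
}

LIBRARY_SCHEMA <- "cellslice-library-1"

#' Persist and reload a reference library
#'
#' Plain-text layout: `manifest.json` (schema version, descriptors, grid,
#' config, per-member sample counts) plus one CSV of measurement rows per
#' grid point. Round-trips exactly.
#'
#' @param lib a `"shape_library"`.
#' @param path directory to create/read.
#' @return `save_library` returns `path` invisibly; `load_library` the
#'   reconstructed library.
#' @export
save_library <- function(lib, path) {
  stopifnot(inherits(lib, "shape_library"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("samples_%02d.csv", seq_along(lib$grid))
  manifest <- list(
    schema = LIBRARY_SCHEMA,
    descriptor_2d = lib$descriptor_2d,
    index_3d = lib$index_3d,
    grid = lib$grid,
    files = files,
    n = vapply(lib$distributions, `[[`, 0, "n"),
    config = lib$config[setdiff(names(lib$config), "packings")]
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(lib$grid)) {
    df <- lib$distributions[[i]]$data
    keep <- intersect(c("cell_id", "L", "a", "p2D", "m"), names(df))
    df <- df[, keep, drop = FALSE]
    # 17 significant digits round-trip IEEE doubles exactly through text
    for (cn in keep) {
      if (is.double(df[[cn]])) df[[cn]] <- sprintf("%.17g", df[[cn]])
    }
    utils::write.csv(df, file.path(path, files[i]), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' @rdname save_library
#' @export
load_library <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stopf("not a library directory: missing %s", mf)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$schema, LIBRARY_SCHEMA)) {
    stopf("library format error: schema '%s' (expected '%s')",
          manifest$schema %||% "<none>", LIBRARY_SCHEMA)
  }
  if (!manifest$descriptor_2d %in% c("p2D", "m")) {
    stopf("library format error: unknown 2D descriptor tag '%s'",
          manifest$descriptor_2d)
  }
  if (!manifest$index_3d %in% c("p3D", "f_R")) {
    stopf("library format error: unknown 3D descriptor tag '%s'",
          manifest$index_3d)
  }
  dists <- vector("list", length(manifest$grid))
  for (i in seq_along(manifest$grid)) {
    f <- file.path(path, manifest$files[i])
    if (!file.exists(f)) stopf("library format error: missing member file %s", f)
    df <- utils::read.csv(f)
    if (nrow(df) != manifest$n[i]) {
      stopf("library format error: %s has %d rows, manifest says %d (truncated?)",
            manifest$files[i], nrow(df), manifest$n[i])
    }
    dists[[i]] <- reference_distribution(df, manifest$grid[i],
                                         manifest$descriptor_2d,
                                         manifest$index_3d)
  }
  cfg <- manifest$config
  if (is.null(cfg)) cfg <- list()
  new_library(dists, manifest$descriptor_2d, manifest$index_3d, config = cfg)
}
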