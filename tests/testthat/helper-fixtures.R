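# Shared heavyweight fixtures, built once per test run and cached in an
# environment.  Sizes follow the scaled-down reference protocol: the library
# grid matches the reference 0.05 spacing but with ~2000 sliced cells per
# point (instead of 30,000) from 48-cell packings, so the whole suite stays
# within a desk-scale budget.  CELLSLICE_FIXTURE_CACHE may point to a
# directory for cross-run caching during development; when unset (the normal
# case) everything is rebuilt in-process.

.fixtures <- new.env(parent = emptyenv())

fixture_cached <- function(name, builder) {
  if (!is.null(.fixtures[[name]])) return(.fixtures[[name]])
  cache_dir <- Sys.getenv("CELLSLICE_FIXTURE_CACHE", "")
  if (nzchar(cache_dir)) {
    path <- file.path(cache_dir, name)
    if (dir.exists(path)) {
      obj <- load_library(path)
      .fixtures[[name]] <- obj
      return(obj)
    }
    obj <- builder()
    save_library(obj, path)
    .fixtures[[name]] <- obj
    return(obj)
  }
  obj <- builder()
  .fixtures[[name]] <- obj
  obj
}

# full-resolution grid (reference 0.05 spacing), ~2000 measurements per point
acc_library <- function() {
  fixture_cached("acc_lib", function() {
    build_library(seq(5.4, 6.4, by = 0.05), cells_per_point = 2000,
                  seed = 20260918, n_cells = 48, slices_per_packing = 80)
  })
}

# large-sample members for K-S sensitivity (>= 10^4 samples per distribution);
# the 5.45 member doubles as the half-step linearity check
acc_sens_library <- function() {
  fixture_cached("acc_sens_lib", function() {
    build_library(c(5.4, 5.45, 5.5, 6.35, 6.4), cells_per_point = 10000,
                  seed = 424242, n_cells = 48, slices_per_packing = 250)
  })
}

# independent test pools (never part of the reference library) for drawing
# "experimental" samples in error studies
acc_test_pools <- function() {
  fixture_cached("acc_pools", function() {
    build_library(c(5.4, 5.6), cells_per_point = 4000, seed = 909090,
                  n_cells = 48, slices_per_packing = 80)
  })
}

# small library for fast inference tests
mini_library <- function() {
  fixture_cached("mini_lib", function() {
    build_library(c(5.6, 5.9, 6.2), cells_per_point = 600, seed = 111,
                  n_cells = 32, slices_per_packing = 30)
  })
}

# one relaxed fluid-regime packing for slicing tests
relaxed_packing <- function() {
  if (is.null(.fixtures$relaxed)) {
    .fixtures$relaxed <- generate_packing(32, 5.8, seed = 4242)$packing
  }
  .fixtures$relaxed
}

# view an existing library through its other stored 2D descriptor
as_descriptor_library <- function(lib, descriptor) {
  dists <- lapply(lib$distributions, function(d) {
    reference_distribution(d$data, d$index_value, descriptor, d$index_3d,
                           d$provenance)
  })
  cellslice:::new_library(dists, descriptor, lib$index_3d, lib$config)
}
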