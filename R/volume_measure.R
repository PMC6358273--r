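#' Labeled voxel volume
#'
#' Container for an integer-labeled 3D image (0 = background) with physical
#' voxel spacing, the direct-measurement pathway for experimentally segmented
#' tissue.
#'
#' @param labels 3D integer array of cell labels.
#' @param spacing voxel size per axis (length-3 or scalar), same length unit
#'   on all axes.
#' @return object of class `"labeled_volume"`.
#' @export
labeled_volume <- function(labels, spacing = c(1, 1, 1)) {
  if (length(dim(labels)) != 3) stopf("labels must be a 3D array")
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  spacing <- as.double(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) stopf("spacing must be 3 positive lengths")
  if (any(labels < 0)) stopf("labels must be non-negative (0 = background)")
  structure(list(labels = labels, spacing = spacing), class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("Labeled volume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g, %d label(s)\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              length(setdiff(unique(as.vector(x$labels)), 0))))
  invisible(x)
}

#' Measure 3D shape descriptors of every label
#'
#' Per label: the volume is the voxel count times the voxel volume; the
#' surface is extracted as an iso-surface of the (lightly smoothed) binary
#' mask at level 0.5 by marching tetrahedra, and its area gives `S`, hence
#' `p3D = S / V^(2/3)`. The inscribed-sphere fraction `f_R` comes from the
#' exact Euclidean distance transform of the mask. Masks are zero-padded, so
#' labels touching the array border are closed off; such labels are flagged
#' `boundary_clipped`.
#'
#' The mask is smoothed with a small Gaussian (`smooth_sigma` voxels) before
#' iso-surfacing: on raw binary data the midpoint iso-surface overestimates
#' areas by tens of percent (staircase bias), while heavy smoothing rounds
#' off polyhedral edges and underestimates them. The default 0.7 voxels
#' balances the two, keeping `p3D` within about 2% for both spherical and
#' polyhedral cells at 30+ voxels per diameter. Use `smooth_sigma = 0` for
#' exactly axis-aligned rectilinear objects.
#'
#' @param vol a [labeled_volume()].
#' @param min_voxels labels smaller than this are skipped with a warning.
#' @param smooth_sigma Gaussian pre-smoothing in voxel units (0 disables).
#' @param f_R also compute the inscribed-sphere fraction.
#' @return data frame: `label`, `n_voxels`, `V`, `S`, `p3D`,
#'   (`f_R`,) `boundary_clipped`.
#' @export
measure_labels_3d <- function(vol, min_voxels = 32, smooth_sigma = 0.7,
                              f_R = FALSE) {
  stopifnot(inherits(vol, "labeled_volume"))
  labs <- sort(setdiff(unique(as.vector(vol$labels)), 0))
  if (!length(labs)) stopf("volume contains no nonzero labels")
  d <- dim(vol$labels)
  sp <- vol$spacing
  vox_vol <- prod(sp)
  pad <- as.integer(ceiling(3 * smooth_sigma) + 1)
  skipped <- 0
  rows <- list()
  for (lb in labs) {
    idx <- which(vol$labels == lb, arr.ind = TRUE)
    nvox <- nrow(idx)
    if (nvox < min_voxels) {
      skipped <- skipped + 1
      next
    }
    lo <- apply(idx, 2, min)
    hi <- apply(idx, 2, max)
    boundary <- any(lo == 1) || any(hi == d)
    nb <- hi - lo + 1 + 2 * pad
    mask <- array(0, nb)
    mask[cbind(idx[, 1] - lo[1] + 1 + pad,
               idx[, 2] - lo[2] + 1 + pad,
               idx[, 3] - lo[3] + 1 + pad)] <- 1
    field <- if (smooth_sigma > 0) {
      cpp_gauss_smooth(as.vector(mask), dim(mask), rep(smooth_sigma, 3))
    } else {
      mask
    }
    S <- cpp_mt_area(as.vector(field), dim(mask), sp, 0.5)
    V <- nvox * vox_vol
    row <- data.frame(label = lb, n_voxels = nvox, V = V, S = S,
                      p3D = S / V^(2 / 3), boundary_clipped = boundary)
    if (f_R) {
      edt <- cpp_edt_sq(as.vector(mask > 0), dim(mask), sp)
      r <- sqrt(max(edt))
      row$f_R <- min(1, (4 / 3) * pi * r^3 / V)
    }
    rows[[length(rows) + 1]] <- row
  }
  if (skipped > 0) warnf("skipped %d label(s) smaller than %d voxels", skipped, min_voxels)
  if (!length(rows)) stopf("no label passed the size threshold")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Slice a labeled volume into 2D shape measurements
#'
#' Extracts one axis-aligned voxel plane and measures every connected label
#' region in it: the outline is traced as a sub-pixel iso-contour (marching
#' squares at level 0.5 on the lightly smoothed mask, so perimeters are not
#' inflated by pixel counting), giving perimeter `L`, area `a`,
#' `p2D = L/sqrt(a)` and the anisotropy index `m` in physical units.
#'
#' @param vol a [labeled_volume()].
#' @param axis slicing axis (1, 2 or 3).
#' @param index voxel index of the plane along that axis.
#' @param min_area regions with area below this (physical units) are dropped;
#'   the count is in attribute `n_dropped`.
#' @param smooth_sigma Gaussian pre-smoothing of each region mask, in pixels.
#' @return data frame: `label`, `component`, `L`, `a`, `p2D`, `m`; empty if
#'   the plane holds no labels.
#' @export
slice_labels <- function(vol, axis = 3, index, min_area = 0, smooth_sigma = 0.7) {
  stopifnot(inherits(vol, "labeled_volume"))
  d <- dim(vol$labels)
  if (!axis %in% 1:3) stopf("axis must be 1, 2 or 3")
  if (index < 1 || index > d[axis]) stopf("plane index %d outside the volume", index)
  sl <- switch(axis,
               vol$labels[index, , ],
               vol$labels[, index, ],
               vol$labels[, , index])
  sp2 <- vol$spacing[-axis]
  labs <- sort(setdiff(unique(as.vector(sl)), 0))
  pad <- as.integer(ceiling(3 * smooth_sigma) + 1)
  rows <- list()
  dropped <- 0
  for (lb in labs) {
    comp <- cpp_components2d(sl == lb)
    for (cc in seq_len(max(comp))) {
      idx <- which(comp == cc, arr.ind = TRUE)
      lo <- apply(idx, 2, min)
      hi <- apply(idx, 2, max)
      nb <- hi - lo + 1 + 2 * pad
      mask <- matrix(0, nb[1], nb[2])
      mask[cbind(idx[, 1] - lo[1] + 1 + pad, idx[, 2] - lo[2] + 1 + pad)] <- 1
      field <- if (smooth_sigma > 0) {
        matrix(cpp_gauss_smooth(as.vector(mask), dim(mask),
                                rep(smooth_sigma, 2)), nb[1], nb[2])
      } else {
        mask
      }
      ct <- cpp_ms_contours(field, 0.5)
      if (!length(ct)) next
      areas <- vapply(ct, function(pm) abs(cpp_polygon_stats(
        pm %*% diag(sp2))[["a"]]), 0)
      poly <- ct[[which.max(areas)]] %*% diag(sp2)
      st <- cpp_polygon_stats(poly)
      if (st[["a"]] <= min_area) {
        dropped <- dropped + 1
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        label = lb, component = cc, L = st[["L"]], a = st[["a"]],
        p2D = st[["L"]] / sqrt(st[["a"]]), m = st[["m"]])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(), component = integer(), L = double(),
               a = double(), p2D = double(), m = double())
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Rasterize a packing into a labeled volume
#'
#' Voxelizes the periodic Voronoi tessellation of a packing on a regular
#' grid (each voxel takes the label of the nearest center under the
#' minimum-image metric). Used to cross-validate the voxel measurement
#' pathway against exact polyhedral geometry.
#'
#' @param p a [packing()].
#' @param voxels_per_unit grid resolution (voxels per unit length).
#' @return a [labeled_volume()] with isotropic spacing `1/voxels_per_unit`.
#' @export
voxelize_packing <- function(p, voxels_per_unit = 16) {
  stopifnot(inherits(p, "packing"))
  dims <- as.integer(round(p$box * voxels_per_unit))
  labs <- cpp_voxelize(p$centers, p$box, dims)
  labeled_volume(array(labs, dims), spacing = p$box / dims)
}

#' Write / read a labeled volume as plain text
#'
#' Portable text serialization (no binary image formats required): a CSV of
#' the nonzero voxels (columns `i`, `j`, `k`, `label`) with a JSON sidecar
#' carrying dimensions and voxel spacing.
#'
#' @param vol a [labeled_volume()].
#' @param path CSV file path (sidecar at `<path>.json`).
#' @return `write_labeled_volume` returns `path` invisibly;
#'   `read_labeled_volume` the reconstructed volume.
#' @export
write_labeled_volume <- function(vol, path) {
  stopifnot(inherits(vol, "labeled_volume"))
  idx <- which(vol$labels != 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
                   label = vol$labels[idx])
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(dims = dim(vol$labels), spacing = vol$spacing),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_labeled_volume
#' @export
read_labeled_volume <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stopf("missing volume sidecar %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- utils::read.csv(path)
  labs <- array(0L, unlist(meta$dims))
  labs[cbind(df$i, df$j, df$k)] <- as.integer(df$label)
  labeled_volume(labs, unlist(meta$spacing))
}
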