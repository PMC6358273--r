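#' Random slicing plane through a packing
#'
#' Draws an isotropically oriented plane: the unit normal is uniform on the
#' sphere and the offset is uniform over the range of positions at which the
#' plane meets the box. Uses the current RNG state, so wrap the call in
#' `set.seed()` for reproducibility.
#'
#' @param box box lengths (length-3) or a [packing()].
#' @return list of class `"slice_plane"` with unit `normal` and `offset`
#'   (signed distance of the plane from the origin along the normal).
#' @export
random_plane <- function(box) {
  if (inherits(box, "packing")) box <- box$box
  n <- stats::rnorm(3)
  n <- n / sqrt(sum(n^2))
  sup <- box_support(box, n)
  structure(list(normal = n, offset = stats::runif(1, sup[1], sup[2])),
            class = "slice_plane")
}

#' @export
print.slice_plane <- function(x, ...) {
  cat(sprintf("Slice plane: normal (%.3f, %.3f, %.3f), offset %.4f\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

#' Slice a packing with a plane into 2D cross-section polygons
#'
#' Intersects every periodic image of every Voronoi cell with an
#' infinitesimally thin plane, yielding exact convex polygons in in-plane
#' coordinates, and computes the 2D descriptors: perimeter `L`, area `a`,
#' shape index `p2D = L/sqrt(a)`, and anisotropy index `m`.
#'
#' Two sampling rules are available:
#' * `boundary = "centroid"` (default): a cross-section is kept, whole, iff
#'   its area centroid falls inside the box cross-section (associated-point
#'   rule). This is unbiased and produces no boundary-truncated fragments; it
#'   is what reference distributions are built from.
#' * `boundary = "clip"`: polygons are clipped to the box cross-section so
#'   that they tile it exactly (their areas sum to the section area);
#'   fragments cut by the section boundary are flagged in column `clipped`.
#'
#' A cell cut more than once by the plane (through periodic wrapping)
#' contributes each piece separately, as an image would show.
#'
#' @param p a [packing()].
#' @param plane a `"slice_plane"` (or list with `normal`, `offset`).
#' @param boundary sampling rule, see above.
#' @param min_area_epsilon numerically degenerate slivers below this area are
#'   dropped (default `1e-12` times the mean cross-section area); the count
#'   is reported in attribute `n_dropped`.
#' @param keep_polygons attach the polygon vertex matrices as attribute
#'   `polygons`.
#' @param thickness optical-section thickness. Reserved for finite-thickness
#'   extensions; only infinitesimally thin sections (`0`) are implemented.
#' @return data frame with columns `cell_id`, `L`, `a`, `p2D`, `m`,
#'   `clipped`; empty if the plane misses the box.
#' @examples
#' p <- packing(matrix(0.5, 1, 3), box = 1)
#' slice_packing(p, list(normal = c(0, 0, 1), offset = 0.5))  # unit square
#' @export
slice_packing <- function(p, plane, boundary = c("centroid", "clip"),
                          min_area_epsilon = NULL, keep_polygons = FALSE,
                          thickness = 0) {
  stopifnot(inherits(p, "packing"))
  if (thickness != 0) {
    stopf("only infinitesimally thin sections (thickness = 0) are implemented")
  }
  boundary <- match.arg(boundary)
  normal <- plane$normal / sqrt(sum(plane$normal^2))
  sup <- box_support(p$box, normal)
  if (plane$offset < sup[1] || plane$offset > sup[2]) {
    out <- data.frame(cell_id = integer(), L = double(), a = double(),
                      p2D = double(), m = double(), clipped = logical())
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  mean_a <- (prod(p$box) / nrow(p$centers))^(2 / 3)
  eps <- min_area_epsilon %||% (1e-12 * mean_a)
  res <- cpp_slice_packing(p$centers, p$box, normal, plane$offset,
                           if (boundary == "centroid") 0L else 1L,
                           eps, keep_polygons)
  out <- data.frame(cell_id = as.integer(res$cell_id), L = res$L, a = res$a,
                    p2D = res$p2D, m = res$m, clipped = res$clipped > 0)
  if (res$n_dropped > 0) {
    message(sprintf("slice_packing: dropped %d degenerate sliver(s)", res$n_dropped))
  }
  attr(out, "n_dropped") <- res$n_dropped
  if (keep_polygons) attr(out, "polygons") <- res$polygons
  out
}

#' 2D shape index
#'
#' `p2D = L / sqrt(a)`: perimeter over the square root of area. Dimensionless
#' and scale invariant, with infimum `2*sqrt(pi)` (about 3.545) attained by
#' the circle.
#'
#' @param L perimeter(s), positive.
#' @param a area(s), positive.
#' @return numeric vector of shape indices.
#' @examples
#' shape_index_2d(2 * pi, pi)  # circle: 2*sqrt(pi)
#' @export
shape_index_2d <- function(L, a) {
  if (any(!is.finite(L)) || any(!is.finite(a)) || any(L <= 0) || any(a <= 0)) {
    stopf("perimeter and area must be positive and finite")
  }
  L / sqrt(a)
}

#' Anisotropy index of a polygon
#'
#' The central second-area-moment tensor
#' \deqn{G = \int_{area} v \otimes v \, dx\,dy,}
#' with `v` the offset from the area centroid, is integrated exactly over the
#' polygon (Green's theorem, closed form over edges). The anisotropy index is
#' the difference of the eigenvalues of `G` over their sum: 0 for shapes with
#' 3-fold or higher rotational symmetry, approaching 1 for degenerate slivers.
#'
#' @param polygon an `n` x 2 matrix of vertices (either orientation).
#' @return scalar `m` in \[0, 1).
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' anisotropy_index(sq)  # 0 by symmetry
#' @export
anisotropy_index <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3) stopf("polygon needs at least 3 vertices")
  st <- cpp_polygon_stats(polygon)
  if (st[["a"]] <= 0) stopf("degenerate polygon: zero area")
  st[["m"]]
}
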