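#' Periodic Voronoi tessellation of a packing
#'
#' Divides the periodic box into convex polyhedral cells, one per center, by
#' incremental half-space clipping against the perpendicular bisector planes
#' of the 27 periodic images of all other centers (processed nearest-first
#' with the standard closure bound). The cells tile the box exactly.
#'
#' @param p a [packing()].
#' @return A list of class `"cell_polyhedra"`; each element is a
#'   `"cell_polyhedron"` with `cell_id`, `vertices` (V x 3), `faces` (list of
#'   vertex-index rings, outward orientation), `neighbor_ids` (cell sharing
#'   each face), `face_areas`, `face_generators`, `V` and `S`.
#' @examples
#' cells <- periodic_voronoi(packing(matrix(0.5, 1, 3), box = 1))
#' cells[[1]]$V  # the unit cube
#' @export
periodic_voronoi <- function(p) {
  stopifnot(inherits(p, "packing"))
  cells <- cpp_voronoi(p$centers, p$box)
  cells <- lapply(cells, structure, class = "cell_polyhedron")
  structure(cells, class = "cell_polyhedra", box = p$box)
}

#' @export
print.cell_polyhedron <- function(x, ...) {
  cat(sprintf(
    "Convex cell %d: %d vertices, %d faces, V = %.4f, S = %.4f, p3D = %.4f\n",
    x$cell_id, nrow(x$vertices), length(x$faces), x$V, x$S, x$S / x$V^(2 / 3)))
  invisible(x)
}

#' @export
print.cell_polyhedra <- function(x, ...) {
  cat(sprintf("Voronoi tessellation: %d cells, total volume %.6g\n",
              length(x), sum(vapply(x, `[[`, 0, "V"))))
  invisible(x)
}

# shared validation: watertightness (every edge in exactly two faces)
check_watertight <- function(poly) {
  edges <- list()
  for (f in poly$faces) {
    n <- length(f)
    for (k in seq_len(n)) {
      e <- sort(c(f[k], f[k %% n + 1]))
      key <- paste(e, collapse = "-")
      edges[[key]] <- (edges[[key]] %||% 0) + 1
    }
  }
  if (length(edges) && !all(unlist(edges) == 2)) {
    stopf("polyhedron is not watertight: %d edge(s) not shared by exactly 2 faces",
          sum(unlist(edges) != 2))
  }
  invisible(TRUE)
}

#' 3D shape descriptors of a convex polyhedral cell
#'
#' Computes the volume `V` (divergence-theorem sum over fan-triangulated
#' faces), surface area `S`, and the dimensionless 3D shape index
#' `p3D = S / V^(2/3)`. `p3D` is scale invariant and bounded below by the
#' sphere value `(36*pi)^(1/3)` (about 4.836).
#'
#' @param poly a `"cell_polyhedron"` (from [periodic_voronoi()]) or any list
#'   with `vertices` and `faces` describing a watertight convex polyhedron
#'   with outward-oriented faces.
#' @param f_R if `TRUE`, also compute the inscribed-sphere volume fraction
#'   via [inscribed_sphere_fraction()].
#' @return A list of class `"cell_geometry_3d"` with `V`, `S`, `p3D` and
#'   optionally `f_R`.
#' @examples
#' cells <- periodic_voronoi(packing(matrix(0.5, 1, 3), box = 1))
#' measure_cell(cells[[1]])  # V = 1, S = 6, p3D = 6
#' @export
measure_cell <- function(poly, f_R = FALSE) {
  check_watertight(poly)
  v <- poly$vertices
  V <- 0
  S <- 0
  for (f in poly$faces) {
    o <- v[f[1], ]
    for (k in seq(2, length(f) - 1)) {
      a <- v[f[k], ]
      b <- v[f[k + 1], ]
      V <- V + sum(o * xprod(a, b))
      S <- S + 0.5 * sqrt(sum(xprod(a - o, b - o)^2))
    }
  }
  V <- abs(V) / 6
  out <- list(V = V, S = S, p3D = S / V^(2 / 3))
  if (f_R) out$f_R <- inscribed_sphere_fraction(poly)
  structure(out, class = "cell_geometry_3d")
}

#' @export
print.cell_geometry_3d <- function(x, ...) {
  cat(sprintf("V = %.5g, S = %.5g, p3D = %.5g%s\n", x$V, x$S, x$p3D,
              if (!is.null(x$f_R)) sprintf(", f_R = %.4f", x$f_R) else ""))
  invisible(x)
}

#' Measure every cell of a tessellation
#'
#' @param cells a `"cell_polyhedra"` list from [periodic_voronoi()].
#' @param f_R also compute the inscribed-sphere fraction (slower).
#' @return data frame with columns `cell_id`, `V`, `S`, `p3D` (and `f_R`).
#' @export
measure_cells <- function(cells, f_R = FALSE) {
  stopifnot(inherits(cells, "cell_polyhedra"))
  out <- data.frame(
    cell_id = vapply(cells, `[[`, 0, "cell_id"),
    V = vapply(cells, `[[`, 0, "V"),
    S = vapply(cells, `[[`, 0, "S")
  )
  out$p3D <- out$S / out$V^(2 / 3)
  if (f_R) out$f_R <- vapply(cells, inscribed_sphere_fraction, 0)
  out
}

xprod <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# outward unit normal and offset (n . x = d) of each face
face_planes <- function(poly) {
  v <- poly$vertices
  t(vapply(poly$faces, function(f) {
    # Newell's method for robustness against near-collinear leading vertices
    n <- c(0, 0, 0)
    m <- length(f)
    for (k in seq_len(m)) {
      a <- v[f[k], ]
      b <- v[f[k %% m + 1], ]
      n <- n + c((a[2] - b[2]) * (a[3] + b[3]),
                 (a[3] - b[3]) * (a[1] + b[1]),
                 (a[1] - b[1]) * (a[2] + b[2]))
    }
    n <- n / sqrt(sum(n^2))
    c(n, sum(n * v[f[1], ]))
  }, numeric(4)))
}

#' Inscribed-sphere volume fraction of a convex cell
#'
#' The largest sphere that fits inside the cell is found as the Chebyshev
#' center of its face half-spaces (maximize `r` subject to the distance to
#' every face being at least `r`), solved exactly. The descriptor
#' `f_R = (4/3) pi r^3 / V` is an alternative 3D compactness measure in
#' (0, 1]: `pi/6` for a cube, 1 only for a sphere.
#'
#' @param poly a `"cell_polyhedron"` or compatible list.
#' @return the scalar `f_R`.
#' @examples
#' cells <- periodic_voronoi(packing(matrix(0.5, 1, 3), box = 1))
#' inscribed_sphere_fraction(cells[[1]])  # pi/6 for the cube
#' @export
inscribed_sphere_fraction <- function(poly) {
  pl <- face_planes(poly)
  ch <- cpp_chebyshev(pl[, 1:3, drop = FALSE], pl[, 4])
  V <- if (!is.null(poly$V)) poly$V else measure_cell(poly)$V
  fr <- (4 / 3) * pi * ch[["r"]]^3 / V
  min(fr, 1)
}
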