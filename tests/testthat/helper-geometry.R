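# geometric constructors and an independent brute-force Voronoi oracle

# orient all faces of a convex polyhedron outward (vertex list + face rings)
make_poly <- function(vertices, faces) {
  ctr <- colMeans(vertices)
  faces <- lapply(faces, function(f) {
    n <- cellslice:::xprod(vertices[f[2], ] - vertices[f[1], ],
                           vertices[f[3], ] - vertices[f[1], ])
    if (sum(n * (colMeans(vertices[f, , drop = FALSE]) - ctr)) < 0) rev(f) else f
  })
  list(vertices = vertices, faces = faces)
}

regular_tetrahedron <- function(edge = 1) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    (edge / (2 * sqrt(2)))
  make_poly(v, list(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2)))
}

# geodesic sphere: subdivided icosahedron projected to the unit sphere
icosphere <- function(level = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(level)) {
    nv <- v
    nf <- NULL
    key <- new.env()
    mid <- function(a, b) {
      kk <- paste(sort(c(a, b)), collapse = "-")
      if (!is.null(key[[kk]])) return(key[[kk]])
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      nv <<- rbind(nv, m)
      key[[kk]] <- nrow(nv)
      nrow(nv)
    }
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c2 <- f[t, 3]
      ab <- mid(a, b); bc <- mid(b, c2); ca <- mid(c2, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c2, ca, bc), c(ab, bc, ca))
    }
    v <- nv
    f <- nf
  }
  make_poly(v, lapply(seq_len(nrow(f)), function(t) f[t, ]))
}

# Brute-force periodic Voronoi cell oracle, algorithmically independent of
# the package's incremental clipping: enumerate all triples of bisector
# planes, solve for candidate vertices, keep those inside every half-space,
# then group vertices by plane to rebuild faces and integrate V and S.
brute_voronoi_cell <- function(centers, box, i, cutoff = NULL) {
  n_cells <- nrow(centers)
  cutoff <- if (is.null(cutoff)) 3.2 * (prod(box) / n_cells)^(1 / 3) else cutoff
  ci <- centers[i, ]
  planes <- NULL
  for (j in seq_len(n_cells)) {
    for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
      if (j == i && ox == 0 && oy == 0 && oz == 0) next
      pj <- centers[j, ] + c(ox, oy, oz) * box
      d <- sqrt(sum((pj - ci)^2))
      if (d < cutoff) {
        nrm <- (pj - ci) / d
        planes <- rbind(planes, c(nrm, sum(nrm * (ci + pj) / 2)))
      }
    }
  }
  np <- nrow(planes)
  verts <- NULL
  vplanes <- list()
  for (a in 1:(np - 2)) for (b in (a + 1):(np - 1)) for (cc in (b + 1):np) {
    A <- planes[c(a, b, cc), 1:3]
    if (abs(det(A)) < 1e-10) next
    x <- solve(A, planes[c(a, b, cc), 4])
    s <- planes[, 1:3] %*% x - planes[, 4]
    if (max(s) < 1e-7) {
      if (!is.null(verts) &&
          any(colSums((t(verts) - x)^2) < 1e-14)) next
      verts <- rbind(verts, as.vector(x))
      vplanes[[nrow(verts)]] <- which(abs(s) < 1e-7)
    }
  }
  # faces: vertices on each plane, ordered by angle
  V <- 0
  S <- 0
  for (pidx in seq_len(np)) {
    on <- which(vapply(vplanes, function(vp) pidx %in% vp, TRUE))
    if (length(on) < 3) next
    nrm <- planes[pidx, 1:3]
    e1 <- cellslice:::xprod(nrm, if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- cellslice:::xprod(nrm, e1)
    ctr <- colMeans(verts[on, , drop = FALSE])
    ang <- apply(verts[on, , drop = FALSE], 1, function(p) {
      r <- p - ctr
      atan2(sum(r * e2), sum(r * e1))
    })
    ring <- verts[on[order(ang)], , drop = FALSE]
    m <- nrow(ring)
    for (k in seq_len(m)) {
      a3 <- ring[k, ]
      b3 <- ring[k %% m + 1, ]
      V <- V + abs(sum((a3 - ci) * cellslice:::xprod(b3 - ci, ctr - ci))) / 6
      S <- S + 0.5 * sqrt(sum(cellslice:::xprod(a3 - ctr, b3 - ctr)^2))
    }
  }
  list(V = V, S = S)
}

# independent 2D convex polygon clip (Sutherland-Hodgman) for oracle checks
clip_polygon_2d <- function(poly, a, b, cval) {
  # keep a*x + b*y <= cval
  out <- NULL
  n <- nrow(poly)
  for (k in seq_len(n)) {
    p <- poly[k, ]
    q <- poly[k %% n + 1, ]
    sp <- a * p[1] + b * p[2] - cval
    sq <- a * q[1] + b * q[2] - cval
    if (sp <= 0) out <- rbind(out, p)
    if (sp * sq < 0) out <- rbind(out, p + (sp / (sp - sq)) * (q - p))
  }
  out
}

# exact area of the box cross-section cut by a plane (oracle for tiling)
box_section_area <- function(box, normal, offset) {
  n <- normal / sqrt(sum(normal^2))
  e1 <- cellslice:::xprod(n, if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cellslice:::xprod(n, e1)
  org <- n * offset
  big <- 4 * max(box)
  poly <- rbind(c(-big, -big), c(big, -big), c(big, big), c(-big, big))
  for (d in 1:3) {
    # 0 <= org[d] + x e1[d] + y e2[d] <= box[d]
    poly <- clip_polygon_2d(poly, -e1[d], -e2[d], org[d])
    if (is.null(poly) || nrow(poly) < 3) return(0)
    poly <- clip_polygon_2d(poly, e1[d], e2[d], box[d] - org[d])
    if (is.null(poly) || nrow(poly) < 3) return(0)
  }
  n2 <- nrow(poly)
  abs(sum(poly[, 1] * poly[c(2:n2, 1), 2] - poly[c(2:n2, 1), 1] * poly[, 2])) / 2
}
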