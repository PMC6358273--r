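#' Create a periodic cell-center packing
#'
#' A packing is the state of the 3D Voronoi model: `N` cell centers in a
#' periodic box. Lengths are dimensionless; by convention the box volume
#' equals the total target cell volume, so that the mean cell volume is 1 for
#' homogeneous unit targets.
#'
#' @param centers numeric matrix (`N` x 3) of cell-center coordinates.
#'   Centers are wrapped into the half-open box.
#' @param box positive lengths of the periodic box (length-3, or a scalar for
#'   a cubic box).
#' @param seed optional integer seed recorded as provenance.
#' @param targets optional [model_targets()] object.
#' @return An object of class `"packing"` with elements `centers`, `box`,
#'   `seed`, `targets`.
#' @examples
#' p <- packing(matrix(runif(24), ncol = 3), box = 2)
#' p
#' @export
packing <- function(centers, box, seed = NULL, targets = NULL) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 3) stopf("centers must be an N x 3 matrix")
  if (nrow(centers) < 1) stopf("a packing needs at least one center")
  storage.mode(centers) <- "double"
  if (length(box) == 1) box <- rep(box, 3)
  box <- as.double(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    stopf("box must be 3 positive lengths")
  }
  centers <- sweep(centers, 2, box, `%%`)
  if (!is.null(targets)) {
    stopifnot(inherits(targets, "model_targets"))
    if (length(targets$V0) != nrow(centers)) {
      stopf("targets are for %d cells but packing has %d centers",
            length(targets$V0), nrow(centers))
    }
    if (abs(prod(box) - sum(targets$V0)) > 1e-6 * prod(box)) {
      stopf("box volume (%g) must equal total target volume (%g)",
            prod(box), sum(targets$V0))
    }
  }
  structure(list(centers = centers, box = box, seed = seed, targets = targets),
            class = "packing")
}

#' @export
print.packing <- function(x, ...) {
  cat(sprintf("Periodic cell packing: %d cells, box %.4g x %.4g x %.4g\n",
              nrow(x$centers), x$box[1], x$box[2], x$box[3]))
  if (!is.null(x$targets)) {
    p0 <- x$targets$S0 / x$targets$V0^(2 / 3)
    cat(sprintf("  targets: p0_3D in [%.3f, %.3f], mean V0 = %.3f\n",
                min(p0), max(p0), mean(x$targets$V0)))
  }
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Write / read a packing as CSV with a JSON sidecar
#'
#' The centers go to `<path>` as plain CSV (columns `x`, `y`, `z`); the box,
#' seed and any model targets go to `<path>.json`.
#'
#' @param p a [packing()].
#' @param path CSV file path.
#' @return `write_packing` returns `path` invisibly; `read_packing` returns
#'   the reconstructed [packing()].
#' @export
write_packing <- function(p, path) {
  stopifnot(inherits(p, "packing"))
  df <- data.frame(x = p$centers[, 1], y = p$centers[, 2], z = p$centers[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(box = p$box, seed = p$seed)
  if (!is.null(p$targets)) {
    meta$targets <- list(S0 = p$targets$S0, V0 = p$targets$V0,
                         kS = p$targets$kS, kV = p$targets$kV)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_packing
#' @export
read_packing <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y", "z") %in% names(df))) {
    stopf("packing CSV must have columns x, y, z")
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stopf("missing packing sidecar %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  targets <- NULL
  if (!is.null(meta$targets)) {
    targets <- model_targets(S0 = meta$targets$S0, V0 = meta$targets$V0,
                             kS = meta$targets$kS, kV = meta$targets$kV)
  }
  packing(as.matrix(df[, c("x", "y", "z")]), box = meta$box,
          seed = meta$seed, targets = targets)
}
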