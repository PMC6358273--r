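# internal helpers

# Deterministic sub-seed derivation so nested stochastic stages (packings,
# slices, noise draws) are reproducible from one user seed.  Kept below 2^31.
subseed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 16807 + 1) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 1 && x == round(x)

# range of plane offsets for which a plane with this unit normal meets the box
box_support <- function(box, normal) {
  corners <- as.matrix(expand.grid(c(0, box[1]), c(0, box[2]), c(0, box[3])))
  pr <- corners %*% normal
  c(min(pr), max(pr))
}
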