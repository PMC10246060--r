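# Internal helpers.

# Run seeded code without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.unit <- function(v) v / sqrt(sum(v^2))

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Isotropic voxel spacings from an affine; errors if axes are not aligned with
# the world frame (the finite-volume stencil operates along grid axes).
.grid_spacing <- function(affine, require_axis_aligned = FALSE) {
  A <- affine[1:3, 1:3]
  h <- sqrt(colSums(A^2))
  if (require_axis_aligned) {
    Rg <- sweep(A, 2, h, "/")
    if (max(abs(Rg - diag(3))) > 1e-9)
      stop("grid axes must be aligned with world axes; resample first")
  }
  h
}

.same_grid <- function(a, b) {
  identical(gridShape(a), gridShape(b)) &&
    max(abs(gridAffine(a) - gridAffine(b))) < 1e-9
}
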