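# Volumetric data model: constructors, coordinate mapping, interpolation,
# vector-aware rigid transforms.

#' Construct a VolumeGrid
#'
#' @param values 3-D array (treated as 1 component) or 4-D array
#'   (nx, ny, nz, ncomp).
#' @param affine 4x4 voxel-index (0-based) to world-mm affine.
#' @return a [VolumeGrid].
#' @export
volumeGrid <- function(values, affine) {
  if (length(dim(values)) == 3L) dim(values) <- c(dim(values), 1L)
  new("VolumeGrid", values = values, affine = affine)
}

#' Construct a VectorField
#'
#' @param values 4-D array with 3 components on the last axis, world-frame
#'   components (V/m for fields).
#' @param affine 4x4 voxel-to-world affine.
#' @return a [VectorField].
#' @export
vectorField <- function(values, affine) {
  new("VectorField", values = values, affine = affine)
}

#' Axis-aligned affine with the grid centred on a world point
#'
#' Convenience affine builder: isotropic spacing, axes aligned with world RAS,
#' grid centre at `center`.
#'
#' @param shape integer length-3 voxel dimensions.
#' @param voxel_mm isotropic voxel edge length (mm).
#' @param center world-mm point at the grid centre.
#' @return 4x4 affine matrix.
#' @export
centeredAffine <- function(shape, voxel_mm, center = c(0, 0, 0)) {
  a <- diag(c(rep(voxel_mm, 3), 1))
  a[1:3, 4] <- center - voxel_mm * (shape - 1) / 2
  a
}

#' World coordinates of all voxel centres
#'
#' @param x a [VolumeGrid] (or subclass).
#' @return (nvox x 3) matrix in array linear order (first index fastest).
#' @export
voxelCenters <- function(x) {
  d <- gridShape(x)
  idx <- cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  )
  voxelToWorld(gridAffine(x), idx)
}

#' Map voxel indices to world coordinates (and back)
#'
#' `voxelToWorld` applies the affine to 0-based (possibly fractional) voxel
#' indices; `worldToVoxel` applies its inverse.
#'
#' @param affine 4x4 affine.
#' @param points n x 3 matrix.
#' @return n x 3 matrix.
#' @export
voxelToWorld <- function(affine, points) {
  points <- rbind(t(points), 1)
  t(affine %*% points)[, 1:3, drop = FALSE]
}

#' @rdname voxelToWorld
#' @export
worldToVoxel <- function(affine, points) {
  voxelToWorld(solve(affine), points)
}

# -- rigid transforms --------------------------------------------------------

#' Construct and manipulate rigid transforms
#'
#' `rigidTransform` validates a 4x4 homogeneous matrix (orthonormal rotation
#' block, det +1). `rotationTransform` builds a rotation of `angle_deg`
#' degrees about a world axis through `center`; `translationTransform` a pure
#' translation. `composeTransforms(T2, T1)` is "T1 then T2";
#' `invertTransform` the exact rigid inverse.
#'
#' @param m 4x4 matrix.
#' @return a [RigidTransform].
#' @export
rigidTransform <- function(m) new("RigidTransform", matrix = unname(m))

#' @rdname rigidTransform
#' @param axis world axis, one of "x", "y", "z", or a length-3 vector.
#' @param angle_deg rotation angle in degrees (right-handed).
#' @param center world point the rotation axis passes through.
#' @export
rotationTransform <- function(axis, angle_deg, center = c(0, 0, 0)) {
  if (is.character(axis))
    axis <- switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
                   stop("unknown axis name"))
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- center - R %*% center
  rigidTransform(m)
}

#' @rdname rigidTransform
#' @param offset translation vector (mm).
#' @export
translationTransform <- function(offset) {
  m <- diag(4)
  m[1:3, 4] <- offset
  rigidTransform(m)
}

#' @rdname rigidTransform
#' @param T2,T1,T rigid transforms.
#' @export
composeTransforms <- function(T2, T1) {
  rigidTransform(transformMatrix(T2) %*% transformMatrix(T1))
}

#' @rdname rigidTransform
#' @export
invertTransform <- function(T) {
  m <- transformMatrix(T)
  R <- m[1:3, 1:3]
  inv <- diag(4)
  inv[1:3, 1:3] <- t(R)
  inv[1:3, 4] <- -t(R) %*% m[1:3, 4]
  rigidTransform(inv)
}

#' @rdname rigidTransform
#' @param points n x 3 matrix of world points.
#' @export
applyTransform <- function(T, points) {
  voxelToWorld(transformMatrix(T), points)
}

.as_rigid <- function(T) {
  if (is.matrix(T)) T <- rigidTransform(T)
  if (!is(T, "RigidTransform"))
    stop("transform must be a RigidTransform or a rigid 4x4 matrix")
  T
}

# -- interpolation -----------------------------------------------------------

.interp_flag <- function(interp) {
  interp <- match.arg(interp, c("trilinear", "nearest"))
  interp == "nearest"
}

#' Sample a volume at arbitrary world points
#'
#' One record per point (all components); serves mesh vertices and streamline
#' points identically. Out-of-bounds samples return zero records.
#'
#' @param vol a [VolumeGrid] (or subclass).
#' @param points n x 3 matrix of world-mm points.
#' @param interp "trilinear" (default for fields) or "nearest" (masks).
#' @return n x ncomp numeric matrix.
#' @export
sampleAtPoints <- function(vol, points, interp = c("trilinear", "nearest")) {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (any(!is.finite(points))) stop("sample points must be finite")
  vox <- worldToVoxel(gridAffine(vol), points)
  cpp_sample_volume(gridValues(vol), dim(gridValues(vol)), vox,
                    .interp_flag(interp))
}

#' Resample a volume onto a target grid
#'
#' Values are interpolated from `vol` at the world positions of the target
#' voxel centres; positions outside `vol` yield zero records.
#'
#' @param vol a [VolumeGrid] (or subclass).
#' @param target_shape integer length-3 target dimensions.
#' @param target_affine 4x4 target voxel-to-world affine.
#' @param interp "trilinear" or "nearest".
#' @return a [VolumeGrid] on the target grid ([VectorField] if `vol` is one).
#' @export
resampleToGrid <- function(vol, target_shape, target_affine,
                           interp = c("trilinear", "nearest")) {
  target_shape <- as.integer(target_shape)
  if (abs(det(target_affine)) < 1e-12) stop("target affine must be invertible")
  tmp <- volumeGrid(array(0, c(target_shape, 1L)), target_affine)
  pts <- voxelCenters(tmp)
  rec <- sampleAtPoints(vol, pts, interp)
  vals <- array(rec, c(target_shape, nComponents(vol)))
  if (is(vol, "VectorField")) vectorField(vals, target_affine)
  else volumeGrid(vals, target_affine)
}

#' Rigidly transform a vector field, rotating voxel vectors
#'
#' Moves a vector field by a rigid transform `T`: each output voxel takes the
#' input value sampled at the pre-image of its world position under `T`, and
#' the sampled 3-vector is additionally rotated by the rotation block of `T`.
#' Consistent rotation of the per-voxel vector direction is what
#' distinguishes this from scalar resampling. The output grid equals the
#' input grid; out-of-bounds samples are zero vectors.
#'
#' @param field a [VectorField].
#' @param T a [RigidTransform] (or rigid 4x4 matrix); non-rigid input is
#'   rejected.
#' @param interp "trilinear" or "nearest".
#' @return a [VectorField] on the same grid.
#' @export
transformVectorVolume <- function(field, T, interp = c("trilinear", "nearest")) {
  if (!is(field, "VectorField")) stop("field must be a VectorField")
  T <- .as_rigid(T)
  m <- transformMatrix(T)
  R <- m[1:3, 1:3]
  pts <- voxelCenters(field)
  src <- applyTransform(invertTransform(T), pts)
  vox <- worldToVoxel(gridAffine(field), src)
  rec <- cpp_sample_volume(gridValues(field), dim(gridValues(field)), vox,
                           .interp_flag(interp))
  out <- rec %*% t(R)
  vectorField(array(out, c(gridShape(field), 3L)), gridAffine(field))
}

#' Per-voxel Euclidean magnitude of a vector field
#'
#' @param field a [VectorField].
#' @return a scalar [VolumeGrid] on the same grid.
#' @export
fieldMagnitude <- function(field) {
  v <- gridValues(field)
  mag <- sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2)
  volumeGrid(array(mag, c(gridShape(field), 1L)), gridAffine(field))
}

# -- projection onto meshes and streamlines ----------------------------------

#' Project field values onto a mesh or streamlines
#'
#' Samples a volume at mesh vertices (filling the per-vertex scalar channel)
#' or at every streamline point. For a 3-component volume the Euclidean
#' magnitude is projected; for a scalar volume the value itself.
#'
#' @param vol a [VolumeGrid] or [VectorField].
#' @param mesh a [TriangleMesh].
#' @param interp interpolation mode.
#' @return `projectOntoMesh`: the mesh with its scalar channel set;
#'   `projectOntoStreamlines`: a list of per-point numeric vectors.
#' @export
projectOntoMesh <- function(vol, mesh, interp = c("trilinear", "nearest")) {
  rec <- sampleAtPoints(vol, meshVertices(mesh), interp)
  val <- if (ncol(rec) == 3L) sqrt(rowSums(rec^2)) else rec[, 1]
  new("TriangleMesh", vertices = mesh@vertices, faces = mesh@faces, scalar = val)
}

#' @rdname projectOntoMesh
#' @param streamlines a [Streamlines] object.
#' @export
projectOntoStreamlines <- function(vol, streamlines,
                                   interp = c("trilinear", "nearest")) {
  lapply(streamlines@lines, function(l) {
    rec <- sampleAtPoints(vol, l, interp)
    if (ncol(rec) == 3L) sqrt(rowSums(rec^2)) else rec[, 1]
  })
}
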