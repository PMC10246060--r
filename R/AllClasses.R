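#' @import methods
#' @importFrom stats rnorm runif sd pt qt setNames
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib tmsfield, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Core volumetric containers
# ---------------------------------------------------------------------------

#' VolumeGrid: a regular voxel grid with a world affine
#'
#' A `VolumeGrid` holds one fixed-length record per voxel (1 scalar, 3-vector
#' or 6 symmetric-tensor components) on a regular grid, together with a 4x4
#' homogeneous affine mapping 0-based voxel indices (i,j,k) to world RAS
#' millimetres. Vector and tensor components are stored in the world frame.
#'
#' @slot values 4-D array, dimensions (nx, ny, nz, ncomp).
#' @slot affine 4x4 numeric matrix, invertible; voxel index -> world mm.
#' @export
setClass("VolumeGrid", representation(values = "array", affine = "matrix"))

setValidity("VolumeGrid", function(object) {
  d <- dim(object@values)
  if (length(d) != 4L) return("values must be a 4-D array (nx, ny, nz, ncomp)")
  if (any(d <= 0L)) return("all dimensions must be positive")
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
  if (abs(det(object@affine)) < 1e-12) return("affine must be invertible")
  if (!all(object@affine[4, ] == c(0, 0, 0, 1))) return("affine last row must be (0,0,0,1)")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    return("all voxel values must be finite")
  TRUE
})

#' VectorField: a 3-component VolumeGrid
#'
#' Serves both dA/dt and E-fields (units V/m); components are expressed along
#' world axes so that rigid rotations act on stored components directly.
#'
#' @export
setClass("VectorField", contains = "VolumeGrid")

setValidity("VectorField", function(object) {
  if (dim(object@values)[4] != 3L) return("VectorField must have 3 components per voxel")
  TRUE
})

#' ConductivityVolume: per-voxel symmetric conductivity tensors with head mask
#'
#' Six tensor components per voxel in the order xx, yy, zz, xy, xz, yz (S/m).
#' Tensors are symmetric positive semi-definite inside the head mask and
#' exactly zero outside it.
#'
#' @slot mask logical 3-D array, TRUE inside the head.
#' @export
setClass("ConductivityVolume", contains = "VolumeGrid",
         representation(mask = "array"))

setValidity("ConductivityVolume", function(object) {
  d <- dim(object@values)
  if (d[4] != 6L) return("ConductivityVolume must have 6 tensor components per voxel")
  if (!identical(dim(object@mask), d[1:3])) return("mask shape must match grid shape")
  if (!is.logical(object@mask)) return("mask must be logical")
  out <- !object@mask
  if (any(abs(matrix(object@values, ncol = 6L)[as.vector(out), ]) > 0))
    return("tensors must be exactly zero outside the mask")
  TRUE
})

#' ScalarPotential: the induced scalar potential on the head mask
#'
#' Zero-mean gauge over the mask; exactly zero outside it. Carries the solver
#' diagnostics (final relative residual and iteration count).
#'
#' @slot mask logical 3-D array (the head mask the solve used).
#' @slot residual final relative residual of the converged solve.
#' @slot iterations number of Krylov iterations used.
#' @export
setClass("ScalarPotential", contains = "VolumeGrid",
         representation(mask = "array", residual = "numeric", iterations = "integer"))

# ---------------------------------------------------------------------------
# Geometry
# ---------------------------------------------------------------------------

#' RigidTransform: a rigid 4x4 homogeneous transform
#'
#' Rotation block orthonormal to 1e-9 with determinant +1; translation in mm.
#' @slot matrix 4x4 homogeneous matrix.
#' @export
setClass("RigidTransform", representation(matrix = "matrix"))

setValidity("RigidTransform", function(object) {
  m <- object@matrix
  if (!all(dim(m) == c(4L, 4L))) return("matrix must be 4x4")
  if (any(!is.finite(m))) return("matrix must be finite")
  if (!all(m[4, ] == c(0, 0, 0, 1))) return("last row must be (0,0,0,1)")
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation block is not orthonormal (R'R != I within 1e-9)")
  if (det(R) < 0) return("rotation block must have determinant +1 (no reflection)")
  TRUE
})

#' TriangleMesh: a triangulated surface in world mm
#'
#' @slot vertices n x 3 numeric matrix of world-mm points.
#' @slot faces m x 3 integer matrix of 1-based vertex indices.
#' @slot scalar optional per-vertex scalar channel (length 0 or n).
#' @export
setClass("TriangleMesh",
         representation(vertices = "matrix", faces = "matrix", scalar = "numeric"))

setValidity("TriangleMesh", function(object) {
  if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
  if (ncol(object@faces) != 3L) return("faces must be m x 3")
  f <- object@faces
  if (any(f < 1L) || any(f > nrow(object@vertices))) return("face index out of range")
  if (length(object@scalar) && length(object@scalar) != nrow(object@vertices))
    return("scalar channel length must equal vertex count")
  TRUE
})

#' Streamlines: an ordered set of polylines in world mm
#'
#' @slot lines list of k x 3 numeric matrices, each with >= 2 points.
#' @export
setClass("Streamlines", representation(lines = "list"))

setValidity("Streamlines", function(object) {
  for (l in object@lines) {
    if (!is.matrix(l) || ncol(l) != 3L || nrow(l) < 2L)
      return("every polyline must be a k x 3 matrix with k >= 2")
    if (any(!is.finite(l))) return("polyline coordinates must be finite")
  }
  TRUE
})

#' HeadGeometry: shells, centre and surface meshes of a synthetic head
#'
#' @slot scalp_mesh,gm_mesh closed icosphere meshes at the scalp and
#'   gray-matter radii.
#' @slot center world-mm head centre.
#' @slot outer_radius scalp radius (mm).
#' @slot shell_radii outer radii of the shells, strictly decreasing from
#'   `outer_radius`.
#' @slot shell_sigma isotropic conductivity of each shell (S/m).
#' @export
setClass("HeadGeometry",
         representation(scalp_mesh = "TriangleMesh", gm_mesh = "TriangleMesh",
                        center = "numeric", outer_radius = "numeric",
                        shell_radii = "numeric", shell_sigma = "numeric"))

setValidity("HeadGeometry", function(object) {
  r <- object@shell_radii
  if (length(object@center) != 3L) return("center must be length 3")
  if (r[1] != object@outer_radius) return("first shell radius must equal outer_radius")
  if (any(diff(r) >= 0)) return("shell radii must be strictly decreasing")
  if (length(object@shell_sigma) != length(r)) return("one conductivity per shell")
  if (any(object@shell_sigma < 0)) return("conductivities must be >= 0")
  TRUE
})

# ---------------------------------------------------------------------------
# Coil
# ---------------------------------------------------------------------------

#' CoilModel: a discretized coil winding
#'
#' Straight current segments in the coil frame (mm); the coil plane is z = 0,
#' -z faces the scalp and the handle points along +y. Circulation sign is
#' carried by segment orientation.
#'
#' @slot segments n x 6 matrix (start xyz, end xyz) in coil-frame mm.
#' @slot loop_id integer loop label per segment.
#' @slot didt coil current rate dI/dt (A/s).
#' @slot name coil name.
#' @export
setClass("CoilModel",
         representation(segments = "matrix", loop_id = "integer",
                        didt = "numeric", name = "character"))

setValidity("CoilModel", function(object) {
  s <- object@segments
  if (ncol(s) != 6L) return("segments must be n x 6 (start, end)")
  len <- sqrt(rowSums((s[, 4:6, drop = FALSE] - s[, 1:3, drop = FALSE])^2))
  if (any(len <= 0)) return("all segment lengths must be > 0")
  if (length(object@loop_id) != nrow(s)) return("one loop id per segment")
  for (id in unique(object@loop_id)) {
    seg <- s[object@loop_id == id, , drop = FALSE]
    gap <- max(sqrt(rowSums((seg[c(2:nrow(seg), 1L), 1:3, drop = FALSE] -
                             seg[, 4:6, drop = FALSE])^2)))
    if (gap > 1e-9) return(sprintf("loop %d does not close (gap %.3g mm)", id, gap))
  }
  TRUE
})

#' PlacementSet: sampled coil placements on a head
#'
#' @slot poses list of [RigidTransform] coil-to-world poses.
#' @slot site character EEG 10-10 site label per pose.
#' @slot direction integer handle-direction index per pose (0-based).
#' @slot seed the generation seed.
#' @export
setClass("PlacementSet",
         representation(poses = "list", site = "character",
                        direction = "integer", seed = "integer"))

setValidity("PlacementSet", function(object) {
  n <- length(object@poses)
  if (length(object@site) != n || length(object@direction) != n)
    return("site and direction must have one entry per pose")
  TRUE
})

# ---------------------------------------------------------------------------
# Surrogate
# ---------------------------------------------------------------------------

#' TrainedSurrogate: a trained volumetric E-field surrogate
#'
#' @slot params list of network weight matrices and biases.
#' @slot config the [surrogateConfig] used for training.
#' @slot norm per-channel input normalization statistics and the target scale.
#' @slot history per-epoch data.frame with columns epoch, loss, ne.
#' @export
setClass("TrainedSurrogate",
         representation(params = "list", config = "list", norm = "list",
                        history = "data.frame"))

setValidity("TrainedSurrogate", function(object) {
  if (!all(is.finite(object@norm$mean)) || !all(is.finite(object@norm$sd)))
    return("normalization statistics must be finite")
  if (nrow(object@history) != object@config$epochs)
    return("history length must equal the number of epochs")
  TRUE
})

# ---------------------------------------------------------------------------
# Streaming
# ---------------------------------------------------------------------------

#' IGTMessage: an OpenIGTLink-subset wire message
#'
#' @slot version protocol version (2).
#' @slot type_name "TRANSFORM" or "IMAGE".
#' @slot device_name device string (<= 20 ASCII chars).
#' @slot ts_sec,ts_nsec timestamp split into whole seconds and nanoseconds
#'   (each fits a 32-bit unsigned integer; together the 64-bit field).
#' @slot body raw body bytes.
#' @export
setClass("IGTMessage",
         representation(version = "integer", type_name = "character",
                        device_name = "character", ts_sec = "numeric",
                        ts_nsec = "numeric", body = "raw"))

setValidity("IGTMessage", function(object) {
  if (!object@type_name %in% c("TRANSFORM", "IMAGE"))
    return("unsupported type_name")
  if (nchar(object@type_name) > 12L) return("type_name exceeds 12 characters")
  if (nchar(object@device_name) > 20L) return("device_name exceeds 20 characters")
  if (object@ts_sec < 0 || object@ts_sec >= 2^32 || object@ts_nsec < 0 ||
      object@ts_nsec >= 2^32)
    return("timestamp halves must fit 32-bit unsigned integers")
  TRUE
})
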