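# Accessor generics for the volumetric containers. Slot access from user code
# is discouraged; these are the supported surface.

#' Grid accessors
#'
#' `gridShape` returns the voxel dimensions, `gridAffine` the 4x4 voxel-to-world
#' affine, `gridValues` the raw value array (nx, ny, nz, ncomp) and
#' `nComponents` the record length per voxel.
#'
#' @param x a [VolumeGrid] (or subclass).
#' @return see individual descriptions.
#' @aliases gridShape gridAffine gridValues nComponents
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname gridShape
#' @export
setGeneric("gridAffine", function(x) standardGeneric("gridAffine"))

#' @rdname gridShape
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname gridShape
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname gridShape
#' @export
setMethod("gridShape", "VolumeGrid", function(x) dim(x@values)[1:3])

#' @rdname gridShape
#' @export
setMethod("gridAffine", "VolumeGrid", function(x) x@affine)

#' @rdname gridShape
#' @export
setMethod("gridValues", "VolumeGrid", function(x) x@values)

#' @rdname gridShape
#' @export
setMethod("nComponents", "VolumeGrid", function(x) dim(x@values)[4])

#' Head mask accessor
#'
#' @param x a [ConductivityVolume] or [ScalarPotential].
#' @return logical 3-D array, TRUE inside the head.
#' @export
setGeneric("headMask", function(x) standardGeneric("headMask"))

#' @rdname headMask
#' @export
setMethod("headMask", "ConductivityVolume", function(x) x@mask)

#' @rdname headMask
#' @export
setMethod("headMask", "ScalarPotential", function(x) x@mask)

#' Transform matrix accessor
#'
#' @param x a [RigidTransform].
#' @return the 4x4 homogeneous matrix.
#' @export
setGeneric("transformMatrix", function(x) standardGeneric("transformMatrix"))

#' @rdname transformMatrix
#' @export
setMethod("transformMatrix", "RigidTransform", function(x) x@matrix)

#' Coil segment accessor
#'
#' @param x a [CoilModel].
#' @return n x 6 matrix of straight segments (start xyz, end xyz), coil frame mm.
#' @export
setGeneric("coilSegments", function(x) standardGeneric("coilSegments"))

#' @rdname coilSegments
#' @export
setMethod("coilSegments", "CoilModel", function(x) x@segments)

#' Mesh accessors
#'
#' @param x a [TriangleMesh].
#' @return `meshVertices`: n x 3 matrix; `meshFaces`: m x 3 integer matrix.
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname meshVertices
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname meshVertices
#' @export
setMethod("meshVertices", "TriangleMesh", function(x) x@vertices)

#' @rdname meshVertices
#' @export
setMethod("meshFaces", "TriangleMesh", function(x) x@faces)

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s: %d x %d x %d voxels, %d component(s)\n",
              class(object), d[1], d[2], d[3], d[4]))
  sp <- sqrt(colSums(object@affine[1:3, 1:3]^2))
  cat(sprintf("  spacing (mm): %.3f %.3f %.3f\n", sp[1], sp[2], sp[3]))
  invisible(object)
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform (coil/world, mm):\n")
  print(round(object@matrix, 6))
  invisible(object)
})

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces%s\n",
              nrow(object@vertices), nrow(object@faces),
              if (length(object@scalar)) ", with scalar channel" else ""))
  invisible(object)
})

setMethod("show", "Streamlines", function(object) {
  cat(sprintf("Streamlines: %d polylines, %d points total\n",
              length(object@lines), sum(vapply(object@lines, nrow, 1L))))
  invisible(object)
})

setMethod("show", "CoilModel", function(object) {
  cat(sprintf("CoilModel '%s': %d segments, %d loop(s), dI/dt = %.3g A/s\n",
              object@name, nrow(object@segments),
              length(unique(object@loop_id)), object@didt))
  invisible(object)
})

setMethod("show", "PlacementSet", function(object) {
  cat(sprintf("PlacementSet: %d poses over %d site(s), seed %d\n",
              length(object@poses), length(unique(object@site)), object@seed))
  invisible(object)
})

setMethod("show", "TrainedSurrogate", function(object) {
  cfg <- object@config
  cat(sprintf("TrainedSurrogate: %d levels, base %d channels, %d epochs (final loss %.4g, NE %.3f)\n",
              cfg$levels, cfg$base_channels, cfg$epochs,
              tail(object@history$loss, 1), tail(object@history$ne, 1)))
  invisible(object)
})

setMethod("show", "IGTMessage", function(object) {
  cat(sprintf("IGTMessage %s from '%s': %d body bytes\n",
              object@type_name, object@device_name, length(object@body)))
  invisible(object)
})
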