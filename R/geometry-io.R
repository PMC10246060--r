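# External formats: NIfTI volumes, STL/PLY meshes, JSON streamlines and
# plain-text 4x4 transforms.

#' Read and write volumes as NIfTI-1
#'
#' Scalar volumes are written 3-D; vector (3) and tensor (6, order
#' xx,yy,zz,xy,xz,yz) volumes as 4-D NIfTI with the components on the last
#' axis. The NIfTI sform carries the voxel-to-world affine (RAS mm).
#'
#' @param path file path (.nii or .nii.gz).
#' @param vol a [VolumeGrid] (or subclass).
#' @param as one of "auto", "volume", "vector": class of the returned object
#'   ("auto" returns a [VectorField] for 3-component files).
#' @return `readNiftiVolume`: a [VolumeGrid] or [VectorField].
#' @export
readNiftiVolume <- function(path, as = c("auto", "volume", "vector")) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  vals <- array(as.numeric(img), dim(img))
  if (length(dim(vals)) == 3L) dim(vals) <- c(dim(vals), 1L)
  nc <- dim(vals)[4]
  if (as == "vector" || (as == "auto" && nc == 3L))
    vectorField(vals, aff)
  else
    volumeGrid(vals, aff)
}

#' @rdname readNiftiVolume
#' @export
writeNiftiVolume <- function(vol, path) {
  vals <- gridValues(vol)
  if (dim(vals)[4] == 1L) dim(vals) <- dim(vals)[1:3]
  img <- RNifti::asNifti(vals)
  RNifti::`sform<-`(img, structure(gridAffine(vol), code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write 4x4 transforms as row-major text
#'
#' Four whitespace-separated numbers per line, four lines (the coil position
#' matrix exchanged with navigation software).
#'
#' @param T a [RigidTransform].
#' @param path file path.
#' @return `readTransformText`: a [RigidTransform].
#' @export
writeTransformText <- function(T, path) {
  m <- transformMatrix(.as_rigid(T))
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             path)
  invisible(path)
}

#' @rdname writeTransformText
#' @export
readTransformText <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (!all(dim(m) == c(4, 4))) stop("transform file must contain a 4x4 matrix")
  rigidTransform(unname(m))
}

#' Read and write meshes as ASCII STL
#'
#' The reader merges exactly-duplicated facet vertices back into a shared
#' vertex table.
#'
#' @param mesh a [TriangleMesh].
#' @param path file path.
#' @param name solid name written to the file.
#' @return `readStl`: a [TriangleMesh].
#' @export
writeStl <- function(mesh, path, name = "mesh") {
  v <- mesh@vertices
  f <- mesh@faces
  n <- .face_normals(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]), con)
    writeLines("    outer loop", con)
    for (j in 1:3) {
      p <- v[f[i, j], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' @rdname writeStl
#' @export
readStl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  key <- apply(coords, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  verts <- coords[uniq, , drop = FALSE]
  idx <- match(key, key[uniq])
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  triangleMesh(verts, faces, check_degenerate = FALSE)
}

.face_normals <- function(mesh) {
  v <- mesh@vertices
  f <- mesh@faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Read and write meshes as ASCII PLY
#'
#' Carries the optional per-vertex scalar channel as a `quality` property.
#'
#' @param mesh a [TriangleMesh].
#' @param path file path.
#' @return `readPly`: a [TriangleMesh].
#' @export
writePly <- function(mesh, path) {
  v <- mesh@vertices
  f <- mesh@faces
  has_scalar <- length(mesh@scalar) > 0
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           if (has_scalar) "property double quality",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  writeLines(hdr, con)
  if (has_scalar)
    writeLines(sprintf("%.17g %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3],
                       mesh@scalar), con)
  else
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' @rdname writePly
#' @export
readPly <- function(path) {
  lines <- readLines(path)
  endh <- which(lines == "end_header")
  hdr <- lines[seq_len(endh)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  has_scalar <- any(grepl("property double quality", hdr))
  vlines <- lines[endh + seq_len(nv)]
  vm <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), as.numeric))
  flines <- lines[endh + nv + seq_len(nf)]
  fm <- do.call(rbind, lapply(strsplit(flines, "\\s+"), function(x)
    as.integer(x[2:4]) + 1L))
  triangleMesh(vm[, 1:3, drop = FALSE], fm,
               scalar = if (has_scalar) vm[, 4] else numeric(0),
               check_degenerate = FALSE)
}

#' Read and write streamlines as line-per-polyline JSON
#'
#' Each polyline is a list of [x, y, z] world-mm points.
#'
#' @param streamlines a [Streamlines] object.
#' @param path file path.
#' @return `readStreamlinesJson`: a [Streamlines] object.
#' @export
writeStreamlinesJson <- function(streamlines, path) {
  jsonlite::write_json(lapply(streamlines@lines, unname), path,
                       digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeStreamlinesJson
#' @export
readStreamlinesJson <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lines <- lapply(raw, function(l)
    do.call(rbind, lapply(l, function(p) as.numeric(unlist(p)))))
  new("Streamlines", lines = lines)
}
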