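# Triangle meshes: construction, icospheres, closure checks.

#' Construct a TriangleMesh
#'
#' @param vertices n x 3 numeric matrix (world mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param scalar optional per-vertex scalar channel.
#' @param check_degenerate error on zero-area faces (default TRUE).
#' @return a [TriangleMesh].
#' @export
triangleMesh <- function(vertices, faces, scalar = numeric(0),
                         check_degenerate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L)
  storage.mode(faces) <- "integer"
  mesh <- new("TriangleMesh", vertices = vertices, faces = faces,
              scalar = as.numeric(scalar))
  if (check_degenerate && any(faceAreas(mesh) <= 0))
    stop("mesh contains degenerate (zero-area) faces")
  mesh
}

#' Triangle areas of a mesh
#'
#' @param mesh a [TriangleMesh].
#' @return numeric vector of face areas (mm^2).
#' @export
faceAreas <- function(mesh) {
  v <- mesh@vertices
  f <- mesh@faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Check whether a mesh is closed
#'
#' A mesh is closed (watertight) when every edge is shared by exactly two
#' faces.
#'
#' @param mesh a [TriangleMesh].
#' @return logical.
#' @export
meshIsClosed <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere: a closed triangulation with
#' near-uniform face sizes, used for the scalp and gray-matter surfaces of
#' synthetic heads.
#'
#' @param radius sphere radius (mm).
#' @param center world-mm centre.
#' @param subdivisions number of 4-to-1 triangle subdivisions (default 3:
#'   642 vertices, 1280 faces).
#' @return a closed [TriangleMesh].
#' @export
icosphere <- function(radius, center = c(0, 0, 0), subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list(v)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1L
      newv[[length(newv) + 1L]] <<- m
      midcache[[key]] <- nv
      nv
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(i - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, newv)
    f <- newf
  }
  verts <- sweep(v * radius, 2, center, "+")
  triangleMesh(verts, f)
}
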