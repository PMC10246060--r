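# Figure-8 coil geometry, analytic dA/dt evaluation and coil-placement
# sampling over EEG 10-10 scalp sites.

#' Construct a discretized figure-8 coil
#'
#' Two coplanar circular loops centred at (-offset, 0, 0) and (+offset, 0, 0)
#' in the coil frame (plane z = 0, -z toward the scalp, handle along +y),
#' wound with opposite circulation so the field concentrates under the loop
#' junction, each discretized into `segments_per_loop` straight chords. The
#' defaults are a plausible proxy for a 70 mm figure-8 treatment coil.
#'
#' @param loop_radius_mm loop radius (default 27 mm).
#' @param loop_center_offset_mm distance of each loop centre from the coil
#'   origin (default 27 mm), must be > 0.
#' @param segments_per_loop chords per loop (>= 8, default 64).
#' @param didt coil current rate dI/dt in A/s (default 1e6).
#' @return a [CoilModel].
#' @export
makeFigure8Coil <- function(loop_radius_mm = 27, loop_center_offset_mm = 27,
                            segments_per_loop = 64L, didt = 1e6) {
  if (loop_radius_mm <= 0) stop("loop radius must be > 0")
  if (loop_center_offset_mm <= 0) stop("loop centre offset must be > 0")
  if (segments_per_loop < 8L) stop("segments_per_loop must be >= 8")
  left <- .loop_segments(c(-loop_center_offset_mm, 0, 0), loop_radius_mm,
                         segments_per_loop, ccw = TRUE)
  right <- .loop_segments(c(loop_center_offset_mm, 0, 0), loop_radius_mm,
                          segments_per_loop, ccw = FALSE)
  new("CoilModel", segments = rbind(left, right),
      loop_id = rep(1:2, each = segments_per_loop),
      didt = didt, name = "figure8-70mm-proxy")
}

#' Construct a single circular loop coil
#'
#' Used mainly as a physics oracle: a single loop coaxial with a spherically
#' symmetric head induces no scalar potential.
#'
#' @param radius_mm loop radius.
#' @param segments chords (>= 8).
#' @param didt dI/dt (A/s).
#' @param center loop centre in the coil frame.
#' @return a [CoilModel].
#' @export
makeCircularLoopCoil <- function(radius_mm = 27, segments = 64L, didt = 1e6,
                                 center = c(0, 0, 0)) {
  new("CoilModel",
      segments = .loop_segments(center, radius_mm, segments, ccw = TRUE),
      loop_id = rep(1L, segments), didt = didt, name = "circular-loop")
}

.loop_segments <- function(center, radius, n, ccw = TRUE) {
  # area-preserving chord polygon: vertices on a slightly larger circle so the
  # polygon's magnetic moment equals the continuous loop's
  r_eff <- radius * sqrt(2 * pi / n / sin(2 * pi / n))
  th <- seq(0, 2 * pi, length.out = n + 1L)
  if (!ccw) th <- rev(th)
  p <- cbind(center[1] + r_eff * cos(th), center[2] + r_eff * sin(th),
             center[3] + 0 * th)
  cbind(p[-(n + 1L), , drop = FALSE], p[-1L, , drop = FALSE])
}

#' Net magnetic moment of a coil (signed loop area sum)
#'
#' Sum of the signed polygon area vectors of all loops times dI/dt-independent
#' unit circulation; for a balanced figure-8 the opposite circulations cancel.
#'
#' @param coil a [CoilModel].
#' @return length-3 numeric vector (mm^2 units).
#' @export
coilMoment <- function(coil) {
  s <- coil@segments
  m <- 0.5 * cbind(
    s[, 2] * s[, 6] - s[, 3] * s[, 5],
    s[, 3] * s[, 4] - s[, 1] * s[, 6],
    s[, 1] * s[, 5] - s[, 2] * s[, 4])
  colSums(m)
}

#' Evaluate the coil's dA/dt field on a voxel grid
#'
#' The time derivative of the magnetic vector potential of the posed coil,
#' evaluated at every voxel centre of `grid` in the world frame:
#' dA/dt(r) = (mu0 dI/dt / 4 pi) * sum over straight segments of the
#' closed-form line integral of 1/|r - r'|. Evaluation points within `guard`
#' mm of a wire have the integrand clamped (with a warning).
#'
#' @param coil a [CoilModel].
#' @param pose a [RigidTransform], coil frame to world.
#' @param grid a [VolumeGrid] defining the evaluation lattice.
#' @param guard clamping distance near the wire (default 0.5 mm).
#' @return a [VectorField] (V/m) on the grid of `grid`.
#' @export
dadtField <- function(coil, pose, grid, guard = 0.5) {
  pose <- .as_rigid(pose)
  segs <- .posed_segments(coil, pose)
  pts <- voxelCenters(grid)
  out <- cpp_dadt(segs, pts, coil@didt, guard)
  ncl <- attr(out, "n_clamped")
  if (!is.null(ncl) && ncl > 0)
    warning(sprintf("%d evaluation point(s) within %.2f mm of a coil wire; distance clamped", ncl, guard))
  vectorField(array(out, c(gridShape(grid), 3L)), gridAffine(grid))
}

#' @rdname dadtField
#' @param points n x 3 world-mm evaluation points.
#' @return `dadtAtPoints`: n x 3 matrix (V/m).
#' @export
dadtAtPoints <- function(coil, pose, points, guard = 0.5) {
  pose <- .as_rigid(pose)
  segs <- .posed_segments(coil, pose)
  out <- cpp_dadt(segs, matrix(as.numeric(points), ncol = 3L), coil@didt, guard)
  attr(out, "n_clamped") <- NULL
  out
}

.posed_segments <- function(coil, pose) {
  m <- transformMatrix(pose)
  s <- coil@segments
  cbind(voxelToWorld(m, s[, 1:3, drop = FALSE]),
        voxelToWorld(m, s[, 4:6, drop = FALSE]))
}

# ---------------------------------------------------------------------------
# EEG 10-10 sites and placement sampling
# ---------------------------------------------------------------------------

#' Idealized EEG 10-10 scalp sites on the unit sphere
#'
#' Constructs the 73 scalp positions of the extended 10-20 (10-10) system on
#' an idealized spherical head: the vertex Cz, the sagittal midline at 10%
#' arc steps, the 20-site outer ring 18 degrees above the equator, interior
#' coronal arcs (AF, F, FC, C, CP, P, PO rows) subdivided through their
#' midline sites, and the 12 equatorial 9/10-suffix sites. Coordinates use
#' +x right, +y anterior, +z superior.
#'
#' @return data.frame with columns `label`, `x`, `y`, `z` (unit vectors).
#' @export
eeg1010Sites <- function() {
  sph <- function(az_deg, el_deg) {
    az <- az_deg * pi / 180
    el <- el_deg * pi / 180
    c(sin(az) * cos(el), cos(az) * cos(el), sin(el))
  }
  sites <- list()
  add <- function(label, p) sites[[label]] <<- p

  # outer ring, elevation 18 deg, azimuth from anterior (+y) toward right (+x)
  ring <- c(Fpz = 0, Fp2 = 18, AF8 = 36, F8 = 54, FT8 = 72, T8 = 90,
            TP8 = 108, P8 = 126, PO8 = 144, O2 = 162, Oz = 180,
            O1 = -162, PO7 = -144, P7 = -126, TP7 = -108, T7 = -90,
            FT7 = -72, F7 = -54, AF7 = -36, Fp1 = -18)
  for (lab in names(ring)) add(lab, sph(ring[[lab]], 18))

  # sagittal midline, 10% (18 deg) steps from nasion over the vertex
  mid <- c(AFz = 36, Fz = 54, FCz = 72, Cz = 90, CPz = 108, Pz = 126, POz = 144)
  for (lab in names(mid)) {
    t <- mid[[lab]] * pi / 180
    add(lab, c(0, cos(t), sin(t)))
  }

  # interior coronal arcs: circle through (left anchor, midline, right anchor)
  rows <- list(
    list(l = "AF7", m = "AFz", r = "AF8", labels = c("AF3", NA, "AF4")),
    list(l = "F7", m = "Fz", r = "F8",
         labels = c("F5", "F3", "F1", NA, "F2", "F4", "F6")),
    list(l = "FT7", m = "FCz", r = "FT8",
         labels = c("FC5", "FC3", "FC1", NA, "FC2", "FC4", "FC6")),
    list(l = "T7", m = "Cz", r = "T8",
         labels = c("C5", "C3", "C1", NA, "C2", "C4", "C6")),
    list(l = "TP7", m = "CPz", r = "TP8",
         labels = c("CP5", "CP3", "CP1", NA, "CP2", "CP4", "CP6")),
    list(l = "P7", m = "Pz", r = "P8",
         labels = c("P5", "P3", "P1", NA, "P2", "P4", "P6")),
    list(l = "PO7", m = "POz", r = "PO8", labels = c("PO3", NA, "PO4")))
  for (row in rows) {
    pts <- .arc_through3(sites[[row$l]], sites[[row$m]], sites[[row$r]],
                         length(row$labels) + 2L)
    for (i in seq_along(row$labels))
      if (!is.na(row$labels[i])) add(row$labels[i], pts[i + 1L, ])
  }

  # equatorial 9/10-suffix sites at the azimuths of their ring counterparts
  eq <- c(F10 = 54, FT10 = 72, T10 = 90, TP10 = 108, P10 = 126, PO10 = 144,
          F9 = -54, FT9 = -72, T9 = -90, TP9 = -108, P9 = -126, PO9 = -144)
  for (lab in names(eq)) add(lab, sph(eq[[lab]], 0))

  labs <- names(sites)
  m <- do.call(rbind, sites)
  data.frame(label = labs, x = m[, 1], y = m[, 2], z = m[, 3])
}

# n points (incl. endpoints) along the circle through p1, pm, p2, from p1 to
# p2 passing through pm.
.arc_through3 <- function(p1, pm, p2, n) {
  # circle centre: solve in the plane spanned by (p1->pm, p1->p2)
  u <- pm - p1
  v <- p2 - p1
  uu <- sum(u * u); vv <- sum(v * v); uv <- sum(u * v)
  den <- 2 * (uu * vv - uv^2)
  k1 <- (vv * (uu - uv)) / den
  k2 <- (uu * (vv - uv)) / den
  ctr <- p1 + k1 * u + k2 * v
  rho <- sqrt(sum((p1 - ctr)^2))
  e1 <- (p1 - ctr) / rho
  w <- pm - ctr
  w <- w - sum(w * e1) * e1
  e2 <- w / sqrt(sum(w^2))
  ang <- function(p) {
    d <- p - ctr
    a <- atan2(sum(d * e2), sum(d * e1))
    if (a < 0) a <- a + 2 * pi
    a
  }
  a2 <- ang(p2)
  t <- seq(0, a2, length.out = n)
  t(sapply(t, function(a) ctr + rho * (cos(a) * e1 + sin(a) * e2)))
}

#' Coil pose at a scalp site
#'
#' Builds the coil-to-world rigid pose for a scalp site: the coil origin sits
#' `standoff_mm` above the scalp along the outward radial, the coil -z axis
#' points toward the head centre, and the handle (+y) starts at the local
#' "toward nasion" tangent rotated by `direction_deg` about the coil normal.
#'
#' @param site_unit unit vector of the site on the head sphere.
#' @param head a [HeadGeometry].
#' @param direction_deg handle rotation about the outward normal (degrees).
#' @param standoff_mm scalp clearance (default 2 mm, a casing proxy).
#' @return a [RigidTransform].
#' @export
coilPoseAtSite <- function(site_unit, head, direction_deg = 0, standoff_mm = 2) {
  rhat <- .unit(site_unit)
  pos <- head@center + (head@outer_radius + standoff_mm) * rhat
  nas <- c(0, 1, 0)  # toward nasion
  t0 <- nas - sum(nas * rhat) * rhat
  if (sqrt(sum(t0^2)) < 1e-6) t0 <- c(1, 0, 0) - sum(c(1, 0, 0) * rhat) * rhat
  t0 <- .unit(t0)
  th <- direction_deg * pi / 180
  handle <- cos(th) * t0 + sin(th) * .cross3(rhat, t0)
  zax <- rhat                      # coil -z faces the scalp
  xax <- .cross3(handle, zax)
  m <- diag(4)
  m[1:3, 1] <- xax
  m[1:3, 2] <- handle
  m[1:3, 3] <- zax
  m[1:3, 4] <- pos
  rigidTransform(m)
}

#' Sample coil placements over 10-10 sites and handle directions
#'
#' Enumerates every combination of the built-in 10-10 scalp sites and
#' `n_directions` handle directions evenly spaced over 360 degrees (step
#' 360/n_directions, direction 0 at the "toward nasion" tangent), then
#' returns a seeded uniform random subset of `n_cases` poses. Defaults follow
#' the training protocol of the real-data pipeline: 78 directions, 300 cases.
#'
#' @param head a [HeadGeometry].
#' @param n_cases number of placements to select.
#' @param n_directions handle directions per site (default 78).
#' @param seed RNG seed for the subset.
#' @param standoff_mm scalp clearance (default 2).
#' @param sites optional data.frame as from [eeg1010Sites()].
#' @return a [PlacementSet].
#' @export
samplePlacements <- function(head, n_cases = 300L, n_directions = 78L,
                             seed = 1L, standoff_mm = 2,
                             sites = eeg1010Sites()) {
  if (n_directions < 1L) stop("n_directions must be >= 1")
  total <- nrow(sites) * n_directions
  if (n_cases > total)
    stop(sprintf("n_cases (%d) exceeds the enumerable set (%d sites x %d directions = %d)",
                 n_cases, nrow(sites), n_directions, total))
  pick <- .with_seed(seed, sort(sample.int(total, n_cases)))
  site_idx <- ((pick - 1L) %/% n_directions) + 1L
  dir_idx <- (pick - 1L) %% n_directions
  poses <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    u <- as.numeric(sites[site_idx[i], c("x", "y", "z")])
    poses[[i]] <- coilPoseAtSite(u, head, dir_idx[i] * 360 / n_directions,
                                 standoff_mm)
  }
  new("PlacementSet", poses = poses, site = sites$label[site_idx],
      direction = as.integer(dir_idx), seed = as.integer(seed))
}

#' Write a placement set as CSV
#'
#' One row per pose: site label, direction index and the 16 row-major entries
#' of the coil-to-world matrix.
#'
#' @param placements a [PlacementSet].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writePlacementsCsv <- function(placements, path) {
  mats <- t(vapply(placements@poses,
                   function(p) as.vector(t(transformMatrix(p))), numeric(16)))
  colnames(mats) <- sprintf("m%d%d", rep(1:4, each = 4), rep(1:4, 4))
  df <- data.frame(site = placements@site, direction_index = placements@direction,
                   mats, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export the coil winding as a displayable STL ribbon
#'
#' Each straight segment becomes a thin in-plane quad (two triangles), wide
#' enough to be visible in a mesh viewer.
#'
#' @param coil a [CoilModel].
#' @param path file path.
#' @param width_mm ribbon width (default 1).
#' @return the path, invisibly.
#' @export
writeCoilStl <- function(coil, path, width_mm = 1) {
  s <- coil@segments
  n <- nrow(s)
  verts <- matrix(0, 4L * n, 3L)
  faces <- matrix(0L, 2L * n, 3L)
  for (i in seq_len(n)) {
    p1 <- s[i, 1:3]; p2 <- s[i, 4:6]
    d <- .unit(p2 - p1)
    perp <- .cross3(d, c(0, 0, 1))
    if (sqrt(sum(perp^2)) < 1e-9) perp <- c(1, 0, 0)
    perp <- .unit(perp) * width_mm / 2
    verts[(i - 1L) * 4L + 1:4, ] <- rbind(p1 - perp, p1 + perp, p2 + perp, p2 - perp)
    o <- (i - 1L) * 4L
    faces[(i - 1L) * 2L + 1:2, ] <- rbind(c(o + 1L, o + 2L, o + 3L),
                                          c(o + 1L, o + 3L, o + 4L))
  }
  writeStl(triangleMesh(verts, faces, check_degenerate = FALSE), path,
           name = coil@name)
  invisible(path)
}
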