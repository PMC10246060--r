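# Synthetic multi-shell spherical head models: conductivity-tensor volumes,
# surface meshes, head masks and synthetic white-matter streamlines. These
# emulate the structure of segmented-MRI volume conductor models (scalp,
# skull, CSF, gray matter, white matter) at a size the solver can handle on a
# desktop.

#' Default five-shell conductivities
#'
#' Standard literature values (S/m): scalp 0.465, skull 0.010, CSF 1.654,
#' gray matter 0.275, white matter 0.126.
#'
#' @param outer_radius_mm scalp radius; shell boundaries are scaled from the
#'   default head proportions.
#' @return data.frame with columns `radius_mm`, `sigma`, `tissue`.
#' @export
defaultShells <- function(outer_radius_mm = 55) {
  ratio <- c(1, 0.891, 0.782, 0.691, 0.509)  # scalp, skull, CSF, GM, WM outer radii
  data.frame(radius_mm = outer_radius_mm * ratio,
             sigma = c(0.465, 0.010, 1.654, 0.275, 0.126),
             tissue = c("scalp", "skull", "csf", "gm", "wm"))
}

#' Generate a multi-shell spherical head
#'
#' Builds an isotropic conductivity-tensor volume on a regular grid: each
#' voxel takes the conductivity of the innermost shell containing its centre
#' (a centre exactly on a shell radius belongs to the outer shell); voxels
#' outside the scalp radius are masked out with exactly-zero tensors. Closed
#' icosphere meshes are generated at the scalp and gray-matter radii.
#'
#' @param outer_radius_mm scalp radius (mm); must fit inside the grid.
#' @param shells data.frame as from [defaultShells()]: strictly decreasing
#'   `radius_mm` and isotropic `sigma` (S/m) per shell.
#' @param grid_shape integer length-3 voxel dimensions (default 48^3).
#' @param voxel_mm isotropic voxel size (default 2.5 mm).
#' @param center world-mm head centre (default origin).
#' @return list with elements `conductivity` (a [ConductivityVolume]) and
#'   `geometry` (a [HeadGeometry]).
#' @export
makeSphereHead <- function(outer_radius_mm = 55, shells = defaultShells(outer_radius_mm),
                           grid_shape = c(48L, 48L, 48L), voxel_mm = 2.5,
                           center = c(0, 0, 0)) {
  grid_shape <- as.integer(grid_shape)
  radii <- shells$radius_mm
  sigma <- shells$sigma
  if (any(diff(radii) >= 0)) stop("shell radii must be strictly decreasing")
  if (any(sigma < 0)) stop("conductivities must be >= 0")
  if (radii[1] != outer_radius_mm) stop("first shell radius must equal outer_radius_mm")
  half_extent <- voxel_mm * (grid_shape - 1) / 2
  if (any(outer_radius_mm > half_extent))
    stop("sphere exceeds grid bounds; enlarge grid_shape or shrink the radius")

  affine <- centeredAffine(grid_shape, voxel_mm, center)
  tmp <- volumeGrid(array(0, c(grid_shape, 1L)), affine)
  pts <- voxelCenters(tmp)
  r <- sqrt(rowSums(sweep(pts, 2, center)^2))
  mask <- r <= radii[1]

  # shell index: outermost shell whose radius is >= r, ties to the outer shell
  shell_idx <- rep(0L, length(r))
  counts <- rowSums(outer(r, radii, "<"))
  shell_idx[mask] <- pmax(1L, counts[mask])

  vals <- array(0, c(grid_shape, 6L))
  flat <- matrix(0, length(r), 6L)
  iso <- c(sigma, 0)[ifelse(shell_idx == 0L, length(sigma) + 1L, shell_idx)]
  flat[, 1:3] <- iso
  vals[] <- flat
  cv <- new("ConductivityVolume", values = vals, affine = affine,
            mask = array(mask, grid_shape))

  geo <- new("HeadGeometry",
             scalp_mesh = icosphere(radii[1], center),
             gm_mesh = icosphere(radii[{
               i <- match("gm", shells$tissue)
               if (is.na(i)) max(1L, length(radii) - 1L) else i
             }], center),
             center = center, outer_radius = radii[1],
             shell_radii = radii, shell_sigma = sigma)
  list(conductivity = cv, geometry = geo)
}

#' Rebuild white-matter tensors with random anisotropy
#'
#' Within the radial shell `(r_in, r_out]` around the head centre, each
#' in-mask tensor is rebuilt with a random unit principal direction and
#' eigenvalues (lambda1, lambda2, lambda2) chosen so that
#' lambda1/lambda2 = `anisotropy_ratio` while the tensor trace is preserved
#' exactly. Voxels elsewhere are unchanged. This synthesizes the
#' fibre-direction-dependent conductivity that diffusion MRI provides for
#' real heads.
#'
#' @param cv a [ConductivityVolume].
#' @param center head centre (world mm).
#' @param wm_shell length-2 numeric `(r_in, r_out)` in mm.
#' @param anisotropy_ratio principal-to-transverse eigenvalue ratio, >= 1.
#' @param seed RNG seed (reproducible tensors).
#' @return a [ConductivityVolume] with anisotropic white matter.
#' @export
randomizeConductivityTensors <- function(cv, center = c(0, 0, 0),
                                         wm_shell, anisotropy_ratio = 3,
                                         seed = 1L) {
  if (anisotropy_ratio < 1) stop("anisotropy_ratio must be >= 1")
  if (anisotropy_ratio == 1) return(cv)
  pts <- voxelCenters(cv)
  r <- sqrt(rowSums(sweep(pts, 2, center)^2))
  sel <- as.vector(cv@mask) & r > wm_shell[1] & r <= wm_shell[2]
  if (!any(sel)) return(cv)

  flat <- matrix(gridValues(cv), ncol = 6L)
  tr <- rowSums(flat[sel, 1:3, drop = FALSE])
  n <- sum(sel)
  u <- .with_seed(seed, matrix(rnorm(3L * n), n, 3L))
  u <- u / sqrt(rowSums(u^2))
  lam2 <- tr / (anisotropy_ratio + 2)
  dl <- (anisotropy_ratio - 1) * lam2  # lambda1 - lambda2
  # T = lam2 I + (lam1 - lam2) u u^T, order xx,yy,zz,xy,xz,yz
  flat[sel, 1] <- lam2 + dl * u[, 1]^2
  flat[sel, 2] <- lam2 + dl * u[, 2]^2
  flat[sel, 3] <- lam2 + dl * u[, 3]^2
  flat[sel, 4] <- dl * u[, 1] * u[, 2]
  flat[sel, 5] <- dl * u[, 1] * u[, 3]
  flat[sel, 6] <- dl * u[, 2] * u[, 3]
  vals <- array(flat, dim(gridValues(cv)))
  new("ConductivityVolume", values = vals, affine = gridAffine(cv), mask = cv@mask)
}

#' Smallest tensor eigenvalue per in-mask voxel
#'
#' Diagnostic for the symmetric-positive-semi-definite invariant of generated
#' conductivity volumes.
#'
#' @param cv a [ConductivityVolume].
#' @return numeric vector of minimum eigenvalues over in-mask voxels.
#' @export
minTensorEigenvalues <- function(cv) {
  flat <- matrix(gridValues(cv), ncol = 6L)[as.vector(cv@mask), , drop = FALSE]
  apply(flat, 1, function(t6) {
    m <- matrix(c(t6[1], t6[4], t6[5],
                  t6[4], t6[2], t6[6],
                  t6[5], t6[6], t6[3]), 3, 3)
    min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  })
}

#' Synthetic white-matter streamlines
#'
#' Generates `n` circular arcs lying strictly inside the white-matter ball
#' (radius = the innermost shell boundary): each arc has a random plane, a
#' random arc radius and a random angular span, sampled reproducibly from
#' `seed`.
#'
#' @param head a [HeadGeometry].
#' @param n number of streamlines.
#' @param points_per_line points per polyline (>= 2).
#' @param seed RNG seed.
#' @param margin_mm clearance kept from the white-matter boundary (default 2).
#' @return a [Streamlines] object.
#' @export
makeSyntheticStreamlines <- function(head, n, points_per_line = 20L, seed = 1L,
                                     margin_mm = 2) {
  if (n < 1) stop("n must be >= 1")
  r_wm <- min(head@shell_radii)
  if (r_wm - margin_mm <= margin_mm)
    stop("white-matter ball too thin for the requested arc margin")
  lines <- vector("list", n)
  .with_seed(seed, for (i in seq_len(n)) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * ax) * ax; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(ax[2] * e1[3] - ax[3] * e1[2],
            ax[3] * e1[1] - ax[1] * e1[3],
            ax[1] * e1[2] - ax[2] * e1[1])
    rho <- runif(1, margin_mm, r_wm - margin_mm)
    t0 <- runif(1, 0, 2 * pi)
    span <- runif(1, pi / 4, pi)
    t <- seq(t0, t0 + span, length.out = points_per_line)
    arc <- outer(cos(t), e1) + outer(sin(t), e2)
    lines[[i]] <- sweep(rho * arc, 2, head@center, "+")
  })
  new("Streamlines", lines = lines)
}
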