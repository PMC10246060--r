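# Quasi-static ground-truth solver. Under the quasi-static approximation the
# induced field is E = -dA/dt - grad(phi) with the scalar potential phi
# satisfying the current-conservation equation div(sigma (grad phi + dA/dt))
# = 0 inside the head and zero normal total current at its boundary. The
# discretization is a cell-centred finite volume scheme on the voxel grid:
# diagonal tensor components enter through harmonic-mean face conductivities,
# off-diagonal components through central-difference cross terms averaged to
# the faces; boundary faces are simply omitted (natural Neumann condition).

#' Solve the induced scalar potential (finite volume)
#'
#' @param cv a [ConductivityVolume] (tensors SPD inside the mask).
#' @param dadt a [VectorField] on the same grid.
#' @param tol relative residual target (default 1e-8).
#' @param max_iter Krylov iteration cap; default `1000 * N^(1/3)` with N the
#'   voxel count.
#' @return a [ScalarPotential] (zero-mean gauge over the mask, zero outside,
#'   with `residual` and `iterations` diagnostics). Non-convergence is an
#'   error carrying the final residual.
#' @export
solvePotentialFdm <- function(cv, dadt, tol = 1e-8, max_iter = NULL) {
  if (!.same_grid(cv, dadt)) stop("conductivity and dA/dt grids are misaligned")
  dims <- gridShape(cv)
  h <- .grid_spacing(gridAffine(cv), require_axis_aligned = TRUE)
  if (is.null(max_iter)) max_iter <- ceiling(1000 * prod(dims)^(1 / 3))

  mask <- cv@mask
  nvox <- prod(dims)
  uid <- rep(NA_integer_, nvox)
  uid[mask] <- seq_len(sum(mask))
  nun <- sum(mask)
  if (nun == 0L) stop("empty head mask")

  s <- matrix(gridValues(cv), ncol = 6L)    # xx yy zz xy xz yz
  a <- matrix(gridValues(dadt), ncol = 3L)

  lin <- array(seq_len(nvox), dims)
  strides <- c(1L, dims[1], dims[1] * dims[2])
  coord <- cbind((seq_len(nvox) - 1L) %% dims[1],
                 ((seq_len(nvox) - 1L) %/% dims[1]) %% dims[2],
                 (seq_len(nvox) - 1L) %/% (dims[1] * dims[2]))

  ti <- integer(0); tj <- integer(0); tv <- numeric(0)      # symmetric part
  ci <- integer(0); cj <- integer(0); cvv <- numeric(0)     # cross terms
  b <- numeric(nun)
  diag_comp <- c(1L, 2L, 3L)
  off_comp <- list(c(4L, 5L), c(4L, 6L), c(5L, 6L))  # (xy,xz), (xy,yz), (xz,yz)
  other_ax <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  has_offdiag <- max(abs(s[, 4:6])) > 0

  add_sym <- function(i, j, v) {
    ti <<- c(ti, i); tj <<- c(tj, j); tv <<- c(tv, v)
  }
  add_cross <- function(i, j, v) {
    keep <- !is.na(j) & v != 0
    ci <<- c(ci, i[keep]); cj <<- c(cj, j[keep]); cvv <<- c(cvv, v[keep])
  }

  for (ax in 1:3) {
    # faces between cell m1 and its +ax neighbour m2, both inside the mask
    sel_idx <- which(mask & coord[, ax] < dims[ax] - 1L)
    m2 <- sel_idx + strides[ax]
    keep <- mask[m2]
    m1 <- sel_idx[keep]; m2 <- m2[keep]
    if (!length(m1)) next
    u1 <- uid[m1]; u2 <- uid[m2]

    s1 <- s[m1, diag_comp[ax]]; s2 <- s[m2, diag_comp[ax]]
    g <- ifelse(s1 + s2 > 0, 2 * s1 * s2 / (s1 + s2), 0) / h[ax]^2
    add_sym(u1, u1, g); add_sym(u2, u2, g)
    add_sym(u1, u2, -g); add_sym(u2, u1, -g)

    # source flux through this face, with the same transmissibilities as the
    # potential flux (harmonic for the normal-normal component, arithmetic for
    # the cross components): with A = -div(sigma grad), A phi = +div_h(sigma a)
    qf <- g * h[ax] * (a[m1, ax] + a[m2, ax]) / 2
    if (has_offdiag) {
      for (t in 1:2) {
        oc <- off_comp[[ax]][t]
        bx <- other_ax[[ax]][t]
        qf <- qf + (s[m1, oc] + s[m2, oc]) / 2 *
          (a[m1, bx] + a[m2, bx]) / 2 / h[ax]
      }
    }
    b[u1] <- b[u1] + qf
    b[u2] <- b[u2] - qf

    if (has_offdiag) {
      for (t in 1:2) {
        oc <- off_comp[[ax]][t]       # sigma component coupling ax with bx
        bx <- other_ax[[ax]][t]
        sf <- (s[m1, oc] + s[m2, oc]) / 2
        w <- sf / (4 * h[bx] * h[ax])
        if (all(w == 0)) next
        for (side in c(1L, -1L)) {    # neighbour offset along bx
          off <- side * strides[bx]
          ok_range <- if (side > 0) coord[, bx] < dims[bx] - 1L else coord[, bx] > 0L
          # stencil cells: m1+off and m2+off
          for (mm in list(m1, m2)) {
            nb <- mm + off
            valid <- ok_range[mm] & mask[pmin(pmax(nb, 1L), nvox)]
            un <- ifelse(valid, uid[pmin(pmax(nb, 1L), nvox)], NA_integer_)
            # flux contributes -w*side to row u1 (outward +ax) and +w*side to u2
            add_cross(u1, un, -side * w)
            add_cross(u2, un, +side * w)
          }
        }
      }
    }
  }

  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(nun, nun))
  d <- Matrix::diag(A)
  d[d <= 0] <- 1
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) {
    phi_flat <- numeric(nun)
    res <- 0; iters <- 0L
  } else if (!has_offdiag || length(ci) == 0L) {
    sol <- .pcg(A, b, d, tol, max_iter)
    phi_flat <- sol$x; res <- sol$residual; iters <- sol$iterations
  } else {
    C <- Matrix::sparseMatrix(i = ci, j = cj, x = cvv, dims = c(nun, nun))
    M <- A + C
    sol <- .bicgstab(M, b, d, tol, max_iter)
    phi_flat <- sol$x; res <- sol$residual; iters <- sol$iterations
  }
  if (res > tol)
    stop(sprintf("potential solve did not converge: relative residual %.3g > tol %.3g after %d iterations",
                 res, tol, iters))

  phi_flat <- phi_flat - mean(phi_flat)   # zero-mean gauge over the mask
  vals <- array(0, c(dims, 1L))
  vals[which(mask)] <- phi_flat           # 4th dim is 1: linear indices align
  new("ScalarPotential", values = vals, affine = gridAffine(cv), mask = mask,
      residual = res, iterations = as.integer(iters))
}

# Jacobi-preconditioned conjugate gradients (A symmetric positive
# semi-definite; the constant null vector is gauged away after the solve).
.pcg <- function(A, b, d, tol, max_iter) {
  x <- numeric(length(b))
  r <- b
  bnorm <- sqrt(sum(b^2))
  z <- r / d
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(max_iter)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / bnorm
    if (res <= tol) return(list(x = x, residual = res, iterations = it))
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, residual = sqrt(sum(r^2)) / bnorm, iterations = max_iter)
}

# Jacobi-preconditioned BiCGSTAB for the nonsymmetric operator that arises
# when off-diagonal (anisotropic) tensor components are present.
.bicgstab <- function(M, b, d, tol, max_iter) {
  n <- length(b)
  x <- numeric(n)
  r <- b
  bnorm <- sqrt(sum(b^2))
  rhat <- r
  rho <- 1; alpha <- 1; omega <- 1
  v <- numeric(n); p <- numeric(n)
  for (it in seq_len(max_iter)) {
    rho_new <- sum(rhat * r)
    if (abs(rho_new) < 1e-300) break
    beta <- (rho_new / rho) * (alpha / omega)
    p <- r + beta * (p - omega * v)
    phat <- p / d
    v <- as.numeric(M %*% phat)
    alpha <- rho_new / sum(rhat * v)
    sres <- r - alpha * v
    if (sqrt(sum(sres^2)) / bnorm <= tol) {
      x <- x + alpha * phat
      return(list(x = x, residual = sqrt(sum(sres^2)) / bnorm, iterations = it))
    }
    shat <- sres / d
    t <- as.numeric(M %*% shat)
    omega <- sum(t * sres) / sum(t * t)
    x <- x + alpha * phat + omega * shat
    r <- sres - omega * t
    res <- sqrt(sum(r^2)) / bnorm
    if (res <= tol) return(list(x = x, residual = res, iterations = it))
    rho <- rho_new
  }
  list(x = x, residual = sqrt(sum(r^2)) / bnorm, iterations = max_iter)
}

#' Total quasi-static E-field
#'
#' E = -dA/dt - grad(phi), with the potential gradient taken by central
#' differences inside the mask and one-sided differences where a neighbour
#' leaves the mask; exactly zero outside the mask.
#'
#' @param dadt a [VectorField].
#' @param phi a [ScalarPotential] on the same grid.
#' @return a [VectorField] (V/m).
#' @export
totalEfield <- function(dadt, phi) {
  if (!.same_grid(dadt, phi)) stop("dA/dt and potential grids are misaligned")
  g <- potentialGradient(phi)
  vals <- -gridValues(dadt) - gridValues(g)
  m <- as.vector(phi@mask)
  flat <- matrix(vals, ncol = 3L)
  flat[!m, ] <- 0
  vectorField(array(flat, dim(vals)), gridAffine(dadt))
}

#' Masked gradient of a scalar potential
#'
#' Central differences at interior voxels, one-sided at the mask boundary,
#' zero outside the mask.
#'
#' @param phi a [ScalarPotential].
#' @return a [VectorField].
#' @export
potentialGradient <- function(phi) {
  dims <- gridShape(phi)
  h <- .grid_spacing(gridAffine(phi), require_axis_aligned = TRUE)
  mask <- phi@mask
  v <- array(gridValues(phi), dims)
  out <- array(0, c(dims, 3L))
  shift <- function(arr, ax, by) {
    idx <- lapply(dims, seq_len)
    src <- idx
    src[[ax]] <- pmin(pmax(idx[[ax]] + by, 1L), dims[ax])
    do.call(`[`, c(list(arr), src))
  }
  for (ax in 1:3) {
    vp <- shift(v, ax, 1L); vm <- shift(v, ax, -1L)
    mp <- shift(mask, ax, 1L); mm <- shift(mask, ax, -1L)
    # the clamped shift duplicates the border; mark those as unavailable
    edge_hi <- slice.index(v, ax) == dims[ax]
    edge_lo <- slice.index(v, ax) == 1L
    mp <- mp & !edge_hi
    mm <- mm & !edge_lo
    g <- array(0, dims)
    both <- mask & mp & mm
    onlyp <- mask & mp & !mm
    onlym <- mask & !mp & mm
    g[both] <- (vp[both] - vm[both]) / (2 * h[ax])
    g[onlyp] <- (vp[onlyp] - v[onlyp]) / h[ax]
    g[onlym] <- (v[onlym] - vm[onlym]) / h[ax]
    out[, , , ax] <- g
  }
  vectorField(out, gridAffine(phi))
}

# ---------------------------------------------------------------------------
# Training-case assembly
# ---------------------------------------------------------------------------

#' Assemble one ground-truth training case
#'
#' Computes the coil dA/dt on the head grid, solves the potential, forms the
#' total E-field, and crops all channels to a reduced field of view of
#' `fov_shape` voxels centred at the coil's scalp projection. The sample's
#' input concatenates 6 conductivity-tensor channels and 3 dA/dt channels;
#' the target is the 3-channel E-field. An FOV extending beyond the head grid
#' is clipped with zero fill (with a warning).
#'
#' @param head a [HeadGeometry].
#' @param cv a [ConductivityVolume].
#' @param coil a [CoilModel].
#' @param pose a [RigidTransform] coil pose.
#' @param fov_shape integer length-3 reduced-FOV voxel dimensions.
#' @param tol,max_iter solver controls (see [solvePotentialFdm()]).
#' @param id case identifier carried through to datasets.
#' @return a `TrainingSample` list: `input` (fov, 9), `target` (fov, 3),
#'   `mask`, `affine`, `pose`, `id`.
#' @export
groundTruthCase <- function(head, cv, coil, pose, fov_shape = c(24L, 24L, 24L),
                            tol = 1e-8, max_iter = NULL, id = "case") {
  fov_shape <- as.integer(fov_shape)
  dims <- gridShape(cv)
  dadt <- dadtField(coil, pose, cv)
  phi <- solvePotentialFdm(cv, dadt, tol = tol, max_iter = max_iter)
  E <- totalEfield(dadt, phi)

  proj <- coilScalpProjection(head, pose)
  ctr <- round(worldToVoxel(gridAffine(cv), matrix(proj, 1)))[1, ]
  start <- as.integer(ctr - fov_shape %/% 2)  # 0-based start index
  if (any(start < 0L) || any(start + fov_shape > dims))
    warning("reduced FOV extends beyond the head grid; clipped with zero fill")

  input <- array(0, c(fov_shape, 9L))
  input[, , , 1:6] <- .crop_zerofill(gridValues(cv), start, fov_shape)
  input[, , , 7:9] <- .crop_zerofill(gridValues(dadt), start, fov_shape)
  target <- .crop_zerofill(gridValues(E), start, fov_shape)
  mask <- array(.crop_zerofill(array(as.numeric(cv@mask), c(dims, 1L)),
                               start, fov_shape) > 0.5, fov_shape)
  fov_affine <- gridAffine(cv)
  fov_affine[1:3, 4] <- voxelToWorld(gridAffine(cv), matrix(start, 1))[1, ]
  list(input = input, target = target, mask = mask, affine = fov_affine,
       pose = pose, id = id)
}

#' Coil scalp projection point
#'
#' The intersection of the ray from the head centre through the coil origin
#' with the scalp sphere.
#'
#' @param head a [HeadGeometry].
#' @param pose a [RigidTransform].
#' @return length-3 world-mm point.
#' @export
coilScalpProjection <- function(head, pose) {
  t <- transformMatrix(pose)[1:3, 4]
  head@center + head@outer_radius * .unit(t - head@center)
}

.crop_zerofill <- function(arr, start, shape) {
  dims <- dim(arr)[1:3]
  nc <- dim(arr)[4]
  out <- array(0, c(shape, nc))
  src_lo <- pmax(start, 0L) + 1L
  src_hi <- pmin(start + shape, dims)
  if (any(src_hi < src_lo)) return(out)
  dst_lo <- src_lo - start
  dst_hi <- src_hi - start
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3], ] <-
    arr[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3], , drop = FALSE]
  out
}

#' Build a training dataset from coil placements
#'
#' Runs [groundTruthCase()] for every pose in a [PlacementSet].
#'
#' @param head,cv,coil,fov_shape,tol,max_iter as in [groundTruthCase()].
#' @param placements a [PlacementSet].
#' @param verbose print progress.
#' @return list of TrainingSample lists.
#' @export
makeTrainingDataset <- function(head, cv, coil, placements,
                                fov_shape = c(24L, 24L, 24L), tol = 1e-8,
                                max_iter = NULL, verbose = FALSE) {
  n <- length(placements@poses)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (verbose) message(sprintf("case %d/%d (%s, dir %d)", i, n,
                                 placements@site[i], placements@direction[i]))
    out[[i]] <- groundTruthCase(head, cv, coil, placements@poses[[i]],
                                fov_shape, tol, max_iter,
                                id = sprintf("%s_d%03d", placements@site[i],
                                             placements@direction[i]))
  }
  out
}

#' Save and load training datasets
#'
#' Single-file serialized container with one named record per case.
#'
#' @param dataset list of TrainingSample lists.
#' @param path file path (.rds).
#' @return `readTrainingDataset`: the dataset list.
#' @export
saveTrainingDataset <- function(dataset, path) {
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname saveTrainingDataset
#' @export
readTrainingDataset <- function(path) readRDS(path)

#' Physics validation: tangentiality of the induced field
#'
#' In a spherically symmetric conductor the induced E-field has no radial
#' component, and a coaxial circular loop induces no scalar potential at all.
#' On a voxel grid these properties hold up to discretization error, which
#' concentrates in a one-voxel staircase layer at tissue boundaries; the
#' validation therefore targets the cortical compartment (out to the
#' gray-matter radius, or `fraction` of the outer radius when the head has a
#' single shell), the region whose field the pipeline is built to predict.
#'
#' `radialFieldFraction` returns max |r-hat . E| over the compartment divided
#' by max ||E|| over the head mask; `gradientFraction` the analogous ratio
#' max ||grad phi|| / max ||dA/dt||.
#'
#' @param E a [VectorField] (the total E-field).
#' @param head a [HeadGeometry].
#' @param mask logical head-mask array.
#' @param fraction compartment radius as a fraction of the outer radius used
#'   for single-shell heads (default 0.8).
#' @return scalar ratio.
#' @export
radialFieldFraction <- function(E, head, mask, fraction = 0.8) {
  pts <- voxelCenters(E)
  rel <- sweep(pts, 2, head@center)
  r <- sqrt(rowSums(rel^2))
  rhat <- rel / pmax(r, 1e-9)
  ev <- matrix(gridValues(E), ncol = 3L)
  m <- as.vector(mask)
  comp <- m & r <= .cortical_radius(head, fraction)
  max(abs(rowSums(ev * rhat))[comp]) / max(sqrt(rowSums(ev^2))[m])
}

#' @rdname radialFieldFraction
#' @param phi a [ScalarPotential].
#' @param dadt the driving [VectorField].
#' @export
gradientFraction <- function(phi, dadt, head, fraction = 0.8) {
  g <- potentialGradient(phi)
  pts <- voxelCenters(phi)
  r <- sqrt(rowSums(sweep(pts, 2, head@center)^2))
  m <- as.vector(phi@mask)
  comp <- m & r <= .cortical_radius(head, fraction)
  gm <- sqrt(rowSums(matrix(gridValues(g), ncol = 3L)^2))
  am <- sqrt(rowSums(matrix(gridValues(dadt), ncol = 3L)^2))
  max(gm[comp]) / max(am[m])
}

.cortical_radius <- function(head, fraction = 0.8) {
  if (length(head@shell_radii) >= 4L) head@shell_radii[4L]  # gray matter
  else fraction * head@outer_radius
}

#' Paper-scale pipeline configuration
#'
#' The full-resolution configuration used with real segmented heads: 1 mm
#' grids and a reduced field of view of 70 x 90 x 50 voxels. Provided for
#' completeness; the package defaults are desk-scale.
#'
#' @return list with `fov_shape` and `voxel_mm`.
#' @export
paperScaleConfig <- function() list(fov_shape = c(70L, 90L, 50L), voxel_mm = 1)
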