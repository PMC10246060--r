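test_that("the solver reproduces a manufactured gradient-source solution", {
  # uniform ball with a = grad(psi): the exact potential is -psi (zero-mean),
  # since sigma (grad phi + a) = 0 carries no current anywhere
  ball <- uniform_ball()
  cv <- ball$conductivity
  pts <- voxelCenters(cv)
  k <- 0.05
  psi <- sin(k * pts[, 1]) * cos(k * pts[, 2])
  a <- cbind(k * cos(k * pts[, 1]) * cos(k * pts[, 2]),
             -k * sin(k * pts[, 1]) * sin(k * pts[, 2]),
             0)
  da <- vectorField(array(a, c(gridShape(cv), 3)), gridAffine(cv))
  phi <- solvePotentialFdm(cv, da)
  m <- as.vector(cv@mask)
  ph <- as.vector(gridValues(phi))[m]
  target <- -(psi[m] - mean(psi[m]))
  expect_lt(sqrt(sum((ph - target)^2) / sum(target^2)), 5e-3)
  expect_lte(phi@residual, 1e-8)
  # zero-mean gauge and zero outside the mask
  expect_lt(abs(mean(ph)), 1e-12)
  expect_true(all(gridValues(phi)[!cv@mask] == 0))
})

test_that("the potential is invariant under global conductivity scaling", {
  hd <- small_head()
  cv <- hd$conductivity
  da <- dadtField(default_coil(),
                  samplePlacements(hd$geometry, 1L, 12L, seed = 2)@poses[[1]],
                  cv)
  phi1 <- solvePotentialFdm(cv, da)
  cv2 <- new("ConductivityVolume", values = gridValues(cv) * 12.7,
             affine = gridAffine(cv), mask = cv@mask)
  phi2 <- solvePotentialFdm(cv2, da)
  expect_lt(max(abs(gridValues(phi2) - gridValues(phi1))),
            1e-8 * max(abs(gridValues(phi1))))
})

test_that("solver contracts: alignment, convergence and error reporting", {
  hd <- small_head()
  cv <- hd$conductivity
  pose <- samplePlacements(hd$geometry, 1L, 12L, seed = 2)@poses[[1]]
  da <- dadtField(default_coil(), pose, cv)
  misaligned <- vectorField(gridValues(da), centeredAffine(gridShape(cv), 3.1))
  expect_error(solvePotentialFdm(cv, misaligned), "misaligned")
  expect_error(solvePotentialFdm(cv, da, max_iter = 2L), "did not converge")
  phi <- solvePotentialFdm(cv, da)
  expect_lte(phi@residual, 1e-8)
  expect_gt(phi@iterations, 0L)
})

test_that("total E-field assembles -dA/dt - grad(phi), zero outside the mask", {
  hd <- small_head()
  cv <- hd$conductivity
  pose <- samplePlacements(hd$geometry, 1L, 12L, seed = 2)@poses[[1]]
  da <- dadtField(default_coil(), pose, cv)
  # phi = 0 gives E = -dA/dt exactly on the mask
  zero_phi <- new("ScalarPotential", values = array(0, c(gridShape(cv), 1)),
                  affine = gridAffine(cv), mask = cv@mask, residual = 0,
                  iterations = 0L)
  E0 <- totalEfield(da, zero_phi)
  m <- as.vector(cv@mask)
  expect_equal(matrix(gridValues(E0), ncol = 3)[m, ],
               -matrix(gridValues(da), ncol = 3)[m, ])
  expect_true(all(matrix(gridValues(E0), ncol = 3)[!m, ] == 0))
  # E + dA/dt + grad(phi) = 0 pointwise with the same stencil
  phi <- solvePotentialFdm(cv, da)
  E <- totalEfield(da, phi)
  g <- potentialGradient(phi)
  res <- gridValues(E) + gridValues(da) + gridValues(g)
  expect_lt(max(abs(matrix(res, ncol = 3)[m, ])), 1e-12)
})

test_that("E scales linearly with the coil current rate", {
  hd <- small_head()
  cv <- hd$conductivity
  pose <- samplePlacements(hd$geometry, 1L, 12L, seed = 6)@poses[[1]]
  solve_E <- function(didt) {
    coil <- makeFigure8Coil(didt = didt)
    da <- dadtField(coil, pose, cv)
    totalEfield(da, solvePotentialFdm(cv, da))
  }
  E1 <- solve_E(1e6)
  E3 <- solve_E(3e6)
  expect_lt(max(abs(gridValues(E3) - 3 * gridValues(E1))),
            1e-6 * max(abs(gridValues(E1))))
})

test_that("tangentiality violation decreases under grid refinement", {
  coil <- default_coil()
  frac <- sapply(c(24L, 48L, 64L), function(n) {
    sh <- data.frame(radius_mm = 55, sigma = 0.3, tissue = "scalp")
    hd <- makeSphereHead(55, sh, rep(n, 3), 120 / n)
    pose <- coilPoseAtSite(c(0.3, 0.2, 0.93), hd$geometry, 25)
    da <- dadtField(coil, pose, hd$conductivity)
    phi <- solvePotentialFdm(hd$conductivity, da)
    radialFieldFraction(totalEfield(da, phi), hd$geometry, hd$conductivity@mask)
  })
  expect_true(all(diff(frac) < 0))
})

test_that("ground-truth cases carry 9 input and 3 target channels around the coil", {
  hd <- small_head_aniso()
  pose <- samplePlacements(hd$geometry, 1L, 12L, seed = 9)@poses[[1]]
  smp <- groundTruthCase(hd$geometry, hd$conductivity, default_coil(), pose,
                         fov_shape = c(16L, 16L, 16L))
  expect_identical(dim(smp$input), c(16L, 16L, 16L, 9L))
  expect_identical(dim(smp$target), c(16L, 16L, 16L, 3L))
  expect_identical(dim(smp$mask), c(16L, 16L, 16L))
  # target vanishes outside the head mask
  expect_true(all(matrix(smp$target, ncol = 3)[!as.vector(smp$mask), ] == 0))
  # FOV centre voxel lies within one voxel of the coil scalp projection
  ctr_world <- voxelToWorld(smp$affine, matrix(c(16, 16, 16) %/% 2, 1))
  proj <- coilScalpProjection(hd$geometry, pose)
  expect_lt(sqrt(sum((ctr_world - proj)^2)), sqrt(3) * 3 + 1e-9)
  # input channels order: 6 tensor then 3 dA/dt
  da <- dadtField(default_coil(), pose, hd$conductivity)
  expect_equal(smp$input[8, 8, 8, 7:9],
               sampleAtPoints(da, voxelToWorld(smp$affine, matrix(c(7, 7, 7), 1)))[1, ],
               tolerance = 1e-9)
})

test_that("a paper-scale FOV request yields the 70 x 90 x 50 shape", {
  hd <- small_head_aniso()
  pose <- samplePlacements(hd$geometry, 1L, 12L, seed = 9)@poses[[1]]
  fov <- paperScaleConfig()$fov_shape
  expect_identical(fov, c(70L, 90L, 50L))
  expect_warning(
    smp <- groundTruthCase(hd$geometry, hd$conductivity, default_coil(), pose,
                           fov_shape = fov),
    "clipped")
  expect_identical(dim(smp$input), c(70L, 90L, 50L, 9L))
})

test_that("dataset assembly runs one case per placement with stable ids", {
  hd <- small_head_aniso()
  pl <- samplePlacements(hd$geometry, 3L, 12L, seed = 1)
  ds <- suppressWarnings(
    makeTrainingDataset(hd$geometry, hd$conductivity, default_coil(), pl,
                        fov_shape = c(16L, 16L, 16L)))
  expect_length(ds, 3L)
  expect_identical(vapply(ds, `[[`, "", "id"),
                   sprintf("%s_d%03d", pl@site, pl@direction))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "ds.rds")
  saveTrainingDataset(ds, p)
  expect_identical(readTrainingDataset(p), ds)
})
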