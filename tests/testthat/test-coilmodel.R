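test_that("figure-8 construction yields two closed counter-wound loops", {
  coil <- makeFigure8Coil(segments_per_loop = 32L)
  expect_identical(nrow(coilSegments(coil)), 64L)
  # loop closure: chained endpoint gaps below 1e-9 mm (checked per loop)
  s <- coilSegments(coil)
  for (id in 1:2) {
    seg <- s[coil@loop_id == id, ]
    gap <- sqrt(rowSums((seg[c(2:nrow(seg), 1), 1:3] - seg[, 4:6])^2))
    expect_lt(max(gap), 1e-9)
  }
  # net magnetic moment cancels for equal counter-wound loops
  expect_lt(max(abs(coilMoment(coil))), 1e-9 * 27^2)
  expect_error(makeFigure8Coil(loop_center_offset_mm = 0), "> 0")
  expect_error(makeFigure8Coil(loop_radius_mm = -1), "> 0")
  expect_error(makeFigure8Coil(segments_per_loop = 4L), ">= 8")
})

test_that("dA/dt vanishes at a single loop's centre and scales linearly in dI/dt", {
  loop <- makeCircularLoopCoil(radius = 30, segments = 48L, didt = 1e6)
  v <- dadtAtPoints(loop, rigidTransform(diag(4)), matrix(0, 1, 3))
  expect_lt(max(abs(v)), 1e-12)
  pts <- matrix(rnorm(30, sd = 15), 10, 3)
  v1 <- dadtAtPoints(loop, rigidTransform(diag(4)), pts)
  loop2 <- makeCircularLoopCoil(radius = 30, segments = 48L, didt = 2e6)
  v2 <- dadtAtPoints(loop2, rigidTransform(diag(4)), pts)
  expect_identical(v2, 2 * v1)
})

test_that("figure-8 dA/dt matches a 10x refined discretization oracle", {
  grid <- volumeGrid(array(0, c(24, 24, 24, 1)), centeredAffine(c(24, 24, 24), 2.5))
  pose <- composeTransforms(rotationTransform("x", 10),
                            translationTransform(c(5, 3, 70)))
  d1 <- dadtField(makeFigure8Coil(), pose, grid)
  d2 <- dadtField(makeFigure8Coil(segments_per_loop = 640L), pose, grid)
  rel <- sqrt(sum((gridValues(d1) - gridValues(d2))^2) / sum(gridValues(d2)^2))
  expect_lt(rel, 1e-3)
})

test_that("posed evaluation is equivariant with vector-volume transformation", {
  grid <- volumeGrid(array(0, c(24, 24, 24, 1)), centeredAffine(c(24, 24, 24), 2.5))
  coil <- default_coil()
  pose <- composeTransforms(rotationTransform("x", 10),
                            translationTransform(c(5, 3, 70)))
  T <- rotationTransform("z", 35)
  direct <- dadtField(coil, composeTransforms(T, pose), grid)
  moved <- transformVectorVolume(dadtField(coil, pose, grid), T)
  # restrict to voxels whose pre-image stays well inside the grid
  pts <- voxelCenters(grid)
  vox <- worldToVoxel(gridAffine(grid),
                      applyTransform(invertTransform(T), pts))
  interior <- apply(vox >= 1 & vox <= 22, 1, all)
  a <- matrix(gridValues(direct), ncol = 3)[interior, ]
  b <- matrix(gridValues(moved), ncol = 3)[interior, ]
  expect_lt(sqrt(sum((a - b)^2) / sum(a^2)), 1e-2)
})

test_that("field magnitude decays monotonically along the coil axis", {
  coil <- default_coil()
  z <- seq(-30, -150, by = -10)  # below the coil plane, beyond one radius
  v <- dadtAtPoints(coil, rigidTransform(diag(4)), cbind(10, 0, z))
  mag <- sqrt(rowSums(v^2))
  expect_true(all(diff(mag) < 0))
})

test_that("the built-in 10-10 table has 73 unit-norm labelled sites", {
  s <- eeg1010Sites()
  expect_identical(nrow(s), 73L)
  expect_false(any(duplicated(s$label)))
  expect_equal(sqrt(s$x^2 + s$y^2 + s$z^2), rep(1, 73), tolerance = 1e-12)
  expect_true(all(c("Cz", "Fpz", "Oz", "T7", "T8", "F3", "PO10") %in% s$label))
})

test_that("each site enumerates the full set of handle directions before subsetting", {
  head <- small_head()$geometry
  one_site <- eeg1010Sites()[1, ]
  pl <- samplePlacements(head, n_cases = 78L, n_directions = 78L, seed = 1,
                         sites = one_site)
  expect_identical(length(pl@poses), 78L)
  expect_identical(sort(pl@direction), 0:77)
  # step is 360/78 degrees about the site normal
  h0 <- transformMatrix(pl@poses[[which(pl@direction == 0)]])[1:3, 2]
  h1 <- transformMatrix(pl@poses[[which(pl@direction == 1)]])[1:3, 2]
  expect_equal(acos(sum(h0 * h1)) * 180 / pi, 360 / 78, tolerance = 1e-6)
})

test_that("placement sampling is seeded, bounded and produces valid poses", {
  head <- small_head()$geometry
  p1 <- samplePlacements(head, 300L, 78L, seed = 4)
  p2 <- samplePlacements(head, 300L, 78L, seed = 4)
  p3 <- samplePlacements(head, 300L, 78L, seed = 5)
  expect_identical(length(p1@poses), 300L)
  expect_identical(lapply(p1@poses, transformMatrix),
                   lapply(p2@poses, transformMatrix))
  expect_false(identical(lapply(p1@poses, transformMatrix),
                         lapply(p3@poses, transformMatrix)))
  expect_error(samplePlacements(head, 73L * 78L + 1L, 78L, seed = 1), "exceeds")
  ctr <- head@center
  for (pose in p1@poses[1:25]) {
    expect_rigid(pose)
    m <- transformMatrix(pose)
    outward <- (m[1:3, 4] - ctr) / sqrt(sum((m[1:3, 4] - ctr)^2))
    expect_lt(sum(-m[1:3, 3] * outward), 0)  # coil -z faces the head centre
    # coil origin sits at scalp radius + standoff
    expect_equal(sqrt(sum((m[1:3, 4] - ctr)^2)), head@outer_radius + 2,
                 tolerance = 1e-9)
  }
})

test_that("placements and coil geometry export to CSV and STL", {
  dir <- withr::local_tempdir()
  head <- small_head()$geometry
  pl <- samplePlacements(head, 10L, 12L, seed = 2)
  f <- file.path(dir, "pl.csv")
  writePlacementsCsv(pl, f)
  df <- read.csv(f)
  expect_identical(nrow(df), 10L)
  expect_identical(ncol(df), 18L)  # site, direction, 16 matrix entries
  m1 <- matrix(as.numeric(df[1, 3:18]), 4, 4, byrow = TRUE)
  expect_equal(m1, transformMatrix(pl@poses[[1]]), tolerance = 1e-12)
  fs <- file.path(dir, "coil.stl")
  writeCoilStl(default_coil(), fs)
  expect_gt(file.size(fs), 0)
  expect_identical(nrow(meshFaces(readStl(fs))), 2L * nrow(coilSegments(default_coil())))
})
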