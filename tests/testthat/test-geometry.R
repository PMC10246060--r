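test_that("rigid transform construction validates orthonormality", {
  expect_s4_class(rotationTransform("z", 37), "RigidTransform")
  bad <- diag(4); bad[1, 1] <- 2
  expect_error(rigidTransform(bad), "orthonormal")
  refl <- diag(c(-1, 1, 1, 1))
  expect_error(rigidTransform(refl), "determinant")
  expect_error(transformVectorVolume(
    vectorField(array(0, c(4, 4, 4, 3)), diag(4)), bad), "orthonormal")
})

test_that("transform composition and inversion are exact", {
  T1 <- rotationTransform("x", 23, center = c(1, 2, 3))
  T2 <- composeTransforms(rotationTransform("y", -41), translationTransform(c(5, -2, 1)))
  p <- matrix(rnorm(30), 10, 3)
  expect_equal(applyTransform(composeTransforms(T2, T1), p),
               applyTransform(T2, applyTransform(T1, p)))
  expect_equal(applyTransform(composeTransforms(invertTransform(T1), T1), p), p,
               tolerance = 1e-12)
})

test_that("identity transform reproduces a vector field bitwise", {
  set.seed(1)
  f <- vectorField(array(rnorm(8^3 * 3), c(8, 8, 8, 3)),
                   centeredAffine(c(8, 8, 8), 2))
  out <- transformVectorVolume(f, rigidTransform(diag(4)), "nearest")
  expect_identical(gridValues(out), gridValues(f))
})

test_that("rotating a uniform +x field by 90 deg about z yields +y vectors", {
  vals <- array(0, c(9, 9, 9, 3))
  vals[, , , 1] <- 1
  f <- vectorField(vals, centeredAffine(c(9, 9, 9), 2))
  out <- transformVectorVolume(f, rotationTransform("z", 90), "nearest")
  v <- gridValues(out)[3:7, 3:7, 3:7, ]  # interior voxels
  expect_equal(max(abs(v[, , , 1])), 0)
  expect_equal(max(abs(v[, , , 2] - 1)), 0)
  expect_equal(max(abs(v[, , , 3])), 0)
})

test_that("vector magnitude is preserved at lattice-aligned rotations", {
  set.seed(2)
  f <- vectorField(array(rnorm(9^3 * 3), c(9, 9, 9, 3)),
                   centeredAffine(c(9, 9, 9), 2))
  T <- rotationTransform("z", 90)
  out <- transformVectorVolume(f, T, "nearest")
  vin <- sqrt(rowSums(matrix(gridValues(f), ncol = 3)^2))
  vout <- sqrt(rowSums(matrix(gridValues(out), ncol = 3)^2))
  # each output magnitude equals the input magnitude at its lattice pre-image
  pts <- voxelCenters(f)
  src <- round(worldToVoxel(gridAffine(f), applyTransform(invertTransform(T), pts)))
  inb <- apply(src >= 0 & src <= 8, 1, all)
  lin <- src[, 1] + 9 * (src[, 2] + 9 * src[, 3]) + 1
  expect_equal(max(abs(vout[inb] - vin[lin[inb]])), 0)
})

test_that("round trip T then T-inverse reproduces interior voxels (nearest)", {
  set.seed(3)
  vals <- array(0, c(12, 12, 12, 3))
  vals[5:8, 5:8, 5:8, ] <- rnorm(4^3 * 3)   # support away from boundaries
  f <- vectorField(vals, centeredAffine(c(12, 12, 12), 2))
  T <- composeTransforms(rotationTransform("z", 90), translationTransform(c(2, 0, 0)))
  back <- transformVectorVolume(transformVectorVolume(f, T, "nearest"),
                                invertTransform(T), "nearest")
  expect_equal(gridValues(back)[5:8, 5:8, 5:8, ], vals[5:8, 5:8, 5:8, ])
})

test_that("composed transform matches brute-force resampling oracle", {
  set.seed(4)
  f <- vectorField(array(rnorm(10^3 * 3), c(10, 10, 10, 3)),
                   centeredAffine(c(10, 10, 10), 2.5))
  T1 <- rotationTransform("z", 30)
  T2 <- composeTransforms(rotationTransform("x", -20), translationTransform(c(1, 2, -1)))
  T21 <- composeTransforms(T2, T1)
  once <- transformVectorVolume(f, T21, "trilinear")
  # oracle: sample input at composed pre-image, rotate by composed rotation
  pts <- voxelCenters(f)
  src <- applyTransform(invertTransform(T21), pts)
  rec <- oracle_interp(gridValues(f), gridAffine(f), src)
  R <- transformMatrix(T21)[1:3, 1:3]
  expect_equal(matrix(gridValues(once), ncol = 3), rec %*% t(R), tolerance = 1e-12)
})

test_that("resampling onto the identical grid with nearest leaves values unchanged", {
  set.seed(5)
  v <- volumeGrid(array(rnorm(6^3 * 2), c(6, 6, 6, 2)), centeredAffine(c(6, 6, 6), 3))
  out <- resampleToGrid(v, gridShape(v), gridAffine(v), "nearest")
  expect_identical(gridValues(out), gridValues(v))
})

test_that("constant volumes stay constant on in-bounds voxels under resampling", {
  v <- volumeGrid(array(7.5, c(8, 8, 8, 1)), centeredAffine(c(8, 8, 8), 2))
  target_aff <- centeredAffine(c(5, 5, 5), 1.7)
  out <- resampleToGrid(v, c(5, 5, 5), target_aff, "trilinear")
  expect_equal(as.vector(gridValues(out)), rep(7.5, 125))
})

test_that("resampling to a 2x finer grid equals the brute-force oracle exactly", {
  set.seed(6)
  v <- volumeGrid(array(rnorm(8^3), c(8, 8, 8, 1)), centeredAffine(c(8, 8, 8), 2))
  fine_aff <- centeredAffine(c(16, 16, 16), 1)
  out <- resampleToGrid(v, c(16, 16, 16), fine_aff, "trilinear")
  tmp <- volumeGrid(array(0, c(16, 16, 16, 1)), fine_aff)
  rec <- oracle_interp(gridValues(v), gridAffine(v), voxelCenters(tmp))
  expect_equal(as.vector(gridValues(out)), as.vector(rec))
})

test_that("sampleAtPoints matches stored values at voxel centres and the oracle elsewhere", {
  set.seed(7)
  v <- volumeGrid(array(rnorm(8^3 * 3), c(8, 8, 8, 3)), centeredAffine(c(8, 8, 8), 2))
  ctr <- voxelCenters(v)
  rec <- sampleAtPoints(v, ctr, "trilinear")
  expect_equal(rec, matrix(gridValues(v), ncol = 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  pts <- matrix(runif(300, -9, 9), 100, 3)
  expect_equal(sampleAtPoints(v, pts, "trilinear"),
               oracle_interp(gridValues(v), gridAffine(v), pts), tolerance = 1e-12)
  expect_equal(sampleAtPoints(v, pts, "nearest"),
               oracle_interp(gridValues(v), gridAffine(v), pts, nearest = TRUE))
  # out-of-bounds points give zero records
  expect_equal(sampleAtPoints(v, matrix(c(100, 100, 100), 1), "trilinear"),
               matrix(0, 1, 3))
  expect_error(sampleAtPoints(v, matrix(c(NA, 0, 0), 1)), "finite")
})

test_that("resampleToGrid and sampleAtPoints agree at target voxel centres", {
  set.seed(8)
  v <- volumeGrid(array(rnorm(8^3), c(8, 8, 8, 1)), centeredAffine(c(8, 8, 8), 2.2))
  aff <- centeredAffine(c(6, 6, 6), 1.9, center = c(1, -1, 0.5))
  out <- resampleToGrid(v, c(6, 6, 6), aff, "trilinear")
  tmp <- volumeGrid(array(0, c(6, 6, 6, 1)), aff)
  expect_equal(as.vector(gridValues(out)),
               as.vector(sampleAtPoints(v, voxelCenters(tmp), "trilinear")))
})

test_that("field projection onto meshes and streamlines samples identically", {
  set.seed(9)
  f <- vectorField(array(rnorm(10^3 * 3), c(10, 10, 10, 3)),
                   centeredAffine(c(10, 10, 10), 2))
  mesh <- icosphere(6, subdivisions = 1L)
  pm <- projectOntoMesh(f, mesh)
  direct <- sampleAtPoints(f, meshVertices(mesh), "trilinear")
  expect_equal(pm@scalar, sqrt(rowSums(direct^2)))
  sl <- new("Streamlines", lines = list(cbind(seq(-5, 5, length.out = 8), 0, 0)))
  ps <- projectOntoStreamlines(f, sl)
  expect_length(ps, 1)
  expect_equal(ps[[1]],
               sqrt(rowSums(sampleAtPoints(f, sl@lines[[1]], "trilinear")^2)))
})

test_that("volume and mesh formats round-trip through disk", {
  set.seed(10)
  dir <- withr::local_tempdir()
  v <- vectorField(array(rnorm(6^3 * 3), c(6, 6, 6, 3)),
                   centeredAffine(c(6, 6, 6), 2.5, center = c(3, -2, 7)))
  p <- file.path(dir, "v.nii.gz")
  writeNiftiVolume(v, p)
  r <- readNiftiVolume(p)
  expect_s4_class(r, "VectorField")
  expect_equal(gridValues(r), gridValues(v), tolerance = 1e-6)
  expect_equal(gridAffine(r), gridAffine(v), tolerance = 1e-5)

  mesh <- icosphere(10, center = c(1, 2, 3), subdivisions = 1L)
  ps <- file.path(dir, "m.stl")
  writeStl(mesh, ps)
  ms <- readStl(ps)
  expect_equal(nrow(meshFaces(ms)), nrow(meshFaces(mesh)))
  expect_true(meshIsClosed(ms))

  mesh@scalar <- seq_len(nrow(meshVertices(mesh))) * 1.5
  pp <- file.path(dir, "m.ply")
  writePly(mesh, pp)
  mp <- readPly(pp)
  expect_equal(meshVertices(mp), meshVertices(mesh), ignore_attr = TRUE)
  expect_equal(mp@scalar, mesh@scalar)

  sl <- makeSyntheticStreamlines(small_head()$geometry, 5, 12, seed = 2)
  pj <- file.path(dir, "s.json")
  writeStreamlinesJson(sl, pj)
  rs <- readStreamlinesJson(pj)
  expect_equal(rs@lines, lapply(sl@lines, unname))

  T <- composeTransforms(rotationTransform("y", 12), translationTransform(c(1, 2, 3)))
  pt <- file.path(dir, "t.txt")
  writeTransformText(T, pt)
  expect_equal(transformMatrix(readTransformText(pt)), transformMatrix(T),
               tolerance = 1e-15)
})
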