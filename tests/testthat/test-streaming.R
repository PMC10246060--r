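test_that("wire layout: 58-byte header and 48-byte TRANSFORM body", {
  pose <- composeTransforms(rotationTransform("z", 40), translationTransform(c(1, 2, 3)))
  raw <- encodeMessage("TRANSFORM", pose, timestamp = c(1700000000, 123456789))
  expect_identical(length(raw), 58L + 48L)
  msg <- decodeMessage(raw)
  expect_identical(length(msg@body), 48L)
  expect_identical(msg@version, 2L)
  expect_identical(msg@ts_sec, 1700000000)
  expect_identical(msg@ts_nsec, 123456789)
  expect_error(encodeMessage("TRANSFORM", pose,
                             device_name = "a-device-name-way-too-long"),
               "20 characters")
})

test_that("messages round-trip for randomized transforms and images", {
  set.seed(30)
  for (i in 1:10) {
    pose <- composeTransforms(
      rotationTransform(rnorm(3), runif(1, -180, 180)),
      translationTransform(rnorm(3, sd = 40)))
    raw <- encodeMessage("TRANSFORM", pose, device_name = sprintf("dev%02d", i),
                         timestamp = c(i * 1e6, i))
    msg <- decodeMessage(raw)
    expect_identical(msg@type_name, "TRANSFORM")
    expect_identical(msg@device_name, sprintf("dev%02d", i))
    # float32 wire precision for the pose
    expect_equal(transformMatrix(messageTransform(msg)),
                 transformMatrix(pose), tolerance = 1e-6)
  }
  img <- volumeGrid(array(rnorm(5 * 4 * 3), c(5, 4, 3, 1)),
                    diag(c(2.5, 2.5, 2.5, 1)))
  msg <- decodeMessage(encodeMessage("IMAGE", img))
  back <- messageImage(msg)
  expect_identical(gridShape(back), c(5L, 4L, 3L))
  expect_identical(gridValues(back), gridValues(img))  # float64 voxels
  expect_equal(gridAffine(back), gridAffine(img), tolerance = 1e-6)
})

test_that("corruption, truncation and unknown types are rejected", {
  raw <- encodeMessage("TRANSFORM", rigidTransform(diag(4)))
  bad <- raw
  bad[70] <- xor(bad[70], as.raw(1))
  expect_error(decodeMessage(bad), "CRC")
  expect_error(decodeMessage(raw[1:57]), "58 header bytes")
  expect_error(decodeMessage(raw[1:80]), "truncated")
  unk <- raw
  unk[3:14] <- c(charToRaw("POSITION"), raw(4))
  expect_error(decodeMessage(unk), "unsupported")
})

test_that("a concatenated stream parses into its constituent messages", {
  img <- volumeGrid(array(1:24 * 1.0, c(2, 3, 4, 1)), diag(4))
  raw <- c(encodeMessage("TRANSFORM", rigidTransform(diag(4))),
           encodeMessage("IMAGE", img))
  msgs <- decodeMessageStream(raw)
  expect_length(msgs, 2L)
  expect_identical(vapply(msgs, function(m) m@type_name, ""),
                   c("TRANSFORM", "IMAGE"))
  expect_error(decodeMessageStream(raw[1:100]), "truncated|trailing")
})

test_that("the server answers each pose with the surrogate's magnitude image", {
  hd <- small_head_aniso()
  model <- toy_model()
  coil <- default_coil()
  poses <- samplePlacements(hd$geometry, 4L, 12L, seed = 8)@poses
  ses <- runSession(model, hd$geometry, hd$conductivity, coil, poses,
                    fov_shape = c(16L, 16L, 16L))
  expect_identical(ses$stats$n_runs, 4L)
  expect_length(ses$images, 4L)
  expect_identical(nrow(ses$stats$runs), 4L)
  expect_true(all(c("cnn_seconds", "vis_seconds") %in% names(ses$stats$runs)))
  expect_true(all(ses$stats$runs$cnn_seconds >= 0))
  expect_true(all(ses$stats$runs$vis_seconds >= 0))
  # streamed magnitudes equal the direct prediction path bit-for-bit
  for (i in seq_along(poses)) {
    q <- messageTransform(decodeMessage(encodeMessage("TRANSFORM", poses[[i]])))
    fov <- tmsfield:::.fov_inputs(hd$geometry, hd$conductivity, coil, q,
                                  c(16L, 16L, 16L))
    direct <- predictEfield(model, fov$sigma, gridValues(fov$dadt))
    expect_identical(gridValues(ses$images[[i]]), gridValues(direct$magnitude))
  }
  # pose-deterministic: an identical session reproduces identical images
  ses2 <- runSession(model, hd$geometry, hd$conductivity, coil, poses,
                     fov_shape = c(16L, 16L, 16L))
  for (i in seq_along(poses))
    expect_identical(gridValues(ses2$images[[i]]), gridValues(ses$images[[i]]))
})

test_that("malformed frames get an error reply and the loop continues", {
  hd <- small_head_aniso()
  model <- toy_model()
  coil <- default_coil()
  pose <- samplePlacements(hd$geometry, 1L, 12L, seed = 8)@poses[[1]]
  tr <- localTransport()
  tr$client$send(as.raw(1:70))   # garbage frame
  tr$client$send(encodeMessage("TRANSFORM", pose))
  stats <- runServerLoop(model, hd$geometry, hd$conductivity, coil, tr$server,
                         n_runs = 1L, fov_shape = c(16L, 16L, 16L))
  expect_identical(stats$n_runs, 1L)
  err <- decodeMessage(tr$client$recv())
  expect_identical(err@device_name, "ERROR")
  expect_identical(err@type_name, "TRANSFORM")
  reply <- decodeMessage(tr$client$recv())
  expect_identical(reply@type_name, "IMAGE")
  # transport loss: requesting more runs than frames aborts with partial stats
  tr2 <- localTransport()
  tr2$client$send(encodeMessage("TRANSFORM", pose))
  expect_warning(
    partial <- runServerLoop(model, hd$geometry, hd$conductivity, coil,
                             tr2$server, n_runs = 3L, fov_shape = c(16L, 16L, 16L)),
    "partial")
  expect_identical(partial$n_runs, 1L)
})
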