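# Shared fixtures, built in code and memoised across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small multi-shell head (binary tensors, per the generator contract)
small_head <- function() fixture("small_head", function() {
  makeSphereHead(40, defaultShells(40), c(32L, 32L, 32L), 3)
})

# anisotropic version of the small head
small_head_aniso <- function() fixture("small_head_aniso", function() {
  hd <- small_head()
  cv <- randomizeConductivityTensors(
    hd$conductivity, wm_shell = c(0, min(hd$geometry@shell_radii)),
    anisotropy_ratio = 3, seed = 7)
  list(conductivity = cv, geometry = hd$geometry)
})

# uniform single-shell conducting ball (symmetry oracles)
uniform_ball <- function() fixture("uniform_ball", function() {
  sh <- data.frame(radius_mm = 55, sigma = 0.3, tissue = "scalp")
  makeSphereHead(55, sh, c(48L, 48L, 48L), 2.5)
})

default_coil <- function() fixture("default_coil", function() makeFigure8Coil())

# a small real training dataset (16 cases, 16^3 FOV) for surrogate unit tests
toy_dataset <- function() fixture("toy_dataset", function() {
  hd <- small_head_aniso()
  coil <- default_coil()
  pl <- samplePlacements(hd$geometry, 16L, 12L, seed = 3)
  suppressWarnings(makeTrainingDataset(hd$geometry, hd$conductivity, coil, pl,
                                       fov_shape = c(16L, 16L, 16L)))
})

toy_model <- function() fixture("toy_model", function() {
  trainSurrogate(toy_dataset()[1:12],
                 surrogateConfig(levels = 3L, base_channels = 4L,
                                 epochs = 200L, seed = 5L))
})

# independent brute-force interpolation oracle (pure R, 8-neighbour weights)
oracle_interp <- function(vals, affine, points, nearest = FALSE) {
  d <- dim(vals)
  inv <- solve(affine)
  out <- matrix(0, nrow(points), d[4])
  for (p in seq_len(nrow(points))) {
    v <- (inv %*% c(points[p, ], 1))[1:3]
    if (nearest) {
      i <- round(v)
      if (all(i >= 0) && all(i <= d[1:3] - 1))
        out[p, ] <- vals[i[1] + 1, i[2] + 1, i[3] + 1, ]
    } else {
      f <- floor(v)
      w <- v - f
      for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
        idx <- f + c(di, dj, dk)
        if (any(idx < 0) || any(idx > d[1:3] - 1)) next
        ww <- prod(ifelse(c(di, dj, dk) == 1, w, 1 - w))
        out[p, ] <- out[p, ] + ww * vals[idx[1] + 1, idx[2] + 1, idx[3] + 1, ]
      }
    }
  }
  out
}

expect_rigid <- function(pose) {
  R <- transformMatrix(pose)[1:3, 1:3]
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
  expect_gt(det(R), 0)
}
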