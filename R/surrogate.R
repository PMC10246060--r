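# Volumetric E-field surrogate: a multi-scale residual 3D U-Net mapping the
# 9-channel (6 conductivity-tensor + 3 dA/dt) reduced-FOV input to the
# 3-channel E-field, trained with Adam on a deep-supervision loss (vector MSE
# at the full resolution plus auxiliary predictions at the coarser decoder
# scales). Convolutions run through the package's im2col+GEMM kernels; the
# backward pass is hand-derived and verified against finite differences in
# the test suite.

#' Surrogate training configuration
#'
#' @param levels number of resolution levels (>= 2, default 3). Input spatial
#'   dims must be divisible by 2^(levels-1).
#' @param base_channels channels at full resolution, doubled per level
#'   (default 4, sized for CPU training).
#' @param epochs training epochs.
#' @param batch_size minibatch size (default 4).
#' @param lr peak Adam learning rate; the schedule is a linear warmup over
#'   `warmup_frac` of the steps followed by cosine decay to zero.
#' @param warmup_frac warmup fraction (default 0.05).
#' @param loss_weights deep-supervision weights, full resolution first
#'   (default 1, 0.5, 0.25).
#' @param seed RNG seed; recorded in outputs, makes training bitwise
#'   reproducible.
#' @return a validated config list.
#' @export
surrogateConfig <- function(levels = 3L, base_channels = 4L, epochs = 100L,
                            batch_size = 4L, lr = 3e-3, warmup_frac = 0.05,
                            loss_weights = c(1, 0.5, 0.25), seed = 1L) {
  if (levels < 2L) stop("levels must be >= 2")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (length(loss_weights) < levels) stop("need one loss weight per level")
  list(levels = as.integer(levels), base_channels = as.integer(base_channels),
       epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr = lr, warmup_frac = warmup_frac,
       loss_weights = loss_weights[seq_len(levels)], seed = as.integer(seed))
}

# -- network definition ------------------------------------------------------

.layer <- function(cin, cout, k, stride = 1L, scale = 1) {
  K <- cin * k^3
  sd <- scale * sqrt(2 / K)
  list(w = matrix(rnorm(cout * K, sd = sd), cout, K),
       b = numeric(cout), k = k, pad = if (k == 3L) 1L else 0L,
       stride = as.integer(stride), cin = cin, cout = cout)
}

.init_net <- function(config, in_channels = 9L, out_channels = 3L) {
  L <- config$levels
  ch <- config$base_channels * 2^(0:(L - 1))
  net <- list()
  net$stem <- .layer(in_channels, ch[1], 3L)
  for (l in 0:(L - 1)) net[[sprintf("enc%d", l)]] <- .layer(ch[l + 1], ch[l + 1], 3L)
  for (l in 1:(L - 1)) net[[sprintf("down%d", l)]] <- .layer(ch[l], ch[l + 1], 3L, stride = 2L)
  for (l in 0:(L - 2)) {
    net[[sprintf("up%d", l)]] <- .layer(ch[l + 2], ch[l + 1], 3L)
    net[[sprintf("dec%d", l)]] <- .layer(ch[l + 1], ch[l + 1], 3L)
  }
  for (l in 0:(L - 1)) net[[sprintf("head%d", l)]] <- .layer(ch[l + 1], out_channels, 1L, scale = 0.1)
  net
}

.conv_fwd <- function(layer, x) {
  cpp_conv3d_fwd(x, dim(x), layer$w, layer$b, layer$k, layer$pad, layer$stride)
}

.conv_bwd <- function(layer, x, gy) {
  cpp_conv3d_bwd(x, dim(x), layer$w, gy, dim(gy), layer$k, layer$pad, layer$stride)
}

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

# forward pass; returns activations needed for the backward pass
.net_forward <- function(net, x, L) {
  cache <- list(x = x, e = vector("list", L), d = vector("list", L),
                u = vector("list", L), upre = vector("list", L),
                ups = vector("list", L), f = vector("list", L),
                aux = vector("list", L))
  a0 <- .relu(.conv_fwd(net$stem, x))
  cache$a0 <- a0
  prev <- a0
  for (l in 0:(L - 1)) {
    if (l > 0) {
      dl <- .relu(.conv_fwd(net[[sprintf("down%d", l)]], prev))
      cache$d[[l + 1]] <- dl
      prev <- dl
    }
    el <- .relu(prev + .conv_fwd(net[[sprintf("enc%d", l)]], prev))
    cache$e[[l + 1]] <- el
    prev <- el
  }
  f <- cache$e[[L]]
  cache$f[[L]] <- f
  cache$aux[[L]] <- .conv_fwd(net[[sprintf("head%d", L - 1)]], f)
  for (l in (L - 2):0) {
    ups <- cpp_upsample2_fwd(f, dim(f))
    upre <- .conv_fwd(net[[sprintf("up%d", l)]], ups)
    u <- .relu(upre) + cache$e[[l + 1]]
    f <- .relu(u + .conv_fwd(net[[sprintf("dec%d", l)]], u))
    cache$ups[[l + 1]] <- ups
    cache$upre[[l + 1]] <- upre
    cache$u[[l + 1]] <- u
    cache$f[[l + 1]] <- f
    cache$aux[[l + 1]] <- .conv_fwd(net[[sprintf("head%d", l)]], f)
  }
  cache
}

# multi-scale targets: y at full resolution, average-pooled per extra level
.pyramid_targets <- function(y, L) {
  ys <- vector("list", L)
  ys[[1]] <- y
  for (l in 2:L) ys[[l]] <- cpp_avgpool2_fwd(ys[[l - 1]], dim(ys[[l - 1]]))
  ys
}

# loss + full backward pass; returns list(loss, grads) with grads mirroring net
.net_backward <- function(net, cache, ys, weights, L) {
  grads <- lapply(net, function(p) list(w = p$w * 0, b = p$b * 0))
  loss <- 0
  gf <- vector("list", L)
  for (l in 0:(L - 1)) {
    aux <- cache$aux[[l + 1]]
    diff <- aux - ys[[l + 1]]
    loss <- loss + weights[l + 1] * mean(diff^2)
    gaux <- (2 * weights[l + 1] / length(diff)) * diff
    dim(gaux) <- dim(aux)
    hl <- sprintf("head%d", l)
    bwd <- .conv_bwd(net[[hl]], cache$f[[l + 1]], gaux)
    grads[[hl]]$w <- grads[[hl]]$w + bwd$gw
    grads[[hl]]$b <- grads[[hl]]$b + bwd$gb
    gf[[l + 1]] <- bwd$gx
  }
  ge <- vector("list", L)
  # decoder, from full resolution upward
  for (l in 0:(L - 2)) {
    f <- cache$f[[l + 1]]
    u <- cache$u[[l + 1]]
    gsum <- gf[[l + 1]] * (f > 0)
    dl <- sprintf("dec%d", l)
    bwd <- .conv_bwd(net[[dl]], u, gsum)
    grads[[dl]]$w <- grads[[dl]]$w + bwd$gw
    grads[[dl]]$b <- grads[[dl]]$b + bwd$gb
    gu <- gsum + bwd$gx
    ge[[l + 1]] <- gu   # additive skip from the encoder
    gupre <- gu * (cache$upre[[l + 1]] > 0)
    ul <- sprintf("up%d", l)
    bwd <- .conv_bwd(net[[ul]], cache$ups[[l + 1]], gupre)
    grads[[ul]]$w <- grads[[ul]]$w + bwd$gw
    grads[[ul]]$b <- grads[[ul]]$b + bwd$gb
    gups <- cpp_upsample2_bwd(bwd$gx, dim(cache$f[[l + 2]]))
    gf[[l + 2]] <- gf[[l + 2]] + gups
  }
  ge[[L]] <- if (is.null(ge[[L]])) gf[[L]] else ge[[L]] + gf[[L]]
  # encoder, from the bottleneck downward
  for (l in (L - 1):0) {
    el <- cache$e[[l + 1]]
    prev <- if (l > 0) cache$d[[l + 1]] else cache$a0
    gsum <- ge[[l + 1]] * (el > 0)
    enl <- sprintf("enc%d", l)
    bwd <- .conv_bwd(net[[enl]], prev, gsum)
    grads[[enl]]$w <- grads[[enl]]$w + bwd$gw
    grads[[enl]]$b <- grads[[enl]]$b + bwd$gb
    gprev <- gsum + bwd$gx
    if (l > 0) {
      gdpre <- gprev * (cache$d[[l + 1]] > 0)
      dwl <- sprintf("down%d", l)
      bwd <- .conv_bwd(net[[dwl]], cache$e[[l]], gdpre)
      grads[[dwl]]$w <- grads[[dwl]]$w + bwd$gw
      grads[[dwl]]$b <- grads[[dwl]]$b + bwd$gb
      ge[[l]] <- if (is.null(ge[[l]])) bwd$gx else ge[[l]] + bwd$gx
    } else {
      gstem <- gprev * (cache$a0 > 0)
      bwd <- .conv_bwd(net$stem, cache$x, gstem)
      grads$stem$w <- grads$stem$w + bwd$gw
      grads$stem$b <- grads$stem$b + bwd$gb
    }
  }
  list(loss = loss, grads = grads)
}

# -- training ----------------------------------------------------------------

# samples (FOV arrays, spatial-last) -> net layout (C, D, H, W)
.to_net <- function(arr) aperm(arr, c(4, 1, 2, 3))

.stack_batch <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(0, c(d, length(lst)))
  for (i in seq_along(lst)) out[, , , , i] <- lst[[i]]
  out
}

#' Train the E-field surrogate
#'
#' Deterministic given `config$seed`: weight initialization and epoch
#' shuffling draw from one seeded stream. Inputs are z-scored per channel and
#' the target is scaled to unit RMS; both statistics are stored with the
#' model and undone at prediction time.
#'
#' @param dataset list of TrainingSample lists (see [groundTruthCase()]).
#' @param config a [surrogateConfig()].
#' @param verbose print per-epoch loss.
#' @return a [TrainedSurrogate].
#' @export
trainSurrogate <- function(dataset, config = surrogateConfig(), verbose = FALSE) {
  if (length(dataset) < 2L) stop("need at least 2 training samples")
  L <- config$levels
  shp <- dim(dataset[[1]]$input)[1:3]
  for (smp in dataset) {
    if (!identical(dim(smp$input)[1:3], shp) || !identical(dim(smp$target)[1:3], shp))
      stop("inconsistent sample shapes in dataset")
  }
  if (any(shp %% 2^(L - 1) != 0))
    stop(sprintf("FOV dims must be divisible by %d for %d levels", 2^(L - 1), L))

  xs <- lapply(dataset, function(smp) .to_net(smp$input))
  ys <- lapply(dataset, function(smp) .to_net(smp$target))

  # per-channel z-score statistics on the training inputs
  nch <- dim(xs[[1]])[1]
  chsum <- numeric(nch); chsq <- numeric(nch); nel <- 0
  tsq <- 0; tn <- 0
  for (i in seq_along(xs)) {
    m <- matrix(xs[[i]], nrow = nch)
    chsum <- chsum + rowSums(m)
    chsq <- chsq + rowSums(m^2)
    nel <- nel + ncol(m)
    tsq <- tsq + sum(ys[[i]]^2); tn <- tn + length(ys[[i]])
  }
  chmean <- chsum / nel
  chsd <- sqrt(pmax(chsq / nel - chmean^2, 0))
  chsd[chsd < 1e-12] <- 1
  tscale <- sqrt(tsq / tn)
  if (tscale == 0) stop("dataset target is identically zero")
  norm <- list(mean = chmean, sd = chsd, target_scale = tscale)

  for (i in seq_along(xs)) {
    xs[[i]] <- (xs[[i]] - chmean) / chsd   # recycles over the channel axis
    ys[[i]] <- ys[[i]] / tscale
  }

  n <- length(xs)
  steps_per_epoch <- ceiling(n / config$batch_size)
  total_steps <- steps_per_epoch * config$epochs
  warm <- max(1L, ceiling(config$warmup_frac * total_steps))

  hist_loss <- numeric(config$epochs)
  hist_ne <- numeric(config$epochs)
  hist_lr <- numeric(config$epochs)

  .with_seed(config$seed, {
    net <- .init_net(config, in_channels = nch)
    madam <- lapply(net, function(p) list(w = p$w * 0, b = p$b * 0))
    vadam <- lapply(net, function(p) list(w = p$w * 0, b = p$b * 0))
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ne_num <- 0; ne_den <- 0
      for (bs in seq_len(steps_per_epoch)) {
        idx <- ord[((bs - 1L) * config$batch_size + 1L):min(bs * config$batch_size, n)]
        x <- .stack_batch(xs[idx])
        y <- .stack_batch(ys[idx])
        step <- step + 1L
        lr_t <- if (step <= warm) config$lr * step / warm
                else config$lr * 0.5 * (1 + cos(pi * (step - warm) / max(1L, total_steps - warm)))
        cache <- .net_forward(net, x, L)
        yt <- .pyramid_targets(y, L)
        bwd <- .net_backward(net, cache, yt, config$loss_weights, L)
        if (!is.finite(bwd$loss))
          stop(sprintf("non-finite loss at epoch %d step %d (lr %.3g); aborting", epoch, bs, lr_t))
        ep_loss <- ep_loss + bwd$loss
        pred <- cache$aux[[1]]
        ne_num <- ne_num + sum((pred - y)^2)
        ne_den <- ne_den + sum(y^2)
        for (nm in names(net)) {
          g <- bwd$grads[[nm]]
          madam[[nm]]$w <- beta1 * madam[[nm]]$w + (1 - beta1) * g$w
          madam[[nm]]$b <- beta1 * madam[[nm]]$b + (1 - beta1) * g$b
          vadam[[nm]]$w <- beta2 * vadam[[nm]]$w + (1 - beta2) * g$w^2
          vadam[[nm]]$b <- beta2 * vadam[[nm]]$b + (1 - beta2) * g$b^2
          bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
          net[[nm]]$w <- net[[nm]]$w - lr_t * (madam[[nm]]$w / bc1) / (sqrt(vadam[[nm]]$w / bc2) + eps)
          net[[nm]]$b <- net[[nm]]$b - lr_t * (madam[[nm]]$b / bc1) / (sqrt(vadam[[nm]]$b / bc2) + eps)
        }
      }
      hist_loss[epoch] <- ep_loss / steps_per_epoch
      hist_ne[epoch] <- sqrt(ne_num / ne_den)
      hist_lr[epoch] <- lr_t
      if (verbose)
        message(sprintf("epoch %3d/%d  loss %.5g  NE %.4f  lr %.2g",
                        epoch, config$epochs, hist_loss[epoch], hist_ne[epoch], lr_t))
    }
    new("TrainedSurrogate", params = net, config = config, norm = norm,
        history = data.frame(epoch = seq_len(config$epochs), lr = hist_lr,
                             loss = hist_loss, ne = hist_ne))
  })
}

#' Predict the E-field for one case
#'
#' Deterministic inference: normalizes the 9-channel input with the stored
#' statistics, runs the network, and un-scales the output.
#'
#' @param model a [TrainedSurrogate].
#' @param sigma conductivity input: a [ConductivityVolume] (cropped to the
#'   training FOV) or a (fov, 6) array.
#' @param dadt a [VectorField] on the same FOV or a (fov, 3) array.
#' @return list with `efield` (a [VectorField]), `magnitude` (a scalar
#'   [VolumeGrid], the per-voxel Euclidean norm) and `affine`.
#' @export
predictEfield <- function(model, sigma, dadt) {
  aff <- diag(4)
  if (is(sigma, "VolumeGrid")) { aff <- gridAffine(sigma); sigma <- gridValues(sigma) }
  if (is(dadt, "VolumeGrid")) { aff <- gridAffine(dadt); dadt <- gridValues(dadt) }
  if (dim(sigma)[4] + dim(dadt)[4] != 9L)
    stop("input must provide 9 channels (6 tensor + 3 dA/dt)")
  input <- array(0, c(dim(sigma)[1:3], 9L))
  input[, , , 1:6] <- sigma
  input[, , , 7:9] <- dadt
  x <- .to_net(input)
  x <- (x - model@norm$mean) / model@norm$sd
  dim(x) <- c(dim(x), 1L)
  cache <- .net_forward(model@params, x, model@config$levels)
  pred <- cache$aux[[1]] * model@norm$target_scale
  dim(pred) <- dim(pred)[1:4]
  vals <- aperm(pred, c(2, 3, 4, 1))
  ef <- vectorField(vals, aff)
  list(efield = ef, magnitude = fieldMagnitude(ef), affine = aff)
}

#' Normalized root-mean-square error between vector fields
#'
#' NE = sqrt( sum_mask ||E_pred - E_true||^2 / sum_mask ||E_true||^2 ).
#' 0 for a perfect prediction; 1 for the zero predictor.
#'
#' @param pred,truth [VectorField]s or (d, 3) arrays of matching shape.
#' @param mask optional logical array restricting the sums.
#' @return scalar NE.
#' @export
neMetric <- function(pred, truth, mask = NULL) {
  if (is(pred, "VolumeGrid")) pred <- gridValues(pred)
  if (is(truth, "VolumeGrid")) truth <- gridValues(truth)
  if (!identical(dim(pred), dim(truth))) stop("pred and truth shapes differ")
  pm <- matrix(pred, ncol = 3L)
  tm <- matrix(truth, ncol = 3L)
  if (!is.null(mask)) {
    pm <- pm[as.vector(mask), , drop = FALSE]
    tm <- tm[as.vector(mask), , drop = FALSE]
  }
  den <- sum(tm^2)
  if (den == 0) stop("NE undefined: ground-truth field has zero energy on the mask")
  sqrt(sum((pm - tm)^2) / den)
}

#' Evaluate a surrogate on a set of cases
#'
#' @param model a [TrainedSurrogate].
#' @param dataset list of TrainingSample lists.
#' @return list with `per_case` (data.frame id, ne), `mean`, `sd`.
#' @export
evaluateSurrogate <- function(model, dataset) {
  ne <- vapply(dataset, function(smp) {
    pred <- predictEfield(model, smp$input[, , , 1:6, drop = FALSE],
                          smp$input[, , , 7:9, drop = FALSE])
    neMetric(gridValues(pred$efield), smp$target, smp$mask)
  }, numeric(1))
  list(per_case = data.frame(id = vapply(dataset, `[[`, "", "id"), ne = ne),
       mean = mean(ne), sd = if (length(ne) > 1) sd(ne) else 0)
}

#' Save and load surrogate checkpoints
#'
#' Single-file archive holding weights, config, normalization statistics and
#' the training history.
#'
#' @param model a [TrainedSurrogate].
#' @param path file path (.rds).
#' @return `readSurrogate`: the model.
#' @export
saveSurrogate <- function(model, path) {
  saveRDS(list(params = model@params, config = model@config,
               norm = model@norm, history = model@history), path)
  invisible(path)
}

#' @rdname saveSurrogate
#' @export
readSurrogate <- function(path) {
  x <- readRDS(path)
  new("TrainedSurrogate", params = x$params, config = x$config,
      norm = x$norm, history = x$history)
}

#' Write a training history as CSV
#'
#' @param model a [TrainedSurrogate].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeHistoryCsv <- function(model, path) {
  write.csv(model@history, path, row.names = FALSE)
  invisible(path)
}
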