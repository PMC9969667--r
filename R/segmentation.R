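## The apex segmentation network: a slim 4-level U-Net style encoder-decoder.
## Three 2x2 max-pool downsamples halve each spatial dimension (so a 640x480
## input reaches an 80x60 bottleneck), three nearest-neighbour upsamples with
## 3x3 convolutions restore resolution, and skip connections concatenate
## equal-resolution encoder and decoder feature maps. All convolutions are
## 3x3; hidden activations are ReLU and the single-channel output is sigmoid.

.convLayerInit <- function(Cin, Cout) {
  sd <- sqrt(2 / (9 * Cin))
  list(k = lapply(1:9, function(i) matrix(stats::rnorm(Cin * Cout, 0, sd),
                                          Cin, Cout)),
       b = numeric(Cout))
}

.layerPlan <- function(base) {
  C <- base * c(1L, 2L, 4L, 8L)
  list(enc1a = c(3L, C[1L]),        enc1b = c(C[1L], C[1L]),
       enc2a = c(C[1L], C[2L]),     enc2b = c(C[2L], C[2L]),
       enc3a = c(C[2L], C[3L]),     enc3b = c(C[3L], C[3L]),
       bot1  = c(C[3L], C[4L]),     bot2  = c(C[4L], C[4L]),
       up3   = c(C[4L], C[3L]),
       dec3a = c(2L * C[3L], C[3L]), dec3b = c(C[3L], C[3L]),
       up2   = c(C[3L], C[2L]),
       dec2a = c(2L * C[2L], C[2L]), dec2b = c(C[2L], C[2L]),
       up1   = c(C[2L], C[1L]),
       dec1a = c(2L * C[1L], C[1L]), dec1b = c(C[1L], C[1L]),
       outc  = c(C[1L], 1L))
}

#' Build the apex segmentation network
#'
#' Constructs the 4-level U-Net style network with randomly initialized
#' parameters (He initialization, deterministic under \code{seed}). Channel
#' widths double per level: \code{baseChannels} x (1, 2, 4, 8).
#'
#' @param baseChannels channels of the first level; 16 is the full-scale
#'   default, smaller values give a reduced-width network for fast CPU runs.
#' @param seed integer seed for parameter initialization.
#' @return An \linkS4class{ApexModel}.
#' @export
buildNetwork <- function(baseChannels = 16L, seed = 1L) {
  stopifnot(baseChannels >= 1L)
  set.seed(seed)
  plan <- .layerPlan(as.integer(baseChannels))
  params <- lapply(plan, function(d) .convLayerInit(d[1L], d[2L]))
  new("ApexModel",
      config = list(levels = 4L, baseChannels = as.integer(baseChannels),
                    kernel = 3L, inputChannels = 3L),
      params = params, seed = as.integer(seed))
}

## forward pass on an (H*W) x 3 matrix; H, W divisible by 8
.netForward <- function(pl, X, H, W, keepCache = FALSE) {
  if (H %% 8L != 0L || W %% 8L != 0L)
    stop(sprintf(paste0("input %dx%d is not divisible by %d: three halvings ",
                        "require both dimensions to be multiples of 8"),
                 W, H, 8L), call. = FALSE)
  C1 <- ncol(pl$enc1a$k[[1L]]); C2 <- ncol(pl$enc2a$k[[1L]])
  C3 <- ncol(pl$enc3a$k[[1L]])
  t1 <- .shiftTables(H, W); t2 <- .shiftTables(H %/% 2L, W %/% 2L)
  t4 <- .shiftTables(H %/% 4L, W %/% 4L)
  t8 <- .shiftTables(H %/% 8L, W %/% 8L)
  pt1 <- .poolTables(H, W); pt2 <- .poolTables(H %/% 2L, W %/% 2L)
  pt4 <- .poolTables(H %/% 4L, W %/% 4L)
  u8 <- .upTables(H %/% 8L, W %/% 8L); u4 <- .upTables(H %/% 4L, W %/% 4L)
  u2 <- .upTables(H %/% 2L, W %/% 2L)

  e1a <- .relu(.convFwd(pl$enc1a, X, t1))
  e1b <- .relu(.convFwd(pl$enc1b, e1a, t1))
  p1 <- .poolFwd(e1b, pt1)
  e2a <- .relu(.convFwd(pl$enc2a, p1$out, t2))
  e2b <- .relu(.convFwd(pl$enc2b, e2a, t2))
  p2 <- .poolFwd(e2b, pt2)
  e3a <- .relu(.convFwd(pl$enc3a, p2$out, t4))
  e3b <- .relu(.convFwd(pl$enc3b, e3a, t4))
  p3 <- .poolFwd(e3b, pt4)
  b1 <- .relu(.convFwd(pl$bot1, p3$out, t8))
  b2 <- .relu(.convFwd(pl$bot2, b1, t8))
  u3c <- .relu(.convFwd(pl$up3, .upFwd(b2, u8), t4))
  c3 <- cbind(e3b, u3c)
  d3a <- .relu(.convFwd(pl$dec3a, c3, t4))
  d3b <- .relu(.convFwd(pl$dec3b, d3a, t4))
  u2c <- .relu(.convFwd(pl$up2, .upFwd(d3b, u4), t2))
  c2 <- cbind(e2b, u2c)
  d2a <- .relu(.convFwd(pl$dec2a, c2, t2))
  d2b <- .relu(.convFwd(pl$dec2b, d2a, t2))
  u1c <- .relu(.convFwd(pl$up1, .upFwd(d2b, u2), t1))
  c1 <- cbind(e1b, u1c)
  d1a <- .relu(.convFwd(pl$dec1a, c1, t1))
  d1b <- .relu(.convFwd(pl$dec1b, d1a, t1))
  z <- .convFwd(pl$outc, d1b, t1)
  P <- .sigmoid(as.vector(z))

  if (!keepCache)
    return(list(P = P,
                dims = list(level1 = c(H, W),
                            level2 = c(H %/% 2L, W %/% 2L),
                            level3 = c(H %/% 4L, W %/% 4L),
                            bottleneck = c(nrow(b2) / (W %/% 8L), W %/% 8L))))
  list(P = P,
       cache = list(X = X, e1a = e1a, e1b = e1b, p1 = p1, e2a = e2a,
                    e2b = e2b, p2 = p2, e3a = e3a, e3b = e3b, p3 = p3,
                    b1 = b1, b2 = b2, u3c = u3c, c3 = c3, d3a = d3a,
                    d3b = d3b, u2c = u2c, c2 = c2, d2a = d2a, d2b = d2b,
                    u1c = u1c, c1 = c1, d1a = d1a, d1b = d1b,
                    H = H, W = W, C = c(C1, C2, C3)),
       dims = list(level1 = c(H, W),
                   level2 = c(H %/% 2L, W %/% 2L),
                   level3 = c(H %/% 4L, W %/% 4L),
                   bottleneck = c(nrow(b2) / (W %/% 8L), W %/% 8L)))
}

## backward pass: dP is dLoss/dP (vector); returns the gradient tree
.netBackward <- function(pl, P, cache, dP) {
  H <- cache$H; W <- cache$W
  C1 <- cache$C[1L]; C2 <- cache$C[2L]; C3 <- cache$C[3L]
  t1 <- .shiftTables(H, W); t2 <- .shiftTables(H %/% 2L, W %/% 2L)
  t4 <- .shiftTables(H %/% 4L, W %/% 4L)
  t8 <- .shiftTables(H %/% 8L, W %/% 8L)
  pt1 <- .poolTables(H, W); pt2 <- .poolTables(H %/% 2L, W %/% 2L)
  pt4 <- .poolTables(H %/% 4L, W %/% 4L)
  u8 <- .upTables(H %/% 8L, W %/% 8L); u4 <- .upTables(H %/% 4L, W %/% 4L)
  u2 <- .upTables(H %/% 2L, W %/% 2L)
  g <- list()

  dz <- matrix(dP * P * (1 - P), ncol = 1L)
  r <- .convBwd(pl$outc, cache$d1b, dz, t1); g$outc <- r$grad
  d <- r$dX * (cache$d1b > 0)
  r <- .convBwd(pl$dec1b, cache$d1a, d, t1); g$dec1b <- r$grad
  d <- r$dX * (cache$d1a > 0)
  r <- .convBwd(pl$dec1a, cache$c1, d, t1); g$dec1a <- r$grad
  dskip1 <- r$dX[, seq_len(C1), drop = FALSE]
  d <- r$dX[, C1 + seq_len(C1), drop = FALSE] * (cache$u1c > 0)
  r <- .convBwd(pl$up1, .upFwd(cache$d2b, u2), d, t1); g$up1 <- r$grad
  d <- .upBwd(r$dX, u2) * (cache$d2b > 0)
  r <- .convBwd(pl$dec2b, cache$d2a, d, t2); g$dec2b <- r$grad
  d <- r$dX * (cache$d2a > 0)
  r <- .convBwd(pl$dec2a, cache$c2, d, t2); g$dec2a <- r$grad
  dskip2 <- r$dX[, seq_len(C2), drop = FALSE]
  d <- r$dX[, C2 + seq_len(C2), drop = FALSE] * (cache$u2c > 0)
  r <- .convBwd(pl$up2, .upFwd(cache$d3b, u4), d, t2); g$up2 <- r$grad
  d <- .upBwd(r$dX, u4) * (cache$d3b > 0)
  r <- .convBwd(pl$dec3b, cache$d3a, d, t4); g$dec3b <- r$grad
  d <- r$dX * (cache$d3a > 0)
  r <- .convBwd(pl$dec3a, cache$c3, d, t4); g$dec3a <- r$grad
  dskip3 <- r$dX[, seq_len(C3), drop = FALSE]
  d <- r$dX[, C3 + seq_len(C3), drop = FALSE] * (cache$u3c > 0)
  r <- .convBwd(pl$up3, .upFwd(cache$b2, u8), d, t4); g$up3 <- r$grad
  d <- .upBwd(r$dX, u8) * (cache$b2 > 0)
  r <- .convBwd(pl$bot2, cache$b1, d, t8); g$bot2 <- r$grad
  d <- r$dX * (cache$b1 > 0)
  r <- .convBwd(pl$bot1, cache$p3$out, d, t8); g$bot1 <- r$grad
  n4 <- (H %/% 4L) * (W %/% 4L)
  d <- (dskip3 + .poolBwd(r$dX, cache$p3$sel, pt4, n4, C3)) * (cache$e3b > 0)
  r <- .convBwd(pl$enc3b, cache$e3a, d, t4); g$enc3b <- r$grad
  d <- r$dX * (cache$e3a > 0)
  r <- .convBwd(pl$enc3a, cache$p2$out, d, t4); g$enc3a <- r$grad
  n2 <- (H %/% 2L) * (W %/% 2L)
  d <- (dskip2 + .poolBwd(r$dX, cache$p2$sel, pt2, n2, C2)) * (cache$e2b > 0)
  r <- .convBwd(pl$enc2b, cache$e2a, d, t2); g$enc2b <- r$grad
  d <- r$dX * (cache$e2a > 0)
  r <- .convBwd(pl$enc2a, cache$p1$out, d, t2); g$enc2a <- r$grad
  n1 <- H * W
  d <- (dskip1 + .poolBwd(r$dX, cache$p1$sel, pt1, n1, C1)) * (cache$e1b > 0)
  r <- .convBwd(pl$enc1b, cache$e1a, d, t1); g$enc1b <- r$grad
  d <- r$dX * (cache$e1a > 0)
  r <- .convBwd(pl$enc1a, cache$X, d, t1); g$enc1a <- r$grad
  g[names(pl)]
}

#' Laplace-smoothed Soft Dice loss
#'
#' Computes \code{1 - (sum(P*B) + 1) / (sum(P) + sum(B) - sum(P*B) + 1)}: one
#' minus a smoothed intersection-over-union between a probability map and a
#' binary mask. The +1 Laplace smoothing makes the loss 0 (not 0/0) when both
#' maps are empty and stabilizes gradients near-empty masks.
#'
#' @param P numeric probability map (vector or matrix), values in [0, 1].
#' @param B binary ground-truth mask, same shape, values 0/1.
#' @return Loss value in [0, 1).
#' @examples
#' softDiceLoss(matrix(c(0.5, 0.5, 0.5, 0.5), 2), matrix(c(1, 0, 0, 0), 2))
#' @export
softDiceLoss <- function(P, B) {
  if (length(P) != length(B) ||
      (!is.null(dim(P)) && !is.null(dim(B)) && !identical(dim(P), dim(B))))
    stop("probability map and mask have different shapes", call. = FALSE)
  if (any(P < 0 | P > 1)) stop("probabilities must lie in [0, 1]",
                               call. = FALSE)
  if (any(B != 0 & B != 1)) stop("mask must be binary", call. = FALSE)
  i <- sum(P * B)
  1 - (i + 1) / (sum(P) + sum(B) - i + 1)
}

## gradient of softDiceLoss w.r.t. P
.diceGrad <- function(P, B) {
  i <- sum(P * B)
  num <- i + 1
  den <- sum(P) + sum(B) - i + 1
  -(B * den - num * (1 - B)) / den^2
}

#' Training configuration
#'
#' @param learningRate SGD learning rate (default 0.01).
#' @param batchSize minibatch size (default 8).
#' @param epochs maximum number of epochs (default 20).
#' @param seed integer seed driving shuffling (and any other randomness).
#' @param shuffle reshuffle the training order every epoch.
#' @param lossTarget optional early-stop threshold: training stops after the
#'   first epoch whose mean loss falls below it.
#' @param clipNorm global gradient-norm clip per minibatch (default
#'   \code{Inf}, i.e. plain SGD). The Soft Dice gradient scales inversely
#'   with the smoothed union, so it is tiny on the initial near-uniform
#'   output and large near convergence; clipping keeps a step size that
#'   escapes the initial plateau from overshooting later. See
#'   \code{\link{reducedTrainConfig}} for the calibrated reduced-scale
#'   setting.
#' @param verbose print the per-epoch mean loss.
#' @return A named list of class \code{trainConfig}.
#' @export
trainConfig <- function(learningRate = 0.01, batchSize = 8L, epochs = 20L,
                        seed = 1L, shuffle = TRUE, lossTarget = NULL,
                        clipNorm = Inf, verbose = FALSE) {
  stopifnot(learningRate >= 0, batchSize >= 1L, epochs >= 1L, clipNorm > 0)
  structure(list(learningRate = learningRate, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 shuffle = isTRUE(shuffle), lossTarget = lossTarget,
                 clipNorm = clipNorm, verbose = isTRUE(verbose)),
            class = "trainConfig")
}

#' @rdname trainConfig
#' @param ... overrides passed on to \code{trainConfig}.
#' @details \code{reducedTrainConfig} is the calibrated training setting for
#'   the reduced-resolution (96x96) synthetic regime: learning rate 2 with
#'   gradient-norm clip 0.1 (an effective maximum step of 0.2), minibatch 8,
#'   up to 20 epochs with early stop once the epoch-mean loss falls below
#'   0.15.
#' @export
reducedTrainConfig <- function(seed = 1L, ...) {
  args <- list(learningRate = 2, clipNorm = 0.1, epochs = 20L,
               lossTarget = 0.15, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(trainConfig, args)
}

#' Train the segmentation network
#'
#' Minibatch stochastic gradient descent on the Soft Dice loss. Fully
#' reproducible: shuffling is driven by \code{config$seed}.
#'
#' @param model an \linkS4class{ApexModel}.
#' @param dataset list of training pairs, each a list with elements
#'   \code{frame} (height x width x 3 array, 0-255) and \code{mask}
#'   (height x width binary matrix). See \code{\link{generateTrainingSet}}.
#' @param config a \code{\link{trainConfig}}.
#' @param val optional validation pairs (same format); when given, the
#'   parameters from the epoch with the lowest validation loss are returned.
#' @return The trained \linkS4class{ApexModel} with an updated
#'   \code{trainLog}.
#' @export
trainNetwork <- function(model, dataset, config = trainConfig(), val = NULL) {
  stopifnot(is(model, "ApexModel"))
  if (length(dataset) == 0L) stop("training dataset is empty", call. = FALSE)
  d <- dim(dataset[[1L]]$frame)
  H <- d[1L]; W <- d[2L]
  Xs <- lapply(dataset, function(it) {
    stopifnot(identical(dim(it$frame)[1:2], c(H, W)))
    matrix(it$frame / 255, H * W, 3L)
  })
  Bs <- lapply(dataset, function(it) as.vector(it$mask))
  valX <- if (!is.null(val))
    lapply(val, function(it) matrix(it$frame / 255, H * W, 3L))
  valB <- if (!is.null(val)) lapply(val, function(it) as.vector(it$mask))

  pl <- model@params
  set.seed(config$seed)
  n <- length(Xs)
  log <- data.frame(epoch = integer(), loss = numeric(),
                    valLoss = numeric())
  bestVal <- Inf; bestPl <- pl
  for (ep in seq_len(config$epochs)) {
    ord <- if (config$shuffle) sample.int(n) else seq_len(n)
    epLoss <- 0
    starts <- seq(1L, n, by = config$batchSize)
    for (s in starts) {
      items <- ord[s:min(s + config$batchSize - 1L, n)]
      acc <- NULL
      for (it in items) {
        fw <- .netForward(pl, Xs[[it]], H, W, keepCache = TRUE)
        epLoss <- epLoss + softDiceLoss(fw$P, Bs[[it]])
        gr <- .netBackward(pl, fw$P, fw$cache, .diceGrad(fw$P, Bs[[it]]))
        acc <- if (is.null(acc)) gr else .map2Params(acc, gr, `+`)
      }
      if (config$learningRate > 0) {
        acc <- .mapParams(acc, function(g) g / length(items))
        if (is.finite(config$clipNorm)) {
          gn <- sqrt(.sumSqParams(acc))
          if (gn > config$clipNorm)
            acc <- .mapParams(acc, function(g) g * config$clipNorm / gn)
        }
        pl <- .map2Params(pl, acc,
                          function(w, g) w - config$learningRate * g)
      }
    }
    epLoss <- epLoss / n
    vl <- NA_real_
    if (!is.null(val)) {
      vl <- mean(vapply(seq_along(valX), function(i)
        softDiceLoss(.netForward(pl, valX[[i]], H, W)$P, valB[[i]]),
        numeric(1)))
      if (vl < bestVal) { bestVal <- vl; bestPl <- pl }
    }
    log <- rbind(log, data.frame(epoch = ep, loss = epLoss, valLoss = vl))
    if (config$verbose)
      message(sprintf("epoch %d: loss %.4f%s", ep, epLoss,
                      if (is.na(vl)) "" else sprintf(" val %.4f", vl)))
    if (!is.null(config$lossTarget) && epLoss < config$lossTarget) break
  }
  if (!is.null(val)) pl <- bestPl
  initialize(model, params = pl,
             trainLog = rbind(model@trainLog,
                              log[, c("epoch", "loss", "valLoss")]))
}

## reflect-pad an (H*W) x C matrix grid to (H2 x W2) on the bottom/right
.reflectPad <- function(img, H2, W2) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  if (H2 - H >= H || W2 - W >= W)
    stop(sprintf("input %dx%d too small to pad to %dx%d", W, H, W2, H2),
         call. = FALSE)
  ri <- c(seq_len(H), H - seq_len(H2 - H))
  ci <- c(seq_len(W), W - seq_len(W2 - W))
  img[ri, ci, , drop = FALSE]
}

#' Run the segmentation network on an image
#'
#' Deterministic forward pass producing a per-pixel apex probability map the
#' same size as the input. Inputs whose dimensions are not multiples of 8
#' (for instance 101x101 search-range crops) are reflect-padded to the next
#' multiple and the output map is cropped back.
#'
#' @param model an \linkS4class{ApexModel}.
#' @param image height x width x 3 numeric array, values 0-255.
#' @return Numeric matrix (height x width) of probabilities in [0, 1].
#' @export
inferMap <- function(model, image) {
  stopifnot(is(model, "ApexModel"))
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L)
    stop("image must be a height x width x 3 array", call. = FALSE)
  H <- d[1L]; W <- d[2L]
  H2 <- as.integer(ceiling(H / 8) * 8); W2 <- as.integer(ceiling(W / 8) * 8)
  img <- if (H2 != H || W2 != W) .reflectPad(image, H2, W2) else image
  X <- matrix(img / 255, H2 * W2, 3L)
  P <- matrix(.netForward(model@params, X, H2, W2)$P, H2, W2)
  P[seq_len(H), seq_len(W), drop = FALSE]
}

#' Spatial sizes of the network's feature maps for a given input
#'
#' Runs a forward pass on a blank input of the requested size and reports the
#' measured height and width of the feature maps at each resolution level,
#' including the bottleneck (the fourth, lowest-resolution level).
#'
#' @param model an \linkS4class{ApexModel}.
#' @param inputSize c(height, width), both divisible by 8.
#' @return Named list of c(height, width) per level.
#' @examples
#' \donttest{
#' m <- buildNetwork(baseChannels = 2, seed = 1)
#' networkFieldDims(m, c(480, 640))$bottleneck  # 60 80
#' }
#' @export
networkFieldDims <- function(model, inputSize = c(480L, 640L)) {
  H <- as.integer(inputSize[1L]); W <- as.integer(inputSize[2L])
  X <- matrix(0, H * W, 3L)
  .netForward(model@params, X, H, W)$dims
}

#' Save / load a model checkpoint
#'
#' Checkpoints are single RDS files embedding the network configuration, the
#' parameters, the training log and the initialization seed.
#'
#' @param model an \linkS4class{ApexModel}.
#' @param path checkpoint file path.
#' @return \code{saveApexModel} invisibly returns \code{path};
#'   \code{loadApexModel} returns the restored \linkS4class{ApexModel}.
#' @export
saveApexModel <- function(model, path) {
  stopifnot(is(model, "ApexModel"))
  saveRDS(list(format = "apextrack-model-v1", config = model@config,
               params = model@params, trainLog = model@trainLog,
               seed = model@seed), path)
  invisible(path)
}

#' @rdname saveApexModel
#' @export
loadApexModel <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "apextrack-model-v1"))
    stop(sprintf("'%s' is not an apextrack model checkpoint", path),
         call. = FALSE)
  new("ApexModel", config = x$config, params = x$params,
      trainLog = x$trainLog, seed = x$seed)
}
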