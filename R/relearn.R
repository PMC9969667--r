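## The Model Update (relearning) mechanism. When the loss between the
## probability map and the frame's post-processed binary segmentation - the
## "suspicion" - exceeds a trigger threshold, the network is refined on the
## current frame alone, using that binary map as pseudo-ground-truth. Each
## refinement iteration blends a gradient step with an anchor parameter set
## so the pretrained behaviour is mostly preserved:
##     W[k+1] = (1 - alpha) * WT + alpha * (W[k] - eta * grad L(W[k]))
## The loop stops when suspicion < c * Ts, or when a wall-clock or iteration
## cap fires; the refined parameters then become the new anchor.

#' Model Update configuration
#'
#' @param Ts suspicion trigger threshold, default 0.95.
#' @param c stop factor in (0, 1): refinement stops once suspicion drops
#'   below \code{c * Ts}. Default 0.6.
#' @param alpha blend weight in (0, 1) between the anchor parameters and the
#'   gradient-stepped parameters. Values near 1 let the refinement move
#'   freely; default 0.9 (the anchor pull still bounds the excursion).
#' @param eta relearning learning rate, default 0.5. Relearning fits a
#'   single frame, so a much larger step than the training rate is usable.
#' @param timeCapS wall-clock cap on one relearning event in seconds,
#'   default 3 (monotonic clock).
#' @param maxIters iteration cap making tests hardware-independent,
#'   default 100.
#' @param clipNorm global gradient-norm clip per refinement iteration,
#'   default 0.1: the Soft Dice gradient on a single frame spans orders of
#'   magnitude as the fit improves, and clipping keeps every blended step
#'   bounded (see \code{\link{trainConfig}}).
#' @param boxSide side of the pseudo-ground-truth box used when relearning
#'   is seeded from a location rather than a segmentation (first-frame user
#'   box, or re-acquisition after a total detection failure). Default 33.
#' @return A named list of class \code{relearnConfig}.
#' @export
relearnConfig <- function(Ts = 0.95, c = 0.6, alpha = 0.95, eta = 2,
                          timeCapS = 3, maxIters = 100L, boxSide = 33L,
                          clipNorm = 0.1) {
  stopifnot(Ts > 0, Ts <= 1, c > 0, c < 1, alpha > 0, alpha < 1, eta >= 0,
            timeCapS >= 0, maxIters >= 0L, clipNorm > 0)
  structure(list(Ts = Ts, c = c, alpha = alpha, eta = eta,
                 timeCapS = timeCapS, maxIters = as.integer(maxIters),
                 boxSide = as.integer(boxSide), clipNorm = clipNorm),
            class = "relearnConfig")
}

#' Suspicion score of a frame's segmentation
#'
#' The Soft Dice loss (\code{\link{softDiceLoss}}) between the network's
#' probability map and the frame's post-processed binary segmentation map.
#' A high value means the thresholded-and-filtered segmentation explains the
#' probability mass poorly, so the detection is suspect.
#'
#' @param P probability matrix.
#' @param Binit binary segmentation matrix, same size.
#' @return Suspicion in [0, 1).
#' @export
computeSuspicion <- function(P, Binit) softDiceLoss(P, Binit)

#' Anchored blended parameter update
#'
#' One Model Update iteration:
#' \code{W[k+1] = (1 - alpha) * WT + alpha * (W[k] - eta * grad)},
#' element-wise over structurally identical parameter sets. At
#' \code{alpha -> 1} this reduces to a plain SGD step; with a zero gradient,
#' iterating it converges geometrically to the anchor \code{WT} with
#' ratio \code{alpha}.
#'
#' @param Wk current parameters (nested list of numeric arrays).
#' @param WT anchor parameters, same structure.
#' @param grad gradient of the loss at \code{Wk}, same structure.
#' @param eta learning rate.
#' @param alpha blend weight in (0, 1].
#' @return The updated parameter set.
#' @examples
#' blendedUpdate(list(w = 2), list(w = 1), list(w = 5), eta = 0.1, alpha = 0.5)
#' # w = 0.5*1 + 0.5*(2 - 0.5) = 1.25
#' @export
blendedUpdate <- function(Wk, WT, grad, eta, alpha) {
  stepped <- .map2Params(Wk, grad, function(w, g) w - eta * g)
  .map2Params(stepped, WT, function(s, t) (1 - alpha) * t + alpha * s)
}

#' Refine the model on a single frame
#'
#' The Model Update refinement loop: repeated forward passes on the frame
#' crop, each followed by an anchored blended gradient step
#' (\code{\link{blendedUpdate}}) on the Soft Dice loss against the fixed
#' pseudo-ground-truth \code{Binit}, until the suspicion drops below
#' \code{c * Ts} or a cap (wall-clock or iteration) fires. On completion the
#' refined parameters become the new anchor for later events in the same
#' video.
#'
#' @param params live model parameters.
#' @param anchor current anchor parameters (the pretrained set, or the
#'   result of the previous Model Update in this video).
#' @param crop height x width x 3 numeric array (0-255), the frame or search
#'   range the suspicion was computed on.
#' @param Binit binary pseudo-ground-truth matrix, held fixed for the loop.
#' @param config a \code{\link{relearnConfig}}.
#' @return list(params, anchor, iterations, finalSuspicion).
#' @export
relearnOnFrame <- function(params, anchor, crop, Binit,
                           config = relearnConfig()) {
  d <- dim(crop)
  H <- d[1L]; W <- d[2L]
  H2 <- as.integer(ceiling(H / 8) * 8); W2 <- as.integer(ceiling(W / 8) * 8)
  img <- if (H2 != H || W2 != W) .reflectPad(crop, H2, W2) else crop
  X <- matrix(img / 255, H2 * W2, 3L)
  Bfull <- matrix(0, H2, W2)
  Bfull[seq_len(H), seq_len(W)] <- Binit
  Bv <- as.vector(Bfull)
  inner <- as.vector(matrix(seq_len(H2 * W2), H2, W2)[seq_len(H), seq_len(W)])

  t0 <- proc.time()[["elapsed"]]
  iters <- 0L
  susp <- NA_real_
  repeat {
    fw <- .netForward(params, X, H2, W2, keepCache = TRUE)
    susp <- softDiceLoss(fw$P[inner], Bv[inner])
    if (susp < config$c * config$Ts) break
    if (iters >= config$maxIters) break
    if (proc.time()[["elapsed"]] - t0 >= config$timeCapS) break
    dP <- numeric(length(fw$P))
    dP[inner] <- .diceGrad(fw$P[inner], Bv[inner])
    grad <- .netBackward(params, fw$P, fw$cache, dP)
    if (is.finite(config$clipNorm)) {
      gn <- sqrt(.sumSqParams(grad))
      if (gn > config$clipNorm)
        grad <- .mapParams(grad, function(g) g * config$clipNorm / gn)
    }
    params <- blendedUpdate(params, anchor, grad, config$eta, config$alpha)
    iters <- iters + 1L
  }
  list(params = params, anchor = params, iterations = iters,
       finalSuspicion = susp)
}

#' Reset the model to its pretrained parameters
#'
#' Restores both the live parameters and the anchor to the pretrained
#' snapshot; used when a new video starts so relearned parameters never leak
#' across tracking tasks. (\code{\link{trackVideo}} does this implicitly.)
#'
#' @param pretrained the pretrained \linkS4class{ApexModel}.
#' @return list(params, anchor), both the pretrained parameter set.
#' @export
resetModel <- function(pretrained) {
  stopifnot(is(pretrained, "ApexModel"))
  list(params = pretrained@params, anchor = pretrained@params)
}
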