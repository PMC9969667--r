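## Seeded synthetic circumnutation videos: a bright, radially soft apex-like
## blob follows an elliptical path with a slow upward growth drift over a
## dark solid background, optionally with static distractor rectangles, a
## mid-video appearance change, and additive Gaussian pixel noise. Exact
## ground-truth centers come for free, so training, tracking, relearning and
## evaluation are all testable without any real footage.

#' Scene specification for a synthetic circumnutation video
#'
#' The blob center at frame t (0-based) is
#' \code{(cx + a*cos(omega*t + phase), cy - growth*t + b*sin(omega*t + phase))}:
#' a near-elliptical oscillation around a slowly rising center, emulating the
#' circumnutation of a growing inflorescence apex. The defaults describe a
#' full-scale 640x480 scene; \code{reducedSceneSpec} gives a proportionally
#' scaled-down 96x96 variant for fast CPU runs.
#'
#' @param frameSize c(width, height) in pixels.
#' @param nFrames number of frames.
#' @param background RGB background color (0-255), a dark solid.
#' @param blobColor RGB core color of the apex blob.
#' @param blobRadius blob radius in pixels.
#' @param softness width in pixels of the blob's soft (anti-aliased) rim.
#' @param center c(cx, cy) ellipse center at frame 0, 0-based pixels.
#' @param semiAxes c(a, b) ellipse semi-axes in pixels.
#' @param omega angular step in radians per frame.
#' @param phase phase offset in radians.
#' @param growth upward growth drift in pixels per frame (positive moves the
#'   apex up, i.e. decreasing y).
#' @param appearanceShift optional list(frame=, color=, radius=): from
#'   \code{frame} on, the blob is rendered with the new color and/or radius
#'   (morphology/lighting change mid-video).
#' @param distractors optional list of static rectangles, each
#'   list(x=, y=, w=, h=, color=), drawn under the blob; they must not touch
#'   the blob's path envelope.
#' @param noiseSigma standard deviation of additive Gaussian pixel noise on
#'   the 0-255 scale (clipped), default 5.
#' @param seed integer seed making the rendering deterministic.
#' @return A validated scene specification list of class \code{sceneSpec}.
#' @export
sceneSpec <- function(frameSize = c(640L, 480L), nFrames = 100L,
                      background = c(16, 16, 22),
                      blobColor = c(235, 235, 215), blobRadius = 16,
                      softness = 2,
                      center = c(320, 300), semiAxes = c(60, 40),
                      omega = 2 * pi / 100, phase = 0, growth = 0.15,
                      appearanceShift = NULL, distractors = NULL,
                      noiseSigma = 5, seed = 1L) {
  spec <- list(frameSize = as.integer(frameSize), nFrames = as.integer(nFrames),
               background = background, blobColor = blobColor,
               blobRadius = blobRadius, softness = softness,
               center = center, semiAxes = semiAxes, omega = omega,
               phase = phase, growth = growth,
               appearanceShift = appearanceShift, distractors = distractors,
               noiseSigma = noiseSigma, seed = as.integer(seed))
  class(spec) <- "sceneSpec"
  .validateSceneSpec(spec)
  spec
}

#' @rdname sceneSpec
#' @param ... overrides passed on to \code{sceneSpec}.
#' @export
reducedSceneSpec <- function(nFrames = 100L, seed = 1L, ...) {
  args <- list(frameSize = c(96L, 96L), nFrames = nFrames,
               blobRadius = 5, softness = 1.5,
               center = c(48, 60), semiAxes = c(14, 9),
               omega = 2 * pi / 60, growth = 0.05, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sceneSpec, args)
}

.blobCenters <- function(spec) {
  t <- seq_len(spec$nFrames) - 1
  data.frame(
    t = t,
    x = spec$center[1L] + spec$semiAxes[1L] * cos(spec$omega * t + spec$phase),
    y = spec$center[2L] - spec$growth * t +
      spec$semiAxes[2L] * sin(spec$omega * t + spec$phase))
}

.maxRadius <- function(spec) {
  r <- spec$blobRadius
  if (!is.null(spec$appearanceShift) &&
      !is.null(spec$appearanceShift$radius))
    r <- max(r, spec$appearanceShift$radius)
  r
}

.validateSceneSpec <- function(spec) {
  w <- spec$frameSize[1L]; h <- spec$frameSize[2L]
  stopifnot(spec$nFrames >= 1L, spec$blobRadius > 0, spec$noiseSigma >= 0)
  ctr <- .blobCenters(spec)
  margin <- .maxRadius(spec) + spec$softness
  if (any(ctr$x - margin < 0) || any(ctr$x + margin > w - 1) ||
      any(ctr$y - margin < 0) || any(ctr$y + margin > h - 1))
    stop("blob path leaves the frame (path must stay one blob radius inside)",
         call. = FALSE)
  if (spec$nFrames > 1L) {
    dx <- diff(ctr$x); dy <- diff(ctr$y)
    if (max(sqrt(dx^2 + dy^2)) > 20)
      stop("per-frame blob displacement exceeds the 20 px motion bound",
         call. = FALSE)
  }
  for (d in spec$distractors) {
    ## keep distractors clear of the path envelope
    ex0 <- min(ctr$x) - margin; ex1 <- max(ctr$x) + margin
    ey0 <- min(ctr$y) - margin; ey1 <- max(ctr$y) + margin
    if (d$x <= ex1 && d$x + d$w >= ex0 && d$y <= ey1 && d$y + d$h >= ey0)
      stop("distractor overlaps the blob path envelope", call. = FALSE)
  }
  invisible(spec)
}

## render one frame (no noise); cx, cy 0-based real
.renderFrame <- function(spec, cx, cy, radius, color) {
  w <- spec$frameSize[1L]; h <- spec$frameSize[2L]
  frame <- array(rep(spec$background, each = h * w), c(h, w, 3L))
  for (d in spec$distractors) {
    ys <- max(d$y, 0L):min(d$y + d$h - 1L, h - 1L) + 1L
    xs <- max(d$x, 0L):min(d$x + d$w - 1L, w - 1L) + 1L
    for (ch in 1:3) frame[ys, xs, ch] <- d$color[ch]
  }
  ## radially soft disk: opacity 1 inside radius, fading over `softness`
  xg <- matrix(0:(w - 1), h, w, byrow = TRUE)
  yg <- matrix(0:(h - 1), h, w)
  dist <- sqrt((xg - cx)^2 + (yg - cy)^2)
  op <- pmin(pmax((radius + spec$softness - dist) / spec$softness, 0), 1)
  for (ch in 1:3)
    frame[, , ch] <- frame[, , ch] * (1 - op) + color[ch] * op
  frame
}

#' Generate a synthetic circumnutation video
#'
#' Renders the scene described by a \code{\link{sceneSpec}} and returns the
#' frames together with exact per-frame ground-truth annotations (the blob
#' center rounded to integer pixels). Deterministic under the spec's seed.
#'
#' @param spec a \code{\link{sceneSpec}}.
#' @return A \linkS4class{SyntheticVideo}.
#' @examples
#' v <- generateVideo(reducedSceneSpec(nFrames = 4, seed = 7))
#' annotations(v)
#' @export
generateVideo <- function(spec) {
  stopifnot(inherits(spec, "sceneSpec"))
  .validateSceneSpec(spec)
  ctr <- .blobCenters(spec)
  shift <- spec$appearanceShift
  set.seed(spec$seed)
  frames <- vector("list", spec$nFrames)
  for (i in seq_len(spec$nFrames)) {
    t <- i - 1L
    radius <- spec$blobRadius; color <- spec$blobColor
    if (!is.null(shift) && t >= shift$frame) {
      if (!is.null(shift$color)) color <- shift$color
      if (!is.null(shift$radius)) radius <- shift$radius
    }
    f <- .renderFrame(spec, ctr$x[i], ctr$y[i], radius, color)
    if (spec$noiseSigma > 0)
      f <- f + array(stats::rnorm(length(f), 0, spec$noiseSigma), dim(f))
    frames[[i]] <- pmin(pmax(f, 0), 255)
  }
  ann <- data.frame(frame = ctr$t,
                    x = as.integer(round(ctr$x)),
                    y = as.integer(round(ctr$y)))
  new("SyntheticVideo",
      sequence = FrameSequence(frames, name = sprintf("synthetic-%d",
                                                      spec$seed)),
      annotations = ann, spec = unclass(spec))
}

#' Re-render a synthetic video with a changed blob appearance
#'
#' Frames at and after \code{shift$frame} are re-rendered with the new color
#' and/or radius; earlier frames and all annotations are unchanged. The
#' rendering reuses the spec's seed, so an identity shift reproduces the
#' video byte for byte.
#'
#' @param video a \linkS4class{SyntheticVideo}.
#' @param shift list(frame=, color=, radius=) as in
#'   \code{\link{sceneSpec}}'s \code{appearanceShift}.
#' @return A new \linkS4class{SyntheticVideo}.
#' @export
perturbAppearance <- function(video, shift) {
  stopifnot(is(video, "SyntheticVideo"))
  if (shift$frame < 0L || shift$frame >= nFrames(video))
    stop("shift frame index outside the video", call. = FALSE)
  spec <- video@spec
  class(spec) <- "sceneSpec"
  spec$appearanceShift <- shift
  generateVideo(spec)
}

#' Build a training set of frame/mask pairs from scene specifications
#'
#' Generates each video and pairs every frame with the ground-truth mask of
#' its annotation (\code{\link{makeMask}}).
#'
#' @param specs list of \code{\link{sceneSpec}} objects.
#' @param boxSide mask box side in pixels (odd), default 33.
#' @return List of pairs, each a list(frame=, mask=), in video-then-frame
#'   order; suitable for \code{\link{trainNetwork}}.
#' @export
generateTrainingSet <- function(specs, boxSide = 33L) {
  if (length(specs) == 0L) stop("no scene specifications given", call. = FALSE)
  out <- list()
  for (spec in specs) {
    v <- generateVideo(spec)
    fs <- frames(v); ann <- annotations(v)
    d <- frameDim(v)
    for (i in seq_along(fs))
      out[[length(out) + 1L]] <-
        list(frame = fs[[i]],
             mask = makeMask(c(ann$x[i], ann$y[i]), d, boxSide))
  }
  out
}
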