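## Per-frame tracking loop: crop a search range around the previous apex
## center, segment the crop, threshold the probability map, map candidate
## pixels back to full-frame coordinates, remove outliers (distance gate to
## the previous center, then a coordinate-median gate), and take the mean of
## the survivors as the apex center. The first frame - and any frame right
## after a total detection failure - is re-detected on the whole frame.

#' Tracker configuration
#'
#' @param Tm probability threshold above which a pixel is an apex candidate
#'   (inclusive), default 0.75.
#' @param R1 search half-range in pixels: the crop is (2*R1+1) square.
#'   Default 200 (a GPU-class setting; 50 suits CPU-only machines, see
#'   \code{\link{selectSearchRange}}).
#' @param R2 maximum distance in pixels a candidate may lie from the previous
#'   apex center, default 30.
#' @param R3 maximum deviation in pixels from the candidates' coordinate
#'   medians, default \code{0.5 * R2}.
#' @param T1,T2 benchmark bounds in seconds for the adaptive search range
#'   (defaults 0.04 and 0.17): probe inference faster than \code{T1} selects
#'   R1 = 200, slower than \code{T2} selects R1 = 50, otherwise R1 = 100.
#' @return A named list of class \code{trackerConfig}.
#' @export
trackerConfig <- function(Tm = 0.75, R1 = 200, R2 = 30, R3 = 0.5 * R2,
                          T1 = 0.04, T2 = 0.17) {
  stopifnot(Tm > 0, Tm < 1, R1 > 0, R2 > 0, R3 > 0, T1 < T2)
  structure(list(Tm = Tm, R1 = R1, R2 = R2, R3 = R3, T1 = T1, T2 = T2),
            class = "trackerConfig")
}

#' Crop the search range around the previous apex center
#'
#' Returns a (2*R1+1) square window centered on \code{prevCenter}, shifted
#' inward at the frame borders so the output size never changes (the network
#' always sees real pixels). Before the first detection
#' (\code{prevCenter = NULL}) the whole frame is returned. If the window
#' would exceed the frame, the whole frame is returned with a warning.
#'
#' @param frame height x width x 3 numeric array.
#' @param prevCenter c(x, y) 0-based previous apex center, or NULL.
#' @param R1 search half-range in pixels.
#' @return list(crop = array, offset = c(x, y) 0-based top-left corner of the
#'   crop in full-frame coordinates).
#' @export
cropSearchRange <- function(frame, prevCenter, R1) {
  stopifnot(R1 > 0)
  h <- dim(frame)[1L]; w <- dim(frame)[2L]
  if (is.null(prevCenter))
    return(list(crop = frame, offset = c(0L, 0L)))
  side <- 2L * as.integer(R1) + 1L
  if (side > w || side > h) {
    warning(sprintf("search range %dx%d exceeds the %dx%d frame; using the whole frame",
                    side, side, w, h), call. = FALSE)
    return(list(crop = frame, offset = c(0L, 0L)))
  }
  cx <- as.integer(round(prevCenter[1L])); cy <- as.integer(round(prevCenter[2L]))
  x0 <- min(max(cx - as.integer(R1), 0L), w - side)
  y0 <- min(max(cy - as.integer(R1), 0L), h - side)
  list(crop = frame[(y0 + 1L):(y0 + side), (x0 + 1L):(x0 + side), ,
                    drop = FALSE],
       offset = c(x0, y0))
}

#' Threshold a probability map
#'
#' Pixels with probability >= \code{Tm} become 1, all others 0.
#'
#' @param P numeric probability matrix.
#' @param Tm threshold in (0, 1).
#' @return Integer 0/1 matrix of the same size.
#' @export
thresholdMap <- function(P, Tm) {
  stopifnot(Tm > 0, Tm < 1)
  m <- matrix(0L, nrow(P), ncol(P))
  m[P >= Tm] <- 1L
  m
}

#' Remove outlier candidate pixels
#'
#' Two-step filter in full-frame pixel coordinates: first drop candidates
#' farther than \code{R2} (Euclidean) from the previous apex center; then
#' compute the survivors' coordinate medians (x~, y~) and drop any candidate
#' with |x - x~| > R3 or |y - y~| > R3. With \code{prevCenter = NULL} (first
#' frame / re-detection) only the median step runs. If the first step leaves
#' nothing, the result is empty.
#'
#' @param candidates n x 2 matrix of (x, y) candidate pixel coordinates.
#' @param prevCenter c(x, y) previous apex center, or NULL.
#' @param R2 distance gate in pixels.
#' @param R3 median-deviation gate in pixels.
#' @return The filtered n' x 2 matrix (possibly 0-row).
#' @export
removeOutliers <- function(candidates, prevCenter, R2, R3) {
  stopifnot(R2 > 0, R3 > 0)
  if (is.null(dim(candidates)))
    candidates <- matrix(candidates, ncol = 2L)
  if (nrow(candidates) == 0L) return(candidates)
  if (!is.null(prevCenter)) {
    d2 <- (candidates[, 1L] - prevCenter[1L])^2 +
          (candidates[, 2L] - prevCenter[2L])^2
    candidates <- candidates[d2 <= R2^2, , drop = FALSE]
    if (nrow(candidates) == 0L) return(candidates)
  }
  xm <- stats::median(candidates[, 1L])
  ym <- stats::median(candidates[, 2L])
  keep <- abs(candidates[, 1L] - xm) <= R3 & abs(candidates[, 2L] - ym) <= R3
  candidates[keep, , drop = FALSE]
}

#' Localize the apex center
#'
#' The arithmetic mean of the candidate coordinates, or NULL when the set is
#' empty (the caller handles the failure).
#'
#' @param candidates n x 2 matrix of (x, y) pixel coordinates.
#' @return c(x, y) real-valued center, or NULL.
#' @export
locateCenter <- function(candidates) {
  if (is.null(dim(candidates)))
    candidates <- matrix(candidates, ncol = 2L)
  if (nrow(candidates) == 0L) return(NULL)
  c(mean(candidates[, 1L]), mean(candidates[, 2L]))
}

#' Select the search range from a device benchmark
#'
#' The tracker benchmarks inference on a 401x401 probe image and picks the
#' search half-range accordingly: faster than \code{T1} seconds keeps the
#' large 401x401 search range (R1 = 200), slower than \code{T2} falls back to
#' 101x101 (R1 = 50), anything in between uses 201x201 (R1 = 100).
#'
#' @param benchTimeS measured probe inference time in seconds.
#' @param config a \code{\link{trackerConfig}} supplying T1 and T2.
#' @return R1 in pixels: 200, 100 or 50.
#' @examples
#' selectSearchRange(0.02)  # 200
#' selectSearchRange(0.30)  # 50
#' @export
selectSearchRange <- function(benchTimeS, config = trackerConfig()) {
  stopifnot(benchTimeS > 0)
  if (benchTimeS < config$T1) return(200)
  if (benchTimeS > config$T2) return(50)
  100
}

#' Benchmark probe inference time
#'
#' Times a single forward pass on a 401x401 probe image, the measurement
#' \code{\link{selectSearchRange}} expects.
#'
#' @param model an \linkS4class{ApexModel}.
#' @param probeSide probe image side in pixels, default 401.
#' @return Elapsed seconds.
#' @export
benchmarkInference <- function(model, probeSide = 401L) {
  probe <- array(128, c(probeSide, probeSide, 3L))
  inferMap(model, probe)  # warm the index caches
  t0 <- proc.time()[["elapsed"]]
  inferMap(model, probe)
  proc.time()[["elapsed"]] - t0
}

## initialize the mutable tracking state for one video
.newTrackerState <- function(model, config, relearn) {
  list(prevCenter = NULL, prevLost = FALSE, frameIndex = 0L,
       params = model@params, anchor = model@params,
       config = config, relearn = relearn,
       events = data.frame(frame = integer(), triggerSuspicion = numeric(),
                           finalSuspicion = numeric(),
                           iterations = integer()))
}

## run segmentation + post-processing on one frame with the current params;
## wideSearch forces whole-frame re-detection (first frame / after a loss)
.detect <- function(state, frame, model, wideSearch) {
  cfg <- state$config
  prev <- if (wideSearch) NULL else state$prevCenter
  cr <- cropSearchRange(frame, prev, cfg$R1)
  P <- inferMap(initialize(model, params = state$params), cr$crop)
  bin <- thresholdMap(P, cfg$Tm)
  idx <- which(bin == 1L, arr.ind = TRUE)
  ## crop-local (row, col) -> full-frame 0-based (x, y)
  cand <- cbind(idx[, 2L] - 1L + cr$offset[1L],
                idx[, 1L] - 1L + cr$offset[2L])
  filterCenter <- if (wideSearch) NULL else state$prevCenter
  cand <- removeOutliers(cand, filterCenter, cfg$R2, cfg$R3)
  ## crop-sized binary map of the surviving candidates (the pipeline's
  ## "initial binary segmentation")
  Binit <- matrix(0L, nrow(P), ncol(P))
  if (nrow(cand) > 0L)
    Binit[cbind(cand[, 2L] - cr$offset[2L] + 1L,
                cand[, 1L] - cr$offset[1L] + 1L)] <- 1L
  list(P = P, crop = cr$crop, offset = cr$offset, cand = cand, Binit = Binit)
}

#' Track a single frame
#'
#' One iteration of the tracking pipeline: crop, segment, threshold, filter,
#' localize; computes the suspicion score of the frame's segmentation and
#' invokes the Model Update (\code{\link{relearnOnFrame}}) when it exceeds
#' the trigger threshold, after which the frame is re-detected with the
#' updated parameters. On an empty candidate set the frame is flagged lost,
#' the previous center is retained, and the next frame is re-detected on the
#' whole frame, so a transient failure does not accumulate.
#'
#' @param state tracker state, from \code{.newTrackerState} via
#'   \code{\link{trackVideo}} (treated as opaque).
#' @param frame height x width x 3 numeric array (0-255).
#' @param model the pretrained \linkS4class{ApexModel} (supplies structure;
#'   live parameters are carried in the state).
#' @param relearnEnabled run the Model Update mechanism (default TRUE).
#' @return list(state = updated state, record = one-row data.frame with
#'   columns frame, x, y, lost, relearned, suspicion).
#' @export
trackFrame <- function(state, frame, model, relearnEnabled = TRUE) {
  wide <- is.null(state$prevCenter) || state$prevLost
  det <- .detect(state, frame, model, wide)
  suspicion <- softDiceLoss(det$P, det$Binit)
  relearned <- FALSE
  rl <- state$relearn

  if (relearnEnabled && suspicion > rl$Ts) {
    Binit <- det$Binit
    if (sum(Binit) == 0L) {
      ## the trigger fired on diffuse sub-threshold probability mass (an
      ## appearance change the model half-recognizes): build the
      ## pseudo-ground-truth as a box at the map's probability-weighted
      ## centroid - the model's own best location guess - the same
      ## mechanism the optional first-frame user box uses. A confidently
      ## empty map never reaches this branch (its suspicion is ~0).
      dcrop <- dim(det$crop)[1:2]
      xg <- matrix(0:(dcrop[2L] - 1L), dcrop[1L], dcrop[2L], byrow = TRUE)
      yg <- matrix(0:(dcrop[1L] - 1L), dcrop[1L], dcrop[2L])
      ## weight by the dominant mass only, so diffuse background
      ## probability does not drag the box off the target
      Pm <- det$P * (det$P >= 0.5 * max(det$P))
      Binit <- makeMask(c(sum(xg * Pm) / sum(Pm), sum(yg * Pm) / sum(Pm)),
                        dcrop, rl$boxSide)
    }
    if (sum(Binit) > 0) {
      res <- relearnOnFrame(state$params, state$anchor, det$crop, Binit, rl)
      state$params <- res$params
      state$anchor <- res$anchor
      state$events <- rbind(state$events,
                            data.frame(frame = state$frameIndex,
                                       triggerSuspicion = suspicion,
                                       finalSuspicion = res$finalSuspicion,
                                       iterations = res$iterations))
      relearned <- TRUE
      det <- .detect(state, frame, model, wide)  # re-detect, updated model
      suspicion <- softDiceLoss(det$P, det$Binit)
    }
  }

  center <- locateCenter(det$cand)
  lost <- is.null(center)
  if (!lost) state$prevCenter <- center
  state$prevLost <- lost
  rec <- data.frame(frame = state$frameIndex,
                    x = if (lost) NA_real_ else center[1L],
                    y = if (lost) NA_real_ else center[2L],
                    lost = lost, relearned = relearned,
                    suspicion = suspicion)
  state$frameIndex <- state$frameIndex + 1L
  list(state = state, record = rec)
}

#' Track a whole video
#'
#' Resets the model to its pretrained parameters (per-video isolation of the
#' Model Update), optionally refines it on the first frame from a
#' user-supplied apex box, then iterates \code{\link{trackFrame}} over every
#' frame.
#'
#' @param seq a \linkS4class{FrameSequence} or \linkS4class{SyntheticVideo}.
#' @param model a pretrained \linkS4class{ApexModel}.
#' @param config a \code{\link{trackerConfig}}.
#' @param relearn a \code{\link{relearnConfig}}.
#' @param initBox optional c(x, y) apex center in the first frame (0-based);
#'   the model is refined on frame 0 with a mask built from it before
#'   tracking starts, and it seeds the previous-center state.
#' @param relearnEnabled run the Model Update mechanism (default TRUE).
#' @return A \linkS4class{TrackResult}.
#' @export
trackVideo <- function(seq, model, config = trackerConfig(),
                       relearn = relearnConfig(), initBox = NULL,
                       relearnEnabled = TRUE) {
  if (is(seq, "SyntheticVideo")) seq <- frameSequence(seq)
  stopifnot(is(seq, "FrameSequence"), is(model, "ApexModel"))
  st <- .newTrackerState(model, config, relearn)
  fs <- frames(seq)
  if (!is.null(initBox)) {
    d <- dim(fs[[1L]])[1:2]
    mask <- makeMask(initBox[1:2], d, relearn$boxSide)
    res <- relearnOnFrame(st$params, st$anchor, fs[[1L]], mask, relearn)
    st$params <- res$params
    st$anchor <- res$anchor
    st$prevCenter <- initBox[1:2]
  }
  recs <- vector("list", length(fs))
  for (i in seq_along(fs)) {
    out <- trackFrame(st, fs[[i]], model, relearnEnabled = relearnEnabled)
    st <- out$state
    recs[[i]] <- out$record
  }
  new("TrackResult", records = do.call(rbind, recs),
      relearnEvents = st$events, videoName = sequenceName(seq),
      config = c(unclass(config),
                 list(relearnEnabled = relearnEnabled)))
}

#' Write a trajectory CSV
#'
#' Columns \code{frame,x,y,lost,relearned}: the per-frame tracked center in
#' 0-based pixel coordinates.
#'
#' @param result a \linkS4class{TrackResult}.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeTrajectory <- function(result, path) {
  r <- records(result)
  utils::write.csv(r[, c("frame", "x", "y", "lost", "relearned")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
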