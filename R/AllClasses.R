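#' @import methods
NULL

## Central S4 containers. Frames are numeric arrays of dimension
## height x width x 3 with values on the 0-255 scale; all user-facing pixel
## coordinates are 0-based with the origin at the top-left corner, x growing
## rightward and y growing downward.

#' FrameSequence: an ordered stack of RGB frames
#'
#' Container for a time-lapse image sequence: an ordered list of RGB frames
#' (numeric arrays, height x width x 3, values in 0-255), the capture cadence
#' in minutes, and an optional spatial scale in mm per pixel used to convert
#' pixel errors to physical units.
#'
#' @slot frames list of numeric arrays, each height x width x 3, values 0-255.
#' @slot frameInterval single positive numeric, minutes between frames.
#' @slot scale single numeric, mm per pixel, or \code{NA} when unknown.
#' @slot name identifier string.
#'
#' @aliases FrameSequence
#' @exportClass FrameSequence
setClass("FrameSequence",
  representation(frames = "list", frameInterval = "numeric",
                 scale = "numeric", name = "character"),
  prototype(frameInterval = 2, scale = NA_real_, name = "sequence"))

setValidity("FrameSequence", function(object) {
  if (length(object@frames) < 1L)
    return("a FrameSequence needs at least one frame")
  d <- dim(object@frames[[1L]])
  for (i in seq_along(object@frames)) {
    f <- object@frames[[i]]
    if (!is.numeric(f) || length(dim(f)) != 3L || dim(f)[3L] != 3L)
      return(sprintf("frame %d is not a height x width x 3 numeric array", i))
    if (!identical(dim(f), d))
      return("all frames must share identical dimensions")
  }
  if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
    return("frameInterval must be a single positive number")
  if (length(object@scale) != 1L || (!is.na(object@scale) && object@scale <= 0))
    return("scale must be a single positive number or NA")
  TRUE
})

#' Construct a FrameSequence
#'
#' @param frames list of numeric height x width x 3 arrays with values 0-255.
#' @param frameInterval capture cadence in minutes (default 2).
#' @param scale mm-per-pixel scale, or \code{NA} when unknown.
#' @param name identifier string.
#' @return A \linkS4class{FrameSequence}.
#' @examples
#' f <- array(0, c(48, 64, 3))
#' fs <- FrameSequence(list(f, f), frameInterval = 2)
#' nFrames(fs)
#' @export
FrameSequence <- function(frames, frameInterval = 2, scale = NA_real_,
                          name = "sequence") {
  new("FrameSequence", frames = frames,
      frameInterval = as.numeric(frameInterval),
      scale = as.numeric(scale), name = name)
}

#' ApexModel: the apex segmentation network
#'
#' Holds the trainable parameters and configuration of the U-Net style
#' encoder-decoder segmentation network, plus its training history.
#'
#' @slot config list with elements \code{levels} (4), \code{baseChannels},
#'   \code{kernel} (3) and \code{inputChannels} (3).
#' @slot params named list of convolution layers; each layer holds nine
#'   Cin x Cout weight matrices (one per 3x3 kernel tap) and a bias vector.
#' @slot trainLog data.frame with one row per training epoch (epoch, loss).
#' @slot seed integer seed used for parameter initialization.
#'
#' @aliases ApexModel
#' @exportClass ApexModel
setClass("ApexModel",
  representation(config = "list", params = "list",
                 trainLog = "data.frame", seed = "integer"),
  prototype(trainLog = data.frame(epoch = integer(), loss = numeric()),
            seed = NA_integer_))

setValidity("ApexModel", function(object) {
  cfg <- object@config
  for (fld in c("levels", "baseChannels", "kernel"))
    if (is.null(cfg[[fld]])) return(sprintf("config lacks '%s'", fld))
  if (cfg$levels != 4L) return("levels must be 4 (fourth level is the bottleneck)")
  if (cfg$kernel != 3L) return("kernel size must be 3")
  if (length(object@params) == 0L) return("params are empty")
  TRUE
})

#' TrackResult: per-frame tracker output
#'
#' One row per tracked frame: the predicted apex center (0-based pixel
#' coordinates, \code{NA} while undetected), whether the frame was lost
#' (no surviving candidate pixels), whether a Model Update ran on it, and the
#' suspicion score of the frame's segmentation.
#'
#' @slot records data.frame with columns \code{frame}, \code{x}, \code{y},
#'   \code{lost}, \code{relearned}, \code{suspicion}.
#' @slot relearnEvents data.frame with columns \code{frame},
#'   \code{triggerSuspicion}, \code{finalSuspicion}, \code{iterations}.
#' @slot videoName identifier of the tracked sequence.
#' @slot config snapshot of the tracker configuration used.
#'
#' @aliases TrackResult
#' @exportClass TrackResult
setClass("TrackResult",
  representation(records = "data.frame", relearnEvents = "data.frame",
                 videoName = "character", config = "list"))

setValidity("TrackResult", function(object) {
  need <- c("frame", "x", "y", "lost", "relearned", "suspicion")
  if (!all(need %in% names(object@records)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  TRUE
})

#' SyntheticVideo: a generated sequence with exact ground truth
#'
#' @slot sequence the rendered \linkS4class{FrameSequence}.
#' @slot annotations data.frame \code{frame}, \code{x}, \code{y}: the rounded
#'   blob center per frame (0-based pixel coordinates).
#' @slot spec the scene specification used for rendering (see
#'   \code{\link{sceneSpec}}).
#'
#' @aliases SyntheticVideo
#' @exportClass SyntheticVideo
setClass("SyntheticVideo",
  representation(sequence = "FrameSequence", annotations = "data.frame",
                 spec = "list"))

setValidity("SyntheticVideo", function(object) {
  if (nrow(object@annotations) != length(object@sequence@frames))
    return("annotation count must equal frame count")
  TRUE
})

#' EvalReport: tracking evaluation summary
#'
#' @slot tsr tracking success rate in percent (0-100).
#' @slot errorMeanPx,errorSdPx mean and population standard deviation of the
#'   per-frame Euclidean error over successfully tracked frames, in pixels.
#' @slot errorMeanMm,errorSdMm the same in millimetres (\code{NA} without a
#'   scale).
#' @slot nSuccess number of successfully tracked frames.
#' @slot nFrames total number of scored frames.
#' @slot successRadius success radius used, in pixels.
#'
#' @aliases EvalReport
#' @exportClass EvalReport
setClass("EvalReport",
  representation(tsr = "numeric", errorMeanPx = "numeric", errorSdPx = "numeric",
                 errorMeanMm = "numeric", errorSdMm = "numeric",
                 nSuccess = "integer", nFrames = "integer",
                 successRadius = "numeric"))

## ---- generics + accessors -------------------------------------------------

#' @describeIn FrameSequence-accessors list of frames
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @describeIn FrameSequence-accessors number of frames
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @describeIn FrameSequence-accessors frame height and width, c(h, w)
#' @export
setGeneric("frameDim", function(x) standardGeneric("frameDim"))
#' @describeIn FrameSequence-accessors capture cadence in minutes
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @describeIn FrameSequence-accessors mm-per-pixel scale (NA when unknown)
#' @export
setGeneric("scaleMmPerPx", function(x) standardGeneric("scaleMmPerPx"))
#' @describeIn FrameSequence-accessors identifier string
#' @export
setGeneric("sequenceName", function(x) standardGeneric("sequenceName"))

#' Accessors for FrameSequence
#'
#' @param x a \linkS4class{FrameSequence} (or \linkS4class{SyntheticVideo}
#'   where noted).
#' @name FrameSequence-accessors
NULL

#' @rdname FrameSequence-accessors
#' @export
setMethod("frames", "FrameSequence", function(x) x@frames)
#' @rdname FrameSequence-accessors
#' @export
setMethod("nFrames", "FrameSequence", function(x) length(x@frames))
#' @rdname FrameSequence-accessors
#' @export
setMethod("frameDim", "FrameSequence", function(x) dim(x@frames[[1L]])[1:2])
#' @rdname FrameSequence-accessors
#' @export
setMethod("frameInterval", "FrameSequence", function(x) x@frameInterval)
#' @rdname FrameSequence-accessors
#' @export
setMethod("scaleMmPerPx", "FrameSequence", function(x) x@scale)
#' @rdname FrameSequence-accessors
#' @export
setMethod("sequenceName", "FrameSequence", function(x) x@name)

#' @describeIn ApexModel-accessors network configuration list
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))
#' @describeIn ApexModel-accessors parameter list
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))
#' @describeIn ApexModel-accessors per-epoch training loss log
#' @export
setGeneric("trainLog", function(x) standardGeneric("trainLog"))

#' Accessors for ApexModel
#'
#' @param x an \linkS4class{ApexModel}.
#' @name ApexModel-accessors
NULL

#' @rdname ApexModel-accessors
#' @export
setMethod("modelConfig", "ApexModel", function(x) x@config)
#' @rdname ApexModel-accessors
#' @export
setMethod("modelParams", "ApexModel", function(x) x@params)
#' @rdname ApexModel-accessors
#' @export
setMethod("trainLog", "ApexModel", function(x) x@trainLog)

#' @describeIn TrackResult-accessors per-frame records data.frame
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @describeIn TrackResult-accessors Model Update event log
#' @export
setGeneric("relearnEvents", function(x) standardGeneric("relearnEvents"))

#' Accessors for TrackResult
#'
#' @param x a \linkS4class{TrackResult}.
#' @name TrackResult-accessors
NULL

#' @rdname TrackResult-accessors
#' @export
setMethod("records", "TrackResult", function(x) x@records)
#' @rdname TrackResult-accessors
#' @export
setMethod("relearnEvents", "TrackResult", function(x) x@relearnEvents)

#' @describeIn SyntheticVideo-accessors ground-truth annotations data.frame
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @describeIn SyntheticVideo-accessors the rendered FrameSequence
#' @export
setGeneric("frameSequence", function(x) standardGeneric("frameSequence"))
#' @describeIn SyntheticVideo-accessors the scene specification
#' @export
setGeneric("sceneSpecOf", function(x) standardGeneric("sceneSpecOf"))

#' Accessors for SyntheticVideo
#'
#' @param x a \linkS4class{SyntheticVideo}.
#' @name SyntheticVideo-accessors
NULL

#' @rdname SyntheticVideo-accessors
#' @export
setMethod("annotations", "SyntheticVideo", function(x) x@annotations)
#' @rdname SyntheticVideo-accessors
#' @export
setMethod("frameSequence", "SyntheticVideo", function(x) x@sequence)
#' @rdname SyntheticVideo-accessors
#' @export
setMethod("sceneSpecOf", "SyntheticVideo", function(x) x@spec)
#' @rdname SyntheticVideo-accessors
#' @export
setMethod("frames", "SyntheticVideo", function(x) x@sequence@frames)
#' @rdname SyntheticVideo-accessors
#' @export
setMethod("nFrames", "SyntheticVideo", function(x) length(x@sequence@frames))
#' @rdname SyntheticVideo-accessors
#' @export
setMethod("frameDim", "SyntheticVideo", function(x) frameDim(x@sequence))

#' @describeIn EvalReport-accessors tracking success rate in percent
#' @export
setGeneric("tsr", function(x) standardGeneric("tsr"))

#' Accessors for EvalReport
#'
#' @param x an \linkS4class{EvalReport}.
#' @name EvalReport-accessors
NULL

#' @rdname EvalReport-accessors
#' @export
setMethod("tsr", "EvalReport", function(x) x@tsr)

## ---- show methods ---------------------------------------------------------

setMethod("show", "FrameSequence", function(object) {
  d <- frameDim(object)
  cat(sprintf("FrameSequence '%s': %d frame(s) of %dx%d px, %g min/frame",
              object@name, nFrames(object), d[2L], d[1L],
              object@frameInterval))
  if (!is.na(object@scale))
    cat(sprintf(", %.3f mm/px", object@scale))
  cat("\n")
})

setMethod("show", "ApexModel", function(object) {
  np <- sum(rapply(object@params, length, how = "unlist"))
  cat(sprintf(paste0("ApexModel: %d-level U-Net style segmentation network\n",
                     "  base channels: %d | kernel: %dx%d | parameters: %d\n"),
              object@config$levels, object@config$baseChannels,
              object@config$kernel, object@config$kernel, np))
  if (nrow(object@trainLog) > 0L)
    cat(sprintf("  trained %d epoch(s), final epoch-mean loss %.4f\n",
                max(object@trainLog$epoch),
                object@trainLog$loss[nrow(object@trainLog)]))
})

setMethod("show", "TrackResult", function(object) {
  r <- object@records
  cat(sprintf(paste0("TrackResult '%s': %d frame(s), %d lost, ",
                     "%d Model Update event(s)\n"),
              object@videoName, nrow(r), sum(r$lost),
              nrow(object@relearnEvents)))
})

setMethod("show", "SyntheticVideo", function(object) {
  d <- frameDim(object)
  cat(sprintf("SyntheticVideo: %d annotated frame(s) of %dx%d px (seed %s)\n",
              nFrames(object), d[2L], d[1L],
              format(object@spec$seed)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: TSR %.1f%% (%d/%d frames within %g px)\n",
              object@tsr, object@nSuccess, object@nFrames,
              object@successRadius))
  if (object@nSuccess > 0L) {
    cat(sprintf("  error: %.2f +/- %.2f px", object@errorMeanPx,
                object@errorSdPx))
    if (!is.na(object@errorMeanMm))
      cat(sprintf(" (%.2f +/- %.2f mm)", object@errorMeanMm,
                  object@errorSdMm))
    cat("\n")
  }
})
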