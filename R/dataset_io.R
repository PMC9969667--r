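## Reading/writing sequences, annotations and manifests; ground-truth masks;
## pixel-to-mm conversion. Pixel coordinates in files and in the API are
## 0-based (top-left origin, x rightward, y downward).

.IMG_EXT <- c("png", "tif", "tiff", "jpg", "jpeg")

.readFrame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("reading JPEG frames requires the EBImage package", call. = FALSE)
      a <- EBImage::imageData(EBImage::readImage(path))
      ## EBImage stores width x height [x channels]
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
    },
    stop(sprintf("unsupported frame format '%s' in %s", ext, path),
         call. = FALSE))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img * 255
}

## bilinear resize of an h x w x 3 array to target c(h2, w2)
.resizeFrame <- function(img, target) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  h2 <- target[1L]; w2 <- target[2L]
  if (h == h2 && w == w2) return(img)
  if (requireNamespace("EBImage", quietly = TRUE)) {
    a <- EBImage::resize(EBImage::Image(aperm(img / 255, c(2L, 1L, 3L)),
                                        colormode = "Color"),
                         w = w2, h = h2)
    return(aperm(EBImage::imageData(a), c(2L, 1L, 3L)) * 255)
  }
  ## bilinear fallback
  sy <- (seq_len(h2) - 0.5) * h / h2 + 0.5
  sx <- (seq_len(w2) - 0.5) * w / w2 + 0.5
  y0 <- pmin(pmax(floor(sy), 1L), h); y1 <- pmin(y0 + 1L, h)
  x0 <- pmin(pmax(floor(sx), 1L), w); x1 <- pmin(x0 + 1L, w)
  fy <- pmin(pmax(sy - y0, 0), 1);    fx <- pmin(pmax(sx - x0, 0), 1)
  out <- array(0, c(h2, w2, 3L))
  for (ch in 1:3) {
    p <- img[, , ch]
    a <- p[y0, x0] * (1 - fy) + p[y1, x0] * fy
    b <- p[y0, x1] * (1 - fy) + p[y1, x1] * fy
    out[, , ch] <- a * matrix(1 - fx, h2, w2, byrow = TRUE) +
                   b * matrix(fx, h2, w2, byrow = TRUE)
  }
  out
}

#' Load a frame sequence from disk
#'
#' Reads a directory of numbered image frames (PNG/TIFF/JPEG) into a
#' \linkS4class{FrameSequence}. Frames are sorted by file name, so zero-padded
#' indices sort correctly. Frames whose size differs from \code{targetSize}
#' are resized (bilinear) with a warning, because the tracker's segmentation
#' network is trained at a fixed working resolution; pass
#' \code{targetSize = NA} to keep the native size. Video container files
#' (MP4/AVI) are not decodable here; extract frames to images first.
#'
#' @param path directory containing image frames.
#' @param targetSize c(height, width) the frames must have; default
#'   c(480, 640). Use \code{NA} to disable resizing.
#' @param frameInterval capture cadence in minutes.
#' @param scale optional mm-per-pixel scale.
#' @param name sequence identifier; defaults to the directory name.
#' @return A \linkS4class{FrameSequence}.
#' @export
loadSequence <- function(path, targetSize = c(480L, 640L), frameInterval = 2,
                         scale = NA_real_, name = basename(path)) {
  if (!file.exists(path))
    stop(sprintf("cannot read input '%s': no such file or directory", path),
         call. = FALSE)
  if (!dir.exists(path)) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("mp4", "avi", "mov", "mkv"))
      stop(sprintf(paste0("'%s' is a video container; no decoder is ",
                          "available - extract frames to a directory of ",
                          "PNG images first"), path), call. = FALSE)
    stop(sprintf("'%s' is not a directory of image frames", path),
         call. = FALSE)
  }
  files <- list.files(path, full.names = TRUE)
  files <- files[tolower(tools::file_ext(files)) %in% .IMG_EXT]
  if (length(files) == 0L)
    stop(sprintf("no readable image frames found in '%s'", path),
         call. = FALSE)
  files <- files[order(basename(files))]
  frms <- lapply(files, .readFrame)
  if (!anyNA(targetSize)) {
    d <- dim(frms[[1L]])[1:2]
    if (!all(d == targetSize)) {
      warning(sprintf(
        "frames in '%s' are %dx%d; resizing to the %dx%d working resolution",
        path, d[2L], d[1L], targetSize[2L], targetSize[1L]), call. = FALSE)
    }
    frms <- lapply(frms, .resizeFrame, target = targetSize)
  }
  FrameSequence(frms, frameInterval = frameInterval, scale = scale,
                name = name)
}

#' Write a frame sequence as numbered PNG files
#'
#' @param seq a \linkS4class{FrameSequence} or \linkS4class{SyntheticVideo}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
writeSequence <- function(seq, dir) {
  if (is(seq, "SyntheticVideo")) seq <- frameSequence(seq)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nFrames(seq))
  for (i in seq_len(nFrames(seq))) {
    paths[i] <- file.path(dir, sprintf("frame_%05d.png", i - 1L))
    png::writePNG(pmin(pmax(seq@frames[[i]] / 255, 0), 1), paths[i])
  }
  invisible(paths)
}

#' Read apex annotations from a CSV file
#'
#' The annotation format is a CSV with header \code{frame,x,y}: one row per
#' annotated frame, 0-based frame index and 0-based integer pixel coordinates
#' of the apex box center.
#'
#' @param path CSV file path.
#' @param frameSize optional c(height, width); when given, coordinates are
#'   validated against the frame bounds.
#' @return data.frame with integer columns \code{frame}, \code{x}, \code{y},
#'   sorted by frame.
#' @export
readAnnotations <- function(path, frameSize = NULL) {
  if (!file.exists(path))
    stop(sprintf("cannot read annotations '%s'", path), call. = FALSE)
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!identical(names(df), c("frame", "x", "y")))
    stop(sprintf("'%s': expected header 'frame,x,y', got '%s'",
                 path, paste(names(df), collapse = ",")), call. = FALSE)
  bad <- which(!stats::complete.cases(df) | df$frame < 0 |
                 df$frame != round(df$frame))
  if (length(bad) > 0L)
    stop(sprintf("'%s': malformed row at line %d", path, bad[1L] + 1L),
         call. = FALSE)
  dup <- which(duplicated(df$frame))
  if (length(dup) > 0L)
    stop(sprintf("'%s': duplicate frame index %d at line %d",
                 path, df$frame[dup[1L]], dup[1L] + 1L), call. = FALSE)
  if (!is.null(frameSize)) {
    oob <- df$x < 0 | df$x > frameSize[2L] - 1L |
           df$y < 0 | df$y > frameSize[1L] - 1L
    if (any(oob))
      stop(sprintf("'%s': annotation at frame %d is outside the %dx%d frame",
                   path, df$frame[which(oob)[1L]],
                   frameSize[2L], frameSize[1L]), call. = FALSE)
  }
  df <- df[order(df$frame), , drop = FALSE]
  rownames(df) <- NULL
  df$frame <- as.integer(df$frame)
  df$x <- as.integer(round(df$x)); df$y <- as.integer(round(df$y))
  df
}

#' Write apex annotations to CSV
#'
#' @param ann data.frame with columns \code{frame}, \code{x}, \code{y}.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeAnnotations <- function(ann, path) {
  stopifnot(all(c("frame", "x", "y") %in% names(ann)))
  utils::write.csv(ann[, c("frame", "x", "y")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Build the ground-truth segmentation mask for one annotation
#'
#' The mask is a binary image with a \code{boxSide} x \code{boxSide} square of
#' ones centered on the annotated apex center, clipped at the frame borders
#' (the box is never shifted, so it stays centered on the true apex).
#'
#' @param center c(x, y) 0-based pixel coordinates of the apex center.
#' @param frameSize c(height, width) of the frame.
#' @param boxSide odd positive integer; default 33.
#' @return Integer matrix (height x width) of 0/1 values.
#' @examples
#' m <- makeMask(c(100, 100), c(480, 640))
#' sum(m)  # 1089 = 33 * 33
#' @export
makeMask <- function(center, frameSize, boxSide = 33L) {
  boxSide <- as.integer(boxSide)
  if (boxSide < 1L || boxSide %% 2L == 0L)
    stop("boxSide must be an odd positive integer", call. = FALSE)
  h <- frameSize[1L]; w <- frameSize[2L]
  cx <- round(center[1L]); cy <- round(center[2L])
  if (cx < 0 || cx > w - 1L || cy < 0 || cy > h - 1L)
    stop(sprintf("annotation center (%g, %g) outside %dx%d frame",
                 center[1L], center[2L], w, h), call. = FALSE)
  r <- (boxSide - 1L) %/% 2L
  x0 <- max(cx - r, 0L); x1 <- min(cx + r, w - 1L)
  y0 <- max(cy - r, 0L); y1 <- min(cy + r, h - 1L)
  m <- matrix(0L, h, w)
  m[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L)] <- 1L
  m
}

#' Convert a pixel distance to millimetres
#'
#' @param distancePx non-negative distance in pixels.
#' @param scaleMmPerPx positive mm-per-pixel scale of the video.
#' @return Distance in mm.
#' @examples
#' pxToMm(10, 0.276)  # 2.76
#' @export
pxToMm <- function(distancePx, scaleMmPerPx) {
  if (missing(scaleMmPerPx) || length(scaleMmPerPx) != 1L ||
      is.na(scaleMmPerPx))
    stop(paste("no mm/pixel scale known for this video; supply one",
               "(e.g. from the acquisition ruler)"), call. = FALSE)
  if (scaleMmPerPx <= 0) stop("scaleMmPerPx must be positive", call. = FALSE)
  stopifnot(all(distancePx >= 0))
  distancePx * scaleMmPerPx
}

#' Read a dataset manifest
#'
#' A manifest is a YAML list of entries, each with fields \code{video}
#' (frame directory), \code{annotations} (CSV path), \code{split} (one of
#' train/val/test) and optional \code{scale} (mm per pixel). Paths are
#' resolved relative to the manifest file.
#'
#' @param path YAML manifest path.
#' @param checkPaths verify that every referenced path is readable
#'   (default TRUE).
#' @return data.frame with columns \code{video}, \code{annotations},
#'   \code{split}, \code{scale}.
#' @export
readManifest <- function(path, checkPaths = TRUE) {
  if (!file.exists(path))
    stop(sprintf("cannot read manifest '%s'", path), call. = FALSE)
  y <- yaml::read_yaml(path)
  if (length(y) == 0L) stop("manifest is empty", call. = FALSE)
  base <- dirname(normalizePath(path))
  rel <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  df <- do.call(rbind, lapply(y, function(e) {
    if (is.null(e$video) || is.null(e$annotations) || is.null(e$split))
      stop("manifest entry lacks video/annotations/split", call. = FALSE)
    if (!e$split %in% c("train", "val", "test"))
      stop(sprintf("invalid split '%s'", e$split), call. = FALSE)
    data.frame(video = rel(e$video), annotations = rel(e$annotations),
               split = e$split,
               scale = if (is.null(e$scale)) NA_real_ else as.numeric(e$scale))
  }))
  if (checkPaths) {
    miss <- c(df$video, df$annotations)
    miss <- miss[!file.exists(miss)]
    if (length(miss) > 0L)
      stop(sprintf("manifest references unreadable path '%s'", miss[1L]),
           call. = FALSE)
  }
  df
}
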