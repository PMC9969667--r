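## Evaluation: per-frame Euclidean error, tracking success rate (TSR) with
## mm conversion, a paired Wilcoxon signed-rank comparison, and a
## sum-of-absolute-differences block-matching baseline tracker.

#' Euclidean tracking error
#'
#' @param truth c(x, y) ground-truth apex center.
#' @param pred c(x, y) predicted center.
#' @return Distance in pixels.
#' @examples
#' euclideanError(c(0, 0), c(3, 4))  # 5
#' @export
euclideanError <- function(truth, pred) {
  sqrt((truth[1L] - pred[1L])^2 + (truth[2L] - pred[2L])^2)
}

#' Score a tracking result against ground truth
#'
#' A frame counts as successfully tracked when a prediction exists, the
#' frame is not flagged lost, and its Euclidean error is at most
#' \code{successRadius} pixels. TSR is the percentage of successful frames;
#' the error mean and population standard deviation are computed over the
#' successful frames only, and converted to mm when a scale is known
#' (conversion applied to the per-frame errors).
#'
#' The success-radius semantics are this package's operational definition of
#' per-frame success; its default of 20 px is the observed upper bound on
#' per-frame apex motion at the full 640x480 working resolution, and should
#' be scaled along with the frame size for reduced-resolution material.
#'
#' @param result a \linkS4class{TrackResult}.
#' @param ann annotations data.frame (\code{frame}, \code{x}, \code{y})
#'   covering every tracked frame.
#' @param successRadius success radius in pixels, default 20.
#' @param scale optional mm-per-pixel scale.
#' @return An \linkS4class{EvalReport}.
#' @export
scoreTrack <- function(result, ann, successRadius = 20, scale = NA_real_) {
  stopifnot(is(result, "TrackResult"))
  r <- records(result)
  if (!all(r$frame %in% ann$frame))
    stop("annotations do not cover every tracked frame", call. = FALSE)
  a <- ann[match(r$frame, ann$frame), ]
  eps <- sqrt((a$x - r$x)^2 + (a$y - r$y)^2)
  ok <- !r$lost & !is.na(eps) & eps <= successRadius
  n <- nrow(r)
  e <- eps[ok]
  popSd <- function(v) if (length(v) > 0L) sqrt(mean((v - mean(v))^2)) else NA_real_
  new("EvalReport",
      tsr = 100 * sum(ok) / n,
      errorMeanPx = if (any(ok)) mean(e) else NA_real_,
      errorSdPx = popSd(e),
      errorMeanMm = if (any(ok) && !is.na(scale)) mean(pxToMm(e, scale))
                    else NA_real_,
      errorSdMm = if (any(ok) && !is.na(scale)) popSd(pxToMm(e, scale))
                  else NA_real_,
      nSuccess = sum(ok), nFrames = as.integer(n),
      successRadius = successRadius)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on the per-frame error differences
#' \code{a - b}. Zero differences are dropped; tied absolute differences
#' receive averaged ranks. For \code{n <= exactMax} non-zero pairs the
#' p-value comes from exact enumeration of all 2^n sign assignments (by
#' convolution of the rank distribution); beyond that a normal approximation
#' with tie-corrected variance is used (no continuity correction).
#'
#' @param a,b equal-length numeric vectors of paired per-frame errors,
#'   restricted to frames before either tracker fails.
#' @param exactMax largest n for which the exact distribution is enumerated,
#'   default 25.
#' @return list(statistic = sum of positive-difference ranks, pValue,
#'   n = number of non-zero pairs, exact = logical).
#' @export
wilcoxonPaired <- function(a, b, exactMax = 25L) {
  if (length(a) != length(b)) stop("unequal pair lengths", call. = FALSE)
  if (length(a) < 5L) stop("need at least 5 pairs", call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("all differences are zero: the signed-rank test is degenerate",
         call. = FALSE)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  if (n <= exactMax) {
    ## exact null distribution of W over all 2^n sign assignments, via
    ## convolution on doubled (integer) ranks
    r2 <- as.integer(round(2 * rk))
    tot <- sum(r2)
    cnt <- numeric(tot + 1L)   # cnt[s+1] = #assignments with doubled-sum s
    cnt[1L] <- 1
    for (r in r2) {
      shifted <- c(numeric(r), cnt[seq_len(tot + 1L - r)])
      cnt <- cnt + shifted
    }
    probs <- cnt / 2^n
    w2 <- as.integer(round(2 * W))
    pLe <- sum(probs[seq_len(w2 + 1L)])
    pGe <- sum(probs[(w2 + 1L):(tot + 1L)])
    p <- min(1, 2 * min(pLe, pGe))
    return(list(statistic = W, pValue = p, n = n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu) / sqrt(sig2)
  list(statistic = W, pValue = 2 * stats::pnorm(-abs(z)), n = n,
       exact = FALSE)
}

#' Block-matching baseline tracker
#'
#' A sum-of-absolute-differences (SAD) template tracker: each frame, the
#' grayscale block around the previous center in the previous frame is
#' matched against every integer displacement within \code{searchRadius};
#' the displacement with the smallest SAD wins, ties broken by the smallest
#' displacement magnitude and then row-major order. The baseline cannot
#' detect the apex by itself, so an initial center must be given.
#'
#' @param seq a \linkS4class{FrameSequence} or \linkS4class{SyntheticVideo}.
#' @param initCenter c(x, y) apex center in the first frame (0-based).
#' @param blockSide template block side in pixels (odd), default 33.
#' @param searchRadius maximum displacement per frame in pixels, default 20.
#' @return A \linkS4class{TrackResult} (lost is always FALSE; suspicion NA).
#' @export
blockMatchingBaseline <- function(seq, initCenter, blockSide = 33L,
                                  searchRadius = 20L) {
  if (is(seq, "SyntheticVideo")) seq <- frameSequence(seq)
  stopifnot(is(seq, "FrameSequence"), blockSide %% 2L == 1L,
            searchRadius >= 0L)
  fs <- frames(seq)
  h <- dim(fs[[1L]])[1L]; w <- dim(fs[[1L]])[2L]
  r <- (blockSide - 1L) %/% 2L
  gray <- lapply(fs, function(f) (f[, , 1L] + f[, , 2L] + f[, , 3L]) / 3)

  clampCenter <- function(cx, cy) {
    ncx <- min(max(cx, r), w - 1L - r)
    ncy <- min(max(cy, r), h - 1L - r)
    if (ncx != cx || ncy != cy)
      warning("block would leave the frame; clamping", call. = FALSE)
    c(ncx, ncy)
  }
  block <- function(g, cx, cy)
    g[(cy - r + 1L):(cy + r + 1L), (cx - r + 1L):(cx + r + 1L)]

  cx <- as.integer(round(initCenter[1L])); cy <- as.integer(round(initCenter[2L]))
  cc <- clampCenter(cx, cy); cx <- cc[1L]; cy <- cc[2L]
  recs <- vector("list", length(fs))
  recs[[1L]] <- data.frame(frame = 0L, x = cx, y = cy, lost = FALSE,
                           relearned = FALSE, suspicion = NA_real_)
  for (i in seq_along(fs)[-1L]) {
    tmpl <- block(gray[[i - 1L]], cx, cy)
    best <- Inf; bx <- 0L; by <- 0L
    for (dy in -searchRadius:searchRadius) {       # row-major: y outer
      for (dx in -searchRadius:searchRadius) {
        nx <- cx + dx; ny <- cy + dy
        if (nx < r || nx > w - 1L - r || ny < r || ny > h - 1L - r) next
        sad <- sum(abs(block(gray[[i]], nx, ny) - tmpl))
        better <- sad < best ||
          (sad == best && (dx^2 + dy^2 < bx^2 + by^2))
        if (better) { best <- sad; bx <- dx; by <- dy }
      }
    }
    cx <- cx + bx; cy <- cy + by
    recs[[i]] <- data.frame(frame = i - 1L, x = cx, y = cy, lost = FALSE,
                            relearned = FALSE, suspicion = NA_real_)
  }
  new("TrackResult", records = do.call(rbind, recs),
      relearnEvents = data.frame(frame = integer(),
                                 triggerSuspicion = numeric(),
                                 finalSuspicion = numeric(),
                                 iterations = integer()),
      videoName = sequenceName(seq),
      config = list(method = "block-matching", blockSide = blockSide,
                    searchRadius = searchRadius))
}
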