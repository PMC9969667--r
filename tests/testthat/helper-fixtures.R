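## Shared fixtures. The reduced-scale tracker configuration mirrors the
## full-scale defaults scaled by 96/640: R1 20 (41x41 crops), R2 8, R3 4,
## success radius 3 px. The shared segmentation model is trained once per
## test run (on first use) on 50 reduced synthetic frame/mask pairs and
## memoized, so the end-to-end tracking tests do not retrain.

.fixtures <- new.env(parent = emptyenv())

reducedTrackerConfig <- function(...) trackerConfig(R1 = 20, R2 = 8, R3 = 4, ...)

reducedRelearnConfig <- function(...) relearnConfig(boxSide = 9L, ...)

REDUCED_SUCCESS_RADIUS <- 3  # 20 px default scaled by 96/640

sharedTrainedModel <- function() {
  if (is.null(.fixtures$model)) {
    specs <- lapply(1:2, function(s) reducedSceneSpec(nFrames = 25L, seed = s))
    ds <- generateTrainingSet(specs, boxSide = 9L)
    m <- buildNetwork(baseChannels = 4L, seed = 11L)
    .fixtures$model <- trainNetwork(m, ds, reducedTrainConfig(seed = 11L))
  }
  .fixtures$model
}

## independent brute-force Soft Dice evaluation (double loop, no vectorized
## shortcuts shared with the implementation)
bruteDice <- function(P, B) {
  inter <- 0; sp <- 0; sb <- 0
  for (i in seq_along(P)) {
    inter <- inter + P[i] * B[i]
    sp <- sp + P[i]
    sb <- sb + B[i]
  }
  1 - (inter + 1) / (sp + sb - inter + 1)
}

## independent brute-force outlier filter
bruteFilter <- function(pts, prev, R2, R3) {
  keep1 <- pts[apply(pts, 1L, function(p)
    sqrt(sum((p - prev)^2)) <= R2), , drop = FALSE]
  if (nrow(keep1) == 0L) return(keep1)
  xm <- median(keep1[, 1L]); ym <- median(keep1[, 2L])
  keep1[abs(keep1[, 1L] - xm) <= R3 & abs(keep1[, 2L] - ym) <= R3, ,
        drop = FALSE]
}

## exact Wilcoxon signed-rank p by explicit enumeration of sign vectors
bruteWilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% rk)
  pLe <- mean(Ws <= W + 1e-9)
  pGe <- mean(Ws >= W - 1e-9)
  list(statistic = W, pValue = min(1, 2 * min(pLe, pGe)))
}
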