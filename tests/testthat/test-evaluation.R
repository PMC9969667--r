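test_that("Euclidean error is the plain distance", {
  expect_equal(euclideanError(c(0, 0), c(3, 4)), 5)
  expect_equal(euclideanError(c(2, 2), c(2, 2)), 0)
  expect_equal(euclideanError(c(1, 1), c(4, 5)), 5)
})

.mkResult <- function(x, y, lost = rep(FALSE, length(x))) {
  new("TrackResult",
      records = data.frame(frame = seq_along(x) - 1L, x = x, y = y,
                           lost = lost, relearned = FALSE,
                           suspicion = NA_real_),
      relearnEvents = data.frame(frame = integer(),
                                 triggerSuspicion = numeric(),
                                 finalSuspicion = numeric(),
                                 iterations = integer()),
      videoName = "fixture", config = list())
}

test_that("scoring matches a brute-force per-frame recomputation", {
  set.seed(9)
  n <- 10L
  ann <- data.frame(frame = 0:(n - 1), x = sample(50:100, n),
                    y = sample(50:100, n))
  ## 7 frames within 5 px, 3 pushed far out
  dx <- c(rep(2, 7), rep(30, 3))
  res <- .mkResult(ann$x + dx, ann$y)
  rep <- scoreTrack(res, ann, successRadius = 5)
  expect_equal(tsr(rep), 70)
  expect_equal(rep@nSuccess, 7L)
  expect_equal(rep@errorMeanPx, 2)
  expect_equal(rep@errorSdPx, 0)

  ## brute force on a random fixture with lost frames
  err <- runif(n, 0, 10)
  theta <- runif(n, 0, 2 * pi)
  lost <- c(rep(FALSE, 8), TRUE, FALSE)
  res2 <- .mkResult(ann$x + err * cos(theta), ann$y + err * sin(theta), lost)
  rep2 <- scoreTrack(res2, ann, successRadius = 6, scale = 0.276)
  ok <- !lost & err <= 6
  expect_equal(tsr(rep2), 100 * sum(ok) / n)
  expect_equal(rep2@errorMeanPx, mean(err[ok]), tolerance = 1e-9)
  expect_equal(rep2@errorSdPx, sqrt(mean((err[ok] - mean(err[ok]))^2)),
               tolerance = 1e-9)
  expect_equal(rep2@errorMeanMm, 0.276 * rep2@errorMeanPx)

  ## degenerate: nothing within radius
  rep3 <- scoreTrack(.mkResult(ann$x + 100, ann$y), ann, successRadius = 5)
  expect_equal(tsr(rep3), 0)
  expect_true(is.na(rep3@errorMeanPx))

  expect_error(scoreTrack(res, ann[1:5, ]), "cover")
})

test_that("the signed-rank test matches exact enumeration for small n", {
  set.seed(31)
  for (i in 1:12) {
    n <- sample(6:12, 1)
    a <- runif(n, 0, 10)
    b <- a + rnorm(n, sd = 2)
    ## include occasional exact ties in |difference|
    if (i %% 3 == 0) b[2] <- a[2] + (a[1] - b[1])
    got <- wilcoxonPaired(a, b)
    want <- bruteWilcoxon(a - b)
    expect_true(got$exact)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$pValue, want$pValue, tolerance = 1e-12)
  }
})

test_that("the signed-rank test agrees with stats::wilcox.test on clean data", {
  set.seed(5)
  a <- runif(12); b <- runif(12)       # continuous: no ties, no zeros
  got <- wilcoxonPaired(a, b)
  ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$pValue, ref$p.value, tolerance = 1e-12)

  ## large-n normal approximation
  a2 <- runif(60); b2 <- runif(60)
  got2 <- wilcoxonPaired(a2, b2)
  ref2 <- wilcox.test(a2, b2, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_false(got2$exact)
  expect_equal(got2$pValue, ref2$p.value, tolerance = 1e-12)
})

test_that("the signed-rank test detects a consistent improvement", {
  set.seed(8)
  b <- runif(20, 1, 3)
  a <- b - 0.5                      # uniformly smaller errors
  expect_lt(wilcoxonPaired(a, b)$pValue, 0.05)
  ## symmetric null: paired shuffle of identical values
  v <- c(1:10 / 10)
  expect_equal(wilcoxonPaired(c(v, v + 1), c(v + 1, v))$pValue, 1)
  expect_error(wilcoxonPaired(v, v), "degenerate")
  expect_error(wilcoxonPaired(1:3, 4:6), "at least 5")
  expect_error(wilcoxonPaired(1:6, 1:5), "unequal")
})

test_that("block matching recovers translations and handles degenerate cases", {
  ## textured static scene: zero displacement every frame
  set.seed(14)
  base <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  static <- FrameSequence(list(base, base, base))
  tr <- blockMatchingBaseline(static, c(32, 32), blockSide = 9L,
                              searchRadius = 5L)
  expect_true(all(records(tr)$x == 32))
  expect_true(all(records(tr)$y == 32))

  ## pure integer translation is recovered exactly
  shift <- function(img, dx, dy) {
    out <- array(0, dim(img))
    out[(1 + dy):64, (1 + dx):64, ] <- img[1:(64 - dy), 1:(64 - dx), ]
    out
  }
  moving <- FrameSequence(list(base, shift(base, 2, 1), shift(base, 4, 2)))
  tr2 <- blockMatchingBaseline(moving, c(20, 20), blockSide = 9L,
                               searchRadius = 5L)
  expect_equal(records(tr2)$x, c(20, 22, 24))
  expect_equal(records(tr2)$y, c(20, 21, 22))

  ## zero search radius: the center never moves
  tr3 <- blockMatchingBaseline(moving, c(20, 20), blockSide = 9L,
                               searchRadius = 0L)
  expect_true(all(records(tr3)$x == 20))

  ## an initial center at the border is clamped with a warning
  expect_warning(blockMatchingBaseline(static, c(1, 1), blockSide = 9L,
                                       searchRadius = 2L), "clamp")
})
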