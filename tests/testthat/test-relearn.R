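test_that("suspicion follows the Soft Dice loss on segmentation maps", {
  ## exact agreement: suspicion 0
  B <- matrix(0L, 6, 6); B[2:4, 2:4] <- 1L
  expect_equal(computeSuspicion(B * 1.0, B), 0)
  ## disjoint support with sum(P)=3, sum(B)=4: 1 - 1/8
  P <- matrix(0, 4, 4); P[1, 1:3] <- 1
  B2 <- matrix(0L, 4, 4); B2[3:4, 3:4] <- 1L
  expect_equal(computeSuspicion(P, B2), 1 - 1 / 8)
  ## both empty: no spurious trigger
  expect_equal(computeSuspicion(matrix(0, 4, 4), matrix(0L, 4, 4)), 0)
})

test_that("the blended update matches hand algebra and its limits", {
  ## scalar fixture: 0.5*1 + 0.5*(2 - 0.5) = 1.25
  got <- blendedUpdate(list(w = 2), list(w = 1), list(w = 5),
                       eta = 0.1, alpha = 0.5)
  expect_equal(got$w, 1.25)

  ## alpha -> 1 reduces to a plain SGD step
  set.seed(3)
  Wk <- list(a = matrix(rnorm(6), 2, 3), b = rnorm(4))
  WT <- list(a = matrix(rnorm(6), 2, 3), b = rnorm(4))
  g <- list(a = matrix(rnorm(6), 2, 3), b = rnorm(4))
  sgd <- blendedUpdate(Wk, WT, g, eta = 0.2, alpha = 1)
  expect_equal(sgd$a, Wk$a - 0.2 * g$a)
  expect_equal(sgd$b, Wk$b - 0.2 * g$b)

  ## zero gradient at the anchor is a fixed point
  zg <- list(a = matrix(0, 2, 3), b = numeric(4))
  expect_equal(blendedUpdate(WT, WT, zg, eta = 0.5, alpha = 0.7), WT)

  ## element-wise brute force on random small parameter sets
  for (i in 1:25) {
    eta <- runif(1); alpha <- runif(1, 0.05, 0.95)
    got <- blendedUpdate(Wk, WT, g, eta, alpha)
    for (nm in names(got)) {
      want <- (1 - alpha) * WT[[nm]] + alpha * (Wk[[nm]] - eta * g[[nm]])
      expect_equal(got[[nm]], want, tolerance = 1e-12)
    }
  }

  expect_error(blendedUpdate(list(w = 1:2), list(w = 1), list(w = 0), 1, 0.5),
               "structures")
})

test_that("iterating the update with zero gradient contracts to the anchor", {
  W <- list(w = 5); WT <- list(w = 1); zg <- list(w = 0)
  alpha <- 0.6
  dist <- abs(W$w - WT$w)
  for (k in 1:6) {
    W <- blendedUpdate(W, WT, zg, eta = 0.3, alpha = alpha)
    expect_equal(abs(W$w - WT$w), dist * alpha^k, tolerance = 1e-12)
  }
})

test_that("the refinement loop honours its caps and adapts when allowed", {
  m <- buildNetwork(baseChannels = 2L, seed = 7L)
  crop <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  B <- makeMask(c(16, 16), c(32, 32), 9L)

  ## a zero time cap returns immediately with parameters untouched
  res0 <- relearnOnFrame(m@params, m@params, crop, B,
                         relearnConfig(timeCapS = 0))
  expect_equal(res0$iterations, 0L)
  expect_identical(res0$params, m@params)

  ## the iteration cap bounds the loop deterministically
  res2 <- relearnOnFrame(m@params, m@params, crop, B,
                         relearnConfig(maxIters = 3L, timeCapS = 60))
  expect_lte(res2$iterations, 3L)
  ## refined parameters become the new anchor
  expect_identical(res2$params, res2$anchor)

  ## with room to iterate, the suspicion moves toward the target
  res3 <- relearnOnFrame(m@params, m@params, crop, B,
                         relearnConfig(maxIters = 40L, timeCapS = 60))
  expect_lt(res3$finalSuspicion, res0$finalSuspicion)
})

test_that("the anchor excursion shrinks as the anchor weight grows", {
  ## for a fixed gradient stream, the distance from the pretrained anchor
  ## is increasing in alpha (decreasing in 1 - alpha)
  g <- list(w = 1)
  WT <- list(w = 0)
  excursion <- function(alpha) {
    W <- WT
    for (k in 1:50) W <- blendedUpdate(W, WT, g, eta = 0.1, alpha = alpha)
    abs(W$w - WT$w)
  }
  e <- vapply(c(0.3, 0.6, 0.9), excursion, numeric(1))
  expect_true(all(diff(e) > 0))
  ## and is bounded by the geometric-series limit alpha*eta*|g|/(1-alpha)
  expect_lte(e[3L], 0.9 * 0.1 * 1 / (1 - 0.9) + 1e-9)
})

test_that("model reset restores the pretrained snapshot exactly", {
  m <- buildNetwork(baseChannels = 2L, seed = 12L)
  crop <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  B <- makeMask(c(16, 16), c(32, 32), 9L)
  res <- relearnOnFrame(m@params, m@params, crop, B,
                        relearnConfig(maxIters = 5L, timeCapS = 60))
  expect_false(identical(res$params, m@params))
  st <- resetModel(m)
  expect_identical(st$params, m@params)
  expect_identical(st$anchor, m@params)
  expect_identical(resetModel(m), resetModel(m))
})
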