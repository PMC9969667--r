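test_that("degenerate kinematics produce the expected annotation tracks", {
  ## zero semi-axes, zero growth: stationary blob
  s <- reducedSceneSpec(nFrames = 8L, seed = 1L, semiAxes = c(0, 0),
                        growth = 0)
  v <- generateVideo(s)
  ann <- annotations(v)
  expect_equal(nrow(ann), 8L)
  expect_true(all(ann$x == 48L))
  expect_true(all(ann$y == 60L))

  ## pure growth: y decreases by exactly 1 px per frame
  s2 <- reducedSceneSpec(nFrames = 10L, seed = 1L, semiAxes = c(0, 0),
                         omega = 0, growth = 1, center = c(48, 80))
  ann2 <- annotations(generateVideo(s2))
  expect_equal(diff(ann2$y), rep(-1L, 9L))
})

test_that("rendering is deterministic under the seed", {
  s <- reducedSceneSpec(nFrames = 5L, seed = 21L)
  v1 <- generateVideo(s)
  v2 <- generateVideo(s)
  expect_identical(frames(v1), frames(v2))
  expect_identical(annotations(v1), annotations(v2))
})

test_that("the rendered blob centroid matches the annotation within 1 px", {
  s <- reducedSceneSpec(nFrames = 12L, seed = 4L, noiseSigma = 0)
  v <- generateVideo(s)
  bg <- mean(s$background)
  for (i in c(1L, 6L, 12L)) {
    f <- frames(v)[[i]]
    lum <- (f[, , 1] + f[, , 2] + f[, , 3]) / 3 - bg
    lum[lum < 1] <- 0   # drop residual background so only the blob weighs in
    xg <- matrix(0:(ncol(lum) - 1), nrow(lum), ncol(lum), byrow = TRUE)
    yg <- matrix(0:(nrow(lum) - 1), nrow(lum), ncol(lum))
    cx <- sum(xg * lum) / sum(lum)
    cy <- sum(yg * lum) / sum(lum)
    ann <- annotations(v)[i, ]
    expect_lt(sqrt((cx - ann$x)^2 + (cy - ann$y)^2), 1)
  }
})

test_that("per-frame displacement respects the 20 px motion bound", {
  for (seed in 1:5) {
    ann <- annotations(generateVideo(reducedSceneSpec(nFrames = 40L,
                                                      seed = seed)))
    d <- sqrt(diff(ann$x)^2 + diff(ann$y)^2)
    expect_true(all(d <= 20))
  }
  ## a spec that would exceed the bound is rejected outright
  expect_error(sceneSpec(nFrames = 10L, semiAxes = c(120, 80),
                         omega = pi / 2), "20 px")
})

test_that("specs whose path or distractors collide with the frame are rejected", {
  expect_error(reducedSceneSpec(nFrames = 200L, center = c(48, 20),
                                growth = 0.5), "leaves the frame")
  expect_error(
    reducedSceneSpec(nFrames = 10L,
                     distractors = list(list(x = 40, y = 55, w = 10, h = 10,
                                             color = c(200, 0, 0)))),
    "distractor")
  ## a distractor clear of the path envelope is fine
  s <- reducedSceneSpec(nFrames = 10L,
                        distractors = list(list(x = 2, y = 2, w = 8, h = 8,
                                                color = c(200, 0, 0))))
  expect_s4_class(generateVideo(s), "SyntheticVideo")
})

test_that("appearance perturbation is local in time and seed-stable", {
  s <- reducedSceneSpec(nFrames = 20L, seed = 8L)
  v <- generateVideo(s)
  shifted <- perturbAppearance(v, list(frame = 10L, color = c(200, 40, 170)))
  ## frames before the shift are unchanged byte for byte
  for (i in 1:10) expect_identical(frames(shifted)[[i]], frames(v)[[i]])
  ## the blob region changes color after the shift
  ann <- annotations(v)[15L, ]
  patch <- function(vv) frames(vv)[[15L]][ann$y + (-2:2) + 1L,
                                           ann$x + (-2:2) + 1L, 2L]
  expect_gt(mean(patch(v)) - mean(patch(shifted)), 50)
  ## annotations never change
  expect_identical(annotations(shifted), annotations(v))
  ## identity shift reproduces the video exactly
  same <- perturbAppearance(v, list(frame = 10L, color = s$blobColor,
                                    radius = s$blobRadius))
  expect_identical(frames(same), frames(v))
  expect_error(perturbAppearance(v, list(frame = 99L, color = c(0, 0, 0))),
               "outside")
})

test_that("training sets pair every frame with its clipped mask", {
  specs <- lapply(1:2, function(s) reducedSceneSpec(nFrames = 5L, seed = s))
  ds <- generateTrainingSet(specs, boxSide = 9L)
  expect_length(ds, 10L)
  for (pair in ds) {
    expect_equal(dim(pair$frame)[1:2], dim(pair$mask))
    expect_lte(sum(pair$mask), 81)
    expect_gte(sum(pair$mask), 25)   # worst-case corner clipping
  }
  ## deterministic order
  ds2 <- generateTrainingSet(specs, boxSide = 9L)
  expect_identical(ds, ds2)
  expect_error(generateTrainingSet(list()), "no scene")
})
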