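test_that("makeMask produces a clipped box of ones centered on the annotation", {
  ## interior: full 33x33 box
  m <- makeMask(c(100, 100), c(480, 640))
  expect_equal(sum(m), 33 * 33)
  expect_equal(range(which(colSums(m) > 0)) - 1L, c(84L, 116L))  # x span
  expect_equal(range(which(rowSums(m) > 0)) - 1L, c(84L, 116L))  # y span

  ## corner: clipped to the 17x17 in-bounds part
  expect_equal(sum(makeMask(c(0, 0), c(480, 640))), 17 * 17)

  ## degenerate single-pixel box
  m1 <- makeMask(c(5, 5), c(10, 10), boxSide = 1L)
  expect_equal(sum(m1), 1)
  expect_equal(m1[6, 6], 1L)

  ## brute-force clipped count at an arbitrary border position
  cx <- 3; cy <- 470; r <- 16
  cnt <- sum(outer(0:479, 0:639, function(y, x)
    abs(x - cx) <= r & abs(y - cy) <= r))
  expect_equal(sum(makeMask(c(cx, cy), c(480, 640))), cnt)

  expect_error(makeMask(c(5, 5), c(10, 10), boxSide = 4L), "odd")
  expect_error(makeMask(c(700, 5), c(480, 640)), "outside")
})

test_that("pixel distances convert to mm through the video scale", {
  expect_equal(pxToMm(10, 0.276), 2.76)
  expect_equal(pxToMm(0, 0.276), 0)
  expect_equal(pxToMm(5, 0.2), 1.0)
  expect_error(pxToMm(5), "scale")
  expect_error(pxToMm(5, NA), "scale")
})

test_that("annotation CSV round-trips and malformed input is rejected", {
  ann <- data.frame(frame = c(0L, 2L, 5L), x = c(10L, 20L, 30L),
                    y = c(40L, 50L, 60L))
  path <- withr::local_tempfile(fileext = ".csv")
  writeAnnotations(ann, path)
  expect_equal(readAnnotations(path), ann)

  ## single row parses
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("frame,x,y\n0,100,200", p2)
  got <- readAnnotations(p2)
  expect_equal(got$x, 100L)
  expect_equal(got$y, 200L)

  ## rows come back sorted by frame
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,x,y", "5,1,1", "0,2,2"), p3)
  expect_equal(readAnnotations(p3)$frame, c(0L, 5L))

  ## duplicates, bad header, out-of-bounds, malformed row
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,x,y", "0,1,1", "0,2,2"), p4)
  expect_error(readAnnotations(p4), "duplicate")
  p5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,c", "0,1,1"), p5)
  expect_error(readAnnotations(p5), "header")
  p6 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,x,y", "0,700,10"), p6)
  expect_error(readAnnotations(p6, frameSize = c(480, 640)), "outside")
  p7 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,x,y", "0,5,"), p7)
  expect_error(readAnnotations(p7), "line 2")
})

test_that("frame directories load deterministically and bad input errors", {
  v <- generateVideo(reducedSceneSpec(nFrames = 6L, seed = 3L))
  dir <- withr::local_tempdir()
  writeSequence(v, dir)

  sq <- loadSequence(dir, targetSize = NA)
  expect_s4_class(sq, "FrameSequence")
  expect_equal(nFrames(sq), 6L)
  expect_equal(frameDim(sq), c(96L, 96L))
  ## deterministic: same path, identical pixels
  sq2 <- loadSequence(dir, targetSize = NA)
  expect_identical(frames(sq)[[3L]], frames(sq2)[[3L]])
  ## PNG quantizes to 8 bits; content matches the rendered frames to 1 level
  expect_lt(max(abs(frames(sq)[[1L]] - frames(v)[[1L]])), 1)

  ## frames of another size are resized to the working resolution, warning
  expect_warning(big <- loadSequence(dir), "resizing")
  expect_equal(frameDim(big), c(480L, 640L))

  empty <- withr::local_tempdir()
  expect_error(loadSequence(empty), "no readable image frames")
  expect_error(loadSequence(file.path(empty, "nope")), "no such file")
  mp4 <- withr::local_tempfile(fileext = ".mp4")
  file.create(mp4)
  expect_error(loadSequence(mp4), "video container")
})

test_that("manifests resolve paths and validate entries", {
  dir <- withr::local_tempdir()
  v <- generateVideo(reducedSceneSpec(nFrames = 2L, seed = 1L))
  writeSequence(v, file.path(dir, "vid"))
  writeAnnotations(annotations(v), file.path(dir, "gt.csv"))
  man <- file.path(dir, "data.yaml")
  writeLines(c("- video: vid", "  annotations: gt.csv", "  split: train",
               "  scale: 0.276"), man)
  df <- readManifest(man)
  expect_equal(nrow(df), 1L)
  expect_equal(df$split, "train")
  expect_equal(df$scale, 0.276)
  expect_true(dir.exists(df$video))

  writeLines(c("- video: vid", "  annotations: missing.csv",
               "  split: train"), man)
  expect_error(readManifest(man), "unreadable")
  writeLines(c("- video: vid", "  annotations: gt.csv",
               "  split: nope"), man)
  expect_error(readManifest(man), "invalid split")
})
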