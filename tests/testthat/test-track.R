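test_that("preprocessing is exact in its degenerate configurations", {
  cfg_id <- TrackerConfig(resizeFactor = 1, medianKernel = 1L)
  f <- matrix(runif(64 * 32, 0, 255), 64, 32)
  expect_identical(preprocessFrames(f, cfg_id), f)
  # constant frames are fixed points of the median filter
  cfg_med <- TrackerConfig(resizeFactor = 1, medianKernel = 3L)
  cst <- matrix(77.5, 40, 20)
  expect_identical(preprocessFrames(cst, cfg_med), cst)
  expect_error(preprocessFrames(matrix(numeric(0), 0, 0), cfg_id), "empty")
})

test_that("median filter matches the brute-force oracle", {
  set.seed(42)
  # impulse on constant background: removed by a 3x3 filter
  imp <- matrix(100, 15, 15); imp[8, 8] <- 255
  out <- preprocessFrames(imp, TrackerConfig(resizeFactor = 1,
                                             medianKernel = 3L))
  expect_equal(out[8, 8], 100)
  expect_equal(out, medianFilterOracle(imp, 3L))
  # random frames, kernels 3 and 5, including borders
  for (k in c(3L, 5L)) {
    m <- matrix(sample(0:255, 20 * 12, replace = TRUE), 20, 12)
    expect_equal(
      preprocessFrames(m, TrackerConfig(resizeFactor = 1, medianKernel = k)),
      medianFilterOracle(m, k))
  }
})

test_that("resizing halves dimensions and stays deterministic", {
  f <- matrix(runif(128 * 64, 0, 255), 128, 64)
  cfg <- TrackerConfig(resizeFactor = 0.5, medianKernel = 1L)
  a <- preprocessFrames(f, cfg)
  expect_equal(dim(a), c(64, 32))
  expect_identical(a, preprocessFrames(f, cfg))
})

test_that("color frames collapse to luminance before tracking", {
  nx <- 16; ny <- 8
  col <- array(0, dim = c(nx, ny, 3, 2))
  col[, , 1, ] <- 100; col[, , 2, ] <- 200; col[, , 3, ] <- 50
  g <- preprocessFrames(col, TrackerConfig(resizeFactor = 1,
                                           medianKernel = 1L))
  expect_equal(dim(g), c(nx, ny, 2))
  expect_true(all(abs(g - (0.299 * 100 + 0.587 * 200 + 0.114 * 50)) < 1e-9))
})

test_that("difference mask counts changed pixels exactly", {
  cfg <- TrackerConfig(resizeFactor = 1, medianKernel = 1L,
                       binarizeThreshold = 15, midlineX = 9L)
  a <- matrix(100, 16, 10)
  expect_s4_class(differenceMask(a, a, cfg), "MotionMask")
  m0 <- differenceMask(a, a, cfg)
  expect_equal(m0@nLeft + m0@nRight, 0L)
  # k pixels changed above threshold in the right half -> nRight = k exactly
  b <- a
  changed <- cbind(x = c(10, 12, 15, 9), y = c(2, 5, 9, 10))
  b[changed] <- 100 + 40
  mk <- differenceMask(a, b, cfg)
  expect_equal(mk@nRight, nrow(changed))
  expect_equal(mk@nLeft, 0L)
  # sub-threshold changes are not motion
  c_ <- a; c_[3, 3] <- 100 + 10
  expect_equal(differenceMask(a, c_, cfg)@nLeft, 0L)
  expect_error(differenceMask(a, matrix(0, 4, 4), cfg), "mismatch")
})

test_that("iteration classification follows majority with a motion gate", {
  cfg <- TrackerConfig(minMotionPixels = 1L)
  expect_equal(classifyCounts(10L, 2L, cfg), "left")
  expect_equal(classifyCounts(2L, 10L, cfg), "right")
  expect_equal(classifyCounts(0L, 0L, cfg), "unknown")
  expect_equal(classifyCounts(5L, 5L, cfg), "unknown")          # tie
  cfg5 <- TrackerConfig(minMotionPixels = 5L)
  expect_equal(classifyCounts(2L, 1L, cfg5), "unknown")         # below gate
  expect_equal(classifyCounts(c(3L, 0L), c(0L, 4L),
                              TrackerConfig(minMotionPixels = 0L)),
               c("left", "right"))
})

test_that("carry-forward resolves unknowns and backfills the lead-in", {
  r <- ThermoTrack:::.resolveSides(
    c("unknown", "unknown", "left", "unknown", "right", "unknown"))
  expect_equal(r, c("left", "left", "left", "left", "right", "right"))
  expect_error(ThermoTrack:::.resolveSides(rep("unknown", 4)),
               "no motion detected")
})

test_that("track session bookkeeping is exact", {
  tr <- sweepTrajectory(durationS = 10)
  fs <- renderFrames(tr, RenderConfig(noiseSd = 0, driftAmplitude = 0),
                     seed = 1)
  out <- trackSession(fs, TrackerConfig(), PlatePair(0, 5))
  rec <- records(out$occupancy)
  expect_equal(nrow(rec), 99L)                       # n - 1 iterations
  r <- out$result
  expect_equal(r@secondsLeft + r@secondsRight, 99 / 10)
  expect_identical(r@pctLeft + r@pctRight, 100)      # exact by construction
  # determinism: identical frames + config -> bit-identical series
  out2 <- trackSession(fs, TrackerConfig(), PlatePair(0, 5))
  expect_identical(records(out2$occupancy), rec)
  # warmer/colder orientation follows the pair
  outSwap <- trackSession(fs, TrackerConfig(), PlatePair(5, 0))
  expect_equal(pctColder(outSwap$result), r@pctWarmer)
})

test_that("noise-free tracking equals truth when the blob is clear of the midline", {
  arena <- ArenaGeometry()
  tr <- sweepTrajectory(durationS = 30, arena = arena)
  fs <- renderFrames(tr, RenderConfig(noiseSd = 0, driftAmplitude = 0),
                     seed = 1)
  cfg <- TrackerConfig(resizeFactor = 1, medianKernel = 1L,
                       minMotionPixels = 1L)
  out <- trackSession(fs, cfg, PlatePair(0, 5))
  rec <- records(out$occupancy)
  tt <- truth(fs)
  r <- 5  # blob radius
  clear <- abs(tt$x[-1] - arena@midlineX) > (r + 1) &
    abs(tt$x[-nrow(tt)] - arena@midlineX) > (r + 1)
  expect_equal(rec$resolvedSide[clear], tt$side[-1][clear])
})

test_that("a blob frozen after 10 s keeps its last side by carry-forward", {
  tr <- freezeTrajectory(durationS = 60, moveS = 10)
  fs <- renderFrames(tr, RenderConfig(), seed = 9)
  out <- trackSession(fs, TrackerConfig(), PlatePair(0, 5))
  rec <- records(out$occupancy)
  expect_true(all(rec$resolvedSide[150:nrow(rec)] == "left"))
  expect_gte(pctLeft(out$result), 96)
})

test_that("a static recording raises the no-motion error", {
  still <- Trajectory(x = rep(30, 20), y = rep(30, 20))
  fs <- renderFrames(still, RenderConfig(noiseSd = 0, driftAmplitude = 0),
                     seed = 1)
  expect_error(trackSession(fs, TrackerConfig(), PlatePair(0, 5)),
               "no motion detected")
})

test_that("raising the motion gate never reduces unknown iterations", {
  tr <- simulateTrajectory(PlatePair(0, 5), durationS = 20, seed = 6)
  fs <- renderFrames(tr, RenderConfig(), seed = 6)
  unknowns <- vapply(c(0L, 5L, 20L, 80L, 300L), function(mm) {
    cfg <- TrackerConfig(minMotionPixels = mm)
    tryCatch(
      sum(records(trackSession(fs, cfg,
                               PlatePair(0, 5))$occupancy)$rawSide ==
            "unknown"),
      error = function(e) nFrames(fs) - 1)   # gate so high nothing resolves
  }, numeric(1))
  expect_true(all(diff(unknowns) >= 0))
})

test_that("noise below half the threshold barely moves the occupancy", {
  tr <- simulateTrajectory(PlatePair(0, 5), durationS = 60, seed = 13)
  quiet <- renderFrames(tr, RenderConfig(noiseSd = 0), seed = 13)
  noisy <- renderFrames(tr, RenderConfig(noiseSd = 7), seed = 13)  # 15/2
  p0 <- pctColder(trackSession(quiet, TrackerConfig(),
                               PlatePair(0, 5))$result)
  p1 <- pctColder(trackSession(noisy, TrackerConfig(),
                               PlatePair(0, 5))$result)
  expect_lte(abs(p0 - p1), 1)
})

test_that("stride subsamples the differenced pairs", {
  tr <- sweepTrajectory(durationS = 5)
  fs <- renderFrames(tr, RenderConfig(noiseSd = 0, driftAmplitude = 0),
                     seed = 1)
  out <- trackSession(fs, TrackerConfig(stride = 2L), PlatePair(0, 5))
  expect_equal(nrow(records(out$occupancy)), nFrames(fs) - 2L)
})

test_that("frame sequences round-trip through numbered PNGs", {
  tr <- sweepTrajectory(durationS = 1.5)
  fs <- renderFrames(tr, RenderConfig(), seed = 4)
  d <- withr::local_tempdir()
  writeFrameSequence(fs, d)
  back <- readFrameSequence(d)
  expect_equal(frames(back), frames(fs))
  expect_equal(frameRate(back), frameRate(fs))
  expect_equal(truth(back)$side, truth(fs)$side)
  # a single frame is not a sequence
  one <- file.path(d, "frame_000001.png")
  expect_error(readFrameSequence(one, frameRate = 10), "at least 2")
  expect_error(readFrameSequence("no/such/file.png", frameRate = 10),
               "cannot read")
})
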