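# Frame-difference motion analysis: trace construction, maps, baseline
# removal, motion-period detection, summaries and synchrony.

test_that("frame-difference trace follows its defining arithmetic", {
  # hand computation: 1x1 video (10, 14, 9) -> trace (4, 5)
  fr <- array(c(10, 14, 9), dim = c(3, 1, 1))
  expect_equal(traceValues(frameDifferenceTrace(videoStack(fr, 25))),
               c(4, 5))

  # identical frames -> all-zero trace; length is always T - 1
  still <- videoStack(array(7, dim = c(100, 4, 4)), 25)
  tr <- frameDifferenceTrace(still)
  expect_length(traceValues(tr), 99L)
  expect_equal(traceValues(tr), rep(0, 99))

  # single-frame video is rejected
  expect_error(videoStack(array(1, dim = c(1, 4, 4)), 25), "2 frames")
})

test_that("trace is permutation-sensitive and linear in intensity scale", {
  sim <- simulateBeatingVideo(stdBeatSpec(duration = 4), seed = 5)
  v <- traceValues(frameDifferenceTrace(sim$video))

  set.seed(1)
  shuffled <- frames(sim$video)[sample(dim(frames(sim$video))[1]), , ]
  vs <- traceValues(frameDifferenceTrace(
    videoStack(shuffled, 25, bitScale = 255)))
  expect_false(isTRUE(all.equal(v, vs)))

  scaled <- videoStack(frames(sim$video) * 3, 25, bitScale = 255 * 3)
  expect_equal(traceValues(frameDifferenceTrace(scaled)), 3 * v,
               tolerance = 1e-12)
})

test_that("motion map localizes and conserves the trace integral", {
  # static video -> zero map
  still <- videoStack(array(7, dim = c(50, 6, 6)), 25)
  expect_equal(max(mapValues(motionMap(still, 2))), 0)

  # one flickering pixel -> nonzero only there
  fr <- array(10, dim = c(50, 6, 6))
  fr[seq(1, 50, 2), 3, 4] <- 30
  mm <- motionMap(videoStack(fr, 25), 2)
  expect_gt(mapValues(mm)[3, 4], 0)
  expect_equal(sum(mapValues(mm) > 0), 1L)

  # map summed over pixels = trace sum x pixel count over the same window
  sim <- simulateBeatingVideo(stdBeatSpec(duration = 6), seed = 6)
  win <- 4
  mm <- motionMap(sim$video, win)
  tr <- traceValues(frameDifferenceTrace(sim$video))
  nPairs <- floor(win * 25)
  expect_equal(sum(mapValues(mm)), sum(tr[seq_len(nPairs)]) * 48 * 48,
               tolerance = 1e-9)

  expect_error(motionMap(sim$video, -1), "window")
  expect_error(motionMap(sim$video, 1e4), "duration")
})

test_that("baseline correction zeroes quiescent levels and lines", {
  # already flat at zero: unchanged
  flat <- motionTrace(rep(0, 50), 25)
  expect_equal(traceValues(baselineCorrect(flat)), rep(0, 50))
  expect_true(isBaselineCorrected(baselineCorrect(flat)))

  # a pure linear ramp is removed entirely
  ramp <- motionTrace(seq(0, 5, length.out = 100), 25)
  expect_equal(max(abs(traceValues(baselineCorrect(ramp)))), 0,
               tolerance = 1e-9)

  # adding a tilt leaves detected event widths invariant
  sim <- simulateBeatingVideo(stdBeatSpec(duration = 20), seed = 7)
  tr <- frameDifferenceTrace(sim$video)
  ev0 <- detectMotionPeriods(baselineCorrect(tr), 0.1, mergeGap = 0.2)
  tilted <- motionTrace(traceValues(tr) +
                          seq(0, 2, length.out = length(traceValues(tr))),
                        25)
  evT <- detectMotionPeriods(baselineCorrect(tilted), 0.1, mergeGap = 0.2)
  expect_equal(evT$width, ev0$width)
})

test_that("motion periods are maximal supra-threshold runs", {
  mk <- function(v) motionTrace(v, 25, baselineRemoved = TRUE)

  expect_identical(nrow(detectMotionPeriods(mk(rep(0, 60)), 0.1)), 0L)

  # one run of 12 samples -> one event of width 12/25 = 0.48 s
  v <- rep(0, 60); v[20:31] <- 1
  ev <- detectMotionPeriods(mk(v), 0.1)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$width, 0.48)
  expect_identical(ev$startFrame, 20L)
  expect_identical(ev$endFrame, 32L)   # half-open
  expect_equal(ev$peakAmplitude, 1)

  # two runs separated by one sub-threshold sample stay two events...
  v2 <- rep(0, 60); v2[10:14] <- 1; v2[16:20] <- 2
  expect_identical(nrow(detectMotionPeriods(mk(v2), 0.1)), 2L)
  # ...unless a merge gap at least as long as the dip is allowed
  merged <- detectMotionPeriods(mk(v2), 0.1, mergeGap = 2 / 25)
  expect_identical(nrow(merged), 1L)
  expect_equal(merged$peakAmplitude, 2)

  expect_error(detectMotionPeriods(mk(v), -0.1), "threshold")
  raw <- motionTrace(v, 25)   # not baseline-corrected
  expect_error(detectMotionPeriods(raw, 0.1), "baseline")
})

test_that("contractility summaries average over the entire trace", {
  ev <- data.frame(startFrame = seq_len(38), endFrame = seq_len(38) + 10L,
                   peakAmplitude = rep(1, 38), width = rep(0.4, 38))
  s <- summarizeContractility(ev, 120)
  expect_equal(s$frequency, 19)          # 38 events in 2 min
  expect_identical(s$nEvents, 38L)

  one <- summarizeContractility(ev[1, ], 60)
  expect_equal(one$meanWidth, 0.4)
  expect_true(is.na(one$semWidth))       # SEM undefined for n = 1

  none <- summarizeContractility(ev[0, ], 60)
  expect_equal(none$frequency, 0)
  expect_true(is.na(none$meanAmplitude))

  expect_error(summarizeContractility(ev, -5), "traceDuration")
})

test_that("synchrony lags are antisymmetric and recover programmed delays", {
  cl <- rbind(
    beatCluster(14, 14, radius = 6),
    beatCluster(34, 34, radius = 6, phaseDelay = 0.2))
  sim <- simulateBeatingVideo(stdBeatSpec(duration = 40, clusters = cl),
                              seed = 8)
  roiA <- discRoi(48, 48, 14, 14, 6)
  roiB <- discRoi(48, 48, 34, 34, 6)
  lags <- clusterSynchrony(sim$video, list(A = roiA, B = roiB))
  expect_equal(lags["A", "B"], 0.2, tolerance = 0.045)
  expect_equal(lags["A", "B"], -lags["B", "A"])
  expect_equal(diag(lags), c(A = 0, B = 0))

  # identical signal in both ROIs -> zero lag (split one cluster in two)
  half1 <- discRoi(48, 48, 24, 24, 8) & col(matrix(0, 48, 48)) <= 24
  half2 <- discRoi(48, 48, 24, 24, 8) & col(matrix(0, 48, 48)) > 24
  sim1 <- simulateBeatingVideo(stdBeatSpec(duration = 20), seed = 9)
  lag0 <- clusterSynchrony(sim1$video, list(half1, half2))
  expect_equal(lag0[1, 2], 0, tolerance = 0.045)

  expect_error(clusterSynchrony(sim$video, list(roiA)), "two ROIs")
  expect_error(
    clusterSynchrony(sim$video, list(roiA, matrix(FALSE, 48, 48))),
    "empty")
  expect_error(clusterSynchrony(sim$video, list(roiA, roiA)), "disjoint")
})
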