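# Hertz fitting: forward model, contact-point estimation, inverse fit,
# quality filtering and group aggregation.

test_that("hertzForce matches the closed form and its monotonicities", {
  pr <- probeSpec(2.385e-6, 0.5)
  expect_equal(hertzForce(1000, pr, 0), 0)
  expect_equal(hertzForce(1000, pr, 5e-7), 9.706813e-10, tolerance = 1e-6)
  # linear in E, monotone in delta
  expect_equal(hertzForce(2000, pr, 3e-7), 2 * hertzForce(1000, pr, 3e-7))
  d <- seq(0, 5e-7, length.out = 20)
  expect_true(all(diff(hertzForce(800, pr, d)) > 0))
  expect_error(hertzForce(1000, pr, -1e-9), "depth")
  expect_error(probeSpec(poisson = 0.7), "poisson")
})

test_that("contact-point estimation finds the true onset and ignores offsets", {
  sp <- curveSpec(eTrue = 1000, contactPoint = 1e-6, noiseSd = 0)
  fc <- simulateForceCurve(sp)
  spacing <- diff(curvePosition(fc))[1]
  expect_lt(abs(estimateContactPoint(fc) - 1e-6), 2 * spacing)

  # constant force offset leaves the estimate unchanged
  fcOff <- forceCurve(curvePosition(fc), curveForce(fc) + 2e-10,
                      metadata = curveMetadata(fc))
  expect_equal(estimateContactPoint(fcOff), estimateContactPoint(fc))

  # linear baseline tilt is detrended away
  fcTilt <- simulateForceCurve(curveSpec(baselineSlope = 5e-5, noiseSd = 0))
  expect_lt(abs(estimateContactPoint(fcTilt) - 1e-6), 2 * spacing)

  # pure-noise curve without contact errors out
  set.seed(3)
  noise <- forceCurve(seq(0, 2e-6, length.out = 100),
                      rnorm(100, sd = 5e-12))
  expect_error(estimateContactPoint(noise), "not detectable")
})

test_that("Hertz fit recovers noiseless truth and flags baseline-only curves", {
  pr <- probeSpec()
  for (E in c(500, 2000)) {
    fc <- simulateForceCurve(curveSpec(eTrue = E, noiseSd = 0))
    ft <- fitHertz(fc, pr)
    expect_lt(abs(youngsModulus(ft) - E) / E, 1e-3)
    expect_lt(abs(contactPoint(ft) - 1e-6), 5e-9)
    expect_equal(rejectReason(ft), "none")
  }

  # noiseless fit with offset + tilt-free baseline beats a brute-force grid
  fc <- simulateForceCurve(curveSpec(eTrue = 1200, noiseSd = 0))
  ft <- fitHertz(fc, pr)
  grid <- expand.grid(E = seq(800, 1600, by = 10),
                      cp = seq(0.9e-6, 1.1e-6, by = 2e-9))
  rss <- mapply(function(E, cp) {
    sum((curveForce(fc) -
           hertzForce(E, pr, pmax(curvePosition(fc) - cp, 0)))^2)
  }, grid$E, grid$cp)
  best <- grid[which.min(rss), ]
  expect_lt(abs(youngsModulus(ft) - best$E), 10)       # grid resolution in E
  expect_lt(abs(contactPoint(ft) - best$cp), 2e-9)     # grid resolution in cp

  flat <- forceCurve(seq(0, 2e-6, length.out = 100), rep(0, 100))
  ftFlat <- fitHertz(flat, pr)
  expect_true(is.na(youngsModulus(ftFlat)))
  expect_false(isAccepted(ftFlat))
  expect_equal(rejectReason(ftFlat), "unfit")
})

test_that("fitted E scales with force (with the rms threshold rescaled)", {
  fc <- simulateForceCurve(curveSpec(eTrue = 1000, noiseSd = 5e-12,
                                     seed = 21L))
  pr <- probeSpec()
  ft1 <- fitHertz(fc, pr)
  fc3 <- forceCurve(curvePosition(fc), 3 * curveForce(fc))
  ft3 <- fitHertz(fc3, pr)
  expect_equal(youngsModulus(ft3), 3 * youngsModulus(ft1),
               tolerance = 1e-6)
  expect_equal(rmsResidual(ft3), 3 * rmsResidual(ft1), tolerance = 1e-6)
  q1 <- qcFilter(list(ft1), rmsMax = 25e-12)
  q3 <- qcFilter(list(ft3), rmsMax = 3 * 25e-12)
  expect_identical(q1$tally, q3$tally)
})

test_that("parameter recovery improves with decreasing noise", {
  pr <- probeSpec()
  rmse <- vapply(c(10e-12, 5e-12, 1e-12), function(ns) {
    errs <- vapply(1:40, function(i) {
      fc <- simulateForceCurve(curveSpec(eTrue = 1000, noiseSd = ns,
                                         seed = 1000L + i))
      youngsModulus(fitHertz(fc, pr)) - 1000
    }, numeric(1))
    expect_lt(abs(mean(errs)) / 1000, 0.02)   # bias < 2 %
    sqrt(mean(errs^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("QC applies strict thresholds in order with a complete tally", {
  mk <- function(E, rms, dev) hertzFit(E, 1e-6, 0, rms, dev)
  fits <- list(
    good   = mk(1500, 10e-12, 50e-9),
    atRms  = mk(1500, 25e-12, 50e-9),    # boundary: not strictly below
    overR  = mk(1500, 30e-12, 50e-9),
    atDev  = mk(1500, 10e-12, 100e-9),   # boundary
    overD  = mk(1500, 10e-12, 150e-9),
    lowE   = mk(100, 10e-12, 50e-9),     # boundary of the open E range
    highE  = mk(5e4, 10e-12, 50e-9),
    multi  = mk(5e4, 30e-12, 150e-9))    # fails everything: tagged rms first
  q <- qcFilter(fits)
  expect_identical(unname(q$tally),
                   c(1L, 3L, 2L, 2L, 0L))
  expect_identical(sum(q$tally), length(fits))
  expect_equal(rejectReason(q$rejected[[which(
    vapply(q$rejected, youngsModulus, numeric(1)) == 5e4 &
    vapply(q$rejected, rmsResidual, numeric(1)) == 30e-12)]]), "rms")
  expect_true(isAccepted(q$accepted[[1]]))
  expect_error(qcFilter(list()), "at least one")
})

test_that("loosening any QC threshold never shrinks the accepted set", {
  set.seed(12)
  fits <- lapply(1:60, function(i)
    hertzFit(exp(runif(1, log(50), log(5e4))),
             1e-6, 0, runif(1, 0, 50e-12), runif(1, 0, 200e-9)))
  base <- qcFilter(fits)$tally[["accepted"]]
  for (f in list(
    function() qcFilter(fits, rmsMax = 40e-12)$tally[["accepted"]],
    function() qcFilter(fits, cpDevMax = 300e-9)$tally[["accepted"]],
    function() qcFilter(fits, eRange = c(10, 1e5))$tally[["accepted"]]))
    expect_gte(f(), base)
})

test_that("group aggregation reports means, SEM and empty groups", {
  set.seed(4)
  mkFit <- function(E, ct) hertzFit(E, metadata = list(cellType = ct))
  fits <- c(lapply(rnorm(20, 1200, 100), mkFit, ct = "iCM"),
            lapply(rnorm(20, 1400, 100), mkFit, ct = "CPC"))
  agg <- aggregateElasticity(fits, expected = c("CPC", "iCM", "mCM"))
  expect_setequal(agg$label, c("CPC", "iCM", "mCM"))
  icm <- agg[agg$label == "iCM", ]
  expect_equal(icm$meanE,
               mean(vapply(fits[1:20], youngsModulus, numeric(1))))
  expect_equal(icm$semE,
               sd(vapply(fits[1:20], youngsModulus, numeric(1))) / sqrt(20))
  expect_identical(agg$n[agg$label == "mCM"], 0L)

  single <- aggregateElasticity(list(mkFit(1000, "mCM")))
  expect_true(is.na(single$semE))      # SEM undefined for n = 1

  # balanced pooling: two equal-n groups pool to (a + b) / 2
  a <- agg[agg$label == "CPC", ]; b <- agg[agg$label == "iCM", ]
  pooled <- aggregateElasticity(fits, grouping = character(0))
  expect_equal(nrow(pooled), 1L)
  expect_equal(pooled$meanE, (a$meanE + b$meanE) / 2)

  expect_error(aggregateElasticity(fits, grouping = "nonexistent"),
               "unknown group key")
})

test_that("method differences reproduce simple mean arithmetic", {
  expect_equal(methodDifference(groupSummary("x", 1000),
                                groupSummary("x", 1000)), 0)
  expect_equal(methodDifference(groupSummary("iCM", 1030),
                                groupSummary("iCM", 950)), 80)
  expect_error(methodDifference(groupSummary("iCM", 1030),
                                groupSummary("mCM", 950)), "labels differ")
})
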