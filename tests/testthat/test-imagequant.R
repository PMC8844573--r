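# Thresholding, segmentation, intensity quantification, ratiometrics, band
# spacing and densitometry normalization.

test_that("Li threshold separates classes and transforms predictably", {
  twoVal <- c(rep(10, 90), rep(200, 10))
  t2 <- liThreshold(twoVal)
  expect_gt(t2, 10); expect_lt(t2, 200)

  bi <- bimodalImage()
  tl <- liThreshold(bi$image)
  expect_gte(mean((bi$image > tl) == bi$mask), 0.99)

  # positive-scale equivariance; offset invariance up to the internal shift
  expect_equal(liThreshold(bi$image * 2.5), 2.5 * tl, tolerance = 1e-6)
  expect_equal(liThreshold(bi$image + 40) - 40, tl, tolerance = 1e-3)

  expect_error(liThreshold(matrix(5, 4, 4)), "constant")
})

test_that("Huang threshold recovers bimodal truth and agrees with Li", {
  bi <- bimodalImage()
  th <- huangThreshold(bi$image)
  expect_gte(mean((bi$image > th) == bi$mask), 0.99)

  tl <- liThreshold(bi$image)
  agree <- mean((bi$image > th) == (bi$image > tl))
  expect_gte(agree, 0.98)

  # scale equivariance within histogram quantization
  expect_equal(huangThreshold(bi$image * 2), 2 * th,
               tolerance = 0.01 * diff(range(bi$image)))

  expect_error(huangThreshold(matrix(1, 3, 3)), "constant")
})

test_that("patch segmentation uses 8-connectivity and physical areas", {
  img <- matrix(5, 20, 20)
  mask <- matrix(FALSE, 20, 20)
  mask[3:7, 3:7] <- TRUE          # 25 px
  mask[12:16, 12:16] <- TRUE      # 25 px, disjoint
  img[3:7, 3:7] <- 50; img[12:16, 12:16] <- 80
  p <- segmentPatches(img, mask, pixelSize = 0.5)
  expect_identical(nrow(p), 2L)
  expect_equal(p$nPixels, c(25L, 25L))
  expect_equal(p$area, c(6.25, 6.25))   # 25 px * 0.25 um^2
  expect_setequal(p$meanIntensity, c(50, 80))

  # diagonal-touching pixels are one patch under 8-connectivity
  dm <- matrix(FALSE, 5, 5); dm[1, 1] <- TRUE; dm[2, 2] <- TRUE
  expect_identical(nrow(segmentPatches(matrix(1, 5, 5), dm)), 1L)
  expect_identical(nrow(segmentPatches(matrix(1, 5, 5), dm,
                                       connectivity = 4L)), 2L)

  expect_identical(nrow(segmentPatches(img, matrix(FALSE, 20, 20))), 0L)
  expect_error(segmentPatches(img, matrix(TRUE, 4, 4)), "shapes differ")
})

test_that("area-weighted intensity matches formula and pixel oracle", {
  expect_equal(weightedMeanIntensity(
    data.frame(area = c(1, 3), meanIntensity = c(4, 8))), 7)
  one <- data.frame(area = 2, meanIntensity = 9.5)
  expect_equal(weightedMeanIntensity(one), 9.5)

  # equals the plain mean over the union of patch pixels
  set.seed(10)
  img <- matrix(runif(40 * 40, 0, 100), 40, 40)
  mask <- matrix(runif(40 * 40) < 0.3, 40, 40)
  p <- segmentPatches(img, mask)
  if (nrow(p) > 0)
    expect_equal(weightedMeanIntensity(p), mean(img[mask]),
                 tolerance = 1e-12)

  expect_error(weightedMeanIntensity(one[0, ]), "no patches")
})

test_that("mitochondrial networks partition at the 100 um^2 boundary", {
  p <- data.frame(area = c(99.9, 100, 100.1, 350), meanIntensity = 1)
  cls <- classifyMitoNetworks(p)
  expect_equal(as.character(cls$sizeClass),
               c("small", "small", "large", "large"))
  # partition: every patch in exactly one class
  expect_identical(sum(table(cls$sizeClass)), nrow(p))
  expect_identical(nrow(classifyMitoNetworks(p[0, ])), 0L)
  expect_error(classifyMitoNetworks(data.frame(area = -1)), "areas")
})

test_that("JC-1 ratio is the masked pixelwise quotient", {
  a <- matrix(50, 10, 10)
  r1 <- jc1Ratio(a, a, floor = 10)
  expect_equal(meanRatio(r1), 1)

  sp <- imageSpec(shape = c(48L, 48L),
                  objects = imageObject(24, 24, 20, 20), noiseSd = 0)
  rp <- simulateRatioPair(sp, 2.5)
  ri <- jc1Ratio(rp$aggregate, rp$monomer, floor = 50)
  expect_equal(meanRatio(ri), 2.5)
  expect_identical(validMask(ri), rp$labels > 0L)
  expect_true(all(is.na(ratioMap(ri)[!validMask(ri)])))

  # monomer never above floor: undefined-marked mean
  dark <- jc1Ratio(a, matrix(1, 10, 10), floor = 10)
  expect_true(is.na(meanRatio(dark)))

  expect_error(jc1Ratio(a, matrix(1, 5, 5)), "shapes differ")
})

test_that("nuclear means average over instances, not pixels", {
  sig <- matrix(0, 20, 20)
  mask <- matrix(FALSE, 20, 20)
  mask[2:4, 2:4] <- TRUE;  sig[2:4, 2:4] <- 5      # 9 px nucleus
  mask[10:16, 10:16] <- TRUE; sig[10:16, 10:16] <- 15  # 49 px nucleus
  nm <- nuclearMeanIntensity(mask, sig)
  expect_equal(sort(nm$perNucleus$mean), c(5, 15))
  expect_equal(nm$mean, 10)    # instance average, not (9*5+49*15)/58

  uni <- nuclearMeanIntensity(mask, matrix(7, 20, 20))
  expect_equal(uni$mean, 7)

  expect_error(nuclearMeanIntensity(matrix(FALSE, 20, 20), sig), "no nuclei")
})

test_that("band spacing recovers the generating period in physical units", {
  img <- simulateStriationImage(1.65, 0.1, c(64L, 256L))
  bs <- bandSpacing(img, 0.1)
  expect_equal(bs$spacing, 1.65, tolerance = 0.1 / 1.65)  # one pixel equiv
  expect_gte(bs$nPeaks, 3L)

  # rotating the image 90 degrees leaves the spacing unchanged
  bs90 <- bandSpacing(t(img), 0.1)
  expect_equal(bs90$spacing, bs$spacing, tolerance = 1e-9)

  # doubling the pixel size doubles the reported spacing
  bs2 <- bandSpacing(img, 0.2)
  expect_equal(bs2$spacing, 2 * bs$spacing)

  # fewer than 3 bands -> error
  few <- simulateStriationImage(30, 1, c(16L, 40L))
  expect_error(bandSpacing(few, 1), "fewer than 3")
})

test_that("despeckle removes isolated outliers; 8-bit conversion is min-max", {
  img <- matrix(10, 15, 15)
  img[8, 8] <- 500
  sm <- despeckle(img)
  expect_equal(sm[8, 8], 10)
  expect_equal(dim(sm), dim(img))

  e8 <- to8bit(matrix(c(2, 4, 6, 10), 2, 2))
  expect_equal(range(e8), c(0, 255))
  expect_true(all(e8 == round(e8)))
})

test_that("densitometry normalization anchors the reference group at 1", {
  tab <- data.frame(
    sample = rep(c("CPC", "iCM", "mCM"), each = 2),
    protein = "cTnT",
    bandIntensity = c(2, 2, 4, 4, 8, 8),
    laneTotal = rep(2, 6))
  out <- densitometryNormalize(tab, "CPC")
  expect_equal(mean(out$normalizedExpression[out$sample == "CPC"]), 1)
  expect_equal(out$normalizedExpression,
               c(1, 1, 2, 2, 4, 4))
  expect_true(all(out$referenceUsed == "CPC"))

  # bands (2, 4) with equal lane totals, reference = first sample -> (1, 2)
  simple <- densitometryNormalize(
    data.frame(sample = c("a", "b"), protein = "p",
               bandIntensity = c(2, 4), laneTotal = c(1, 1)), "a")
  expect_equal(simple$normalizedExpression, c(1, 2))

  # undetectable reference falls back and records it
  tab2 <- tab
  tab2$bandIntensity[tab2$sample == "CPC"] <- 0
  out2 <- densitometryNormalize(tab2, "CPC", fallbackReference = "mCM")
  expect_true(all(out2$referenceUsed == "mCM"))
  expect_equal(mean(out2$normalizedExpression[out2$sample == "mCM"]), 1)
  expect_error(densitometryNormalize(tab2, "CPC"), "no fallback")

  bad <- tab; bad$laneTotal[1] <- 0
  expect_error(densitometryNormalize(bad, "CPC"), "lane totals")
})
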