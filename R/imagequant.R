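# Fluorescence and densitometry quantification: automatic thresholding,
# patch segmentation, area-weighted intensities, mitochondrial-network size
# classes, JC-1 ratio maps, nuclear masking, sarcomere band spacing and
# Ponceau-normalized blot tables.

#' Minimum cross-entropy (Li) threshold
#'
#' Iterative scheme of Li & Lee: starting from the image mean, the threshold
#' is repeatedly updated to (mu0 - mu1) / (log mu0 - log mu1), where mu0 and
#' mu1 are the means of the pixels at or below and above the current
#' threshold, until it converges to the minimizer of the cross entropy
#' between the image and its binarization. Deterministic; equivariant to
#' positive scaling and (up to the internal offset used to keep logarithms
#' finite) to adding a constant.
#'
#' @param image numeric matrix or vector with at least 2 distinct values.
#' @param maxIter iteration cap.
#' @return threshold (foreground = pixels strictly above it).
#' @export
#' @examples
#' img <- c(rep(10, 90), rep(200, 10))
#' liThreshold(img)  # strictly between 10 and 200
liThreshold <- function(image, maxIter = 200L) {
  x <- as.numeric(image)
  x <- x[is.finite(x)]
  rng <- range(x)
  stopIfNot(rng[2] > rng[1],
            "constant image: threshold undefined (needs >= 2 distinct values)")
  # offset so both class means stay positive for the logarithms
  tiny <- (rng[2] - rng[1]) * 1e-6
  xs <- x - rng[1] + tiny
  tol <- (rng[2] - rng[1]) * 1e-9
  t0 <- mean(xs)
  for (i in seq_len(maxIter)) {
    m0 <- mean(xs[xs <= t0]); m1 <- mean(xs[xs > t0])
    if (!is.finite(m1)) break   # everything below threshold
    t1 <- (m0 - m1) / (log(m0) - log(m1))
    if (abs(t1 - t0) < tol) { t0 <- t1; break }
    t0 <- t1
  }
  t0 + rng[1] - tiny
}

#' Huang fuzzy threshold
#'
#' Minimizes Huang's measure of fuzziness over a 256-bin histogram: for each
#' candidate threshold, pixel memberships to their class are
#' 1 / (1 + |g - mu_class| / C) with C the intensity range, and the Shannon
#' entropy of those memberships is accumulated over the histogram; the
#' threshold with minimal fuzziness is returned. Deterministic.
#'
#' @param image numeric matrix or vector with at least 2 distinct values.
#' @param nBins histogram resolution (default 256, the 8-bit convention).
#' @return threshold (foreground = pixels strictly above it).
#' @export
huangThreshold <- function(image, nBins = 256L) {
  x <- as.numeric(image)
  x <- x[is.finite(x)]
  rng <- range(x)
  stopIfNot(rng[2] > rng[1],
            "constant image: threshold undefined (needs >= 2 distinct values)")
  brk <- seq(rng[1], rng[2], length.out = nBins + 1L)
  h <- tabulate(pmin(findInterval(x, brk, rightmost.closed = TRUE), nBins),
                nbins = nBins)
  g <- (brk[-1] + brk[-(nBins + 1L)]) / 2    # bin centers
  C <- rng[2] - rng[1]
  W <- cumsum(h); S <- cumsum(h * g)
  n <- W[nBins]; stot <- S[nBins]
  fuzz <- function(u) {
    e <- numeric(length(u))
    inr <- u > 0 & u < 1
    e[inr] <- -u[inr] * log(u[inr]) - (1 - u[inr]) * log(1 - u[inr])
    e
  }
  best <- Inf; bestT <- NA_real_
  for (t in seq_len(nBins - 1L)) {
    if (W[t] == 0L || W[t] == n) next
    mu0 <- S[t] / W[t]
    mu1 <- (stot - S[t]) / (n - W[t])
    u <- numeric(nBins)
    lo <- seq_len(t); hi <- (t + 1L):nBins
    u[lo] <- 1 / (1 + abs(g[lo] - mu0) / C)
    u[hi] <- 1 / (1 + abs(g[hi] - mu1) / C)
    sEnt <- sum(h * fuzz(u))
    if (sEnt < best) { best <- sEnt; bestT <- brk[t + 1L] }
  }
  bestT
}

#' 3 x 3 median despeckle filter
#'
#' The standard despeckle operation: every pixel is replaced by the median of
#' its 3 x 3 neighborhood, with edge pixels replicated at the border. Removes
#' isolated hot/cold pixels without blurring band structure the way a mean
#' filter would.
#'
#' @param image numeric matrix.
#' @return filtered matrix of the same shape.
#' @export
despeckle <- function(image) {
  stopifnot(is.matrix(image))
  H <- nrow(image); W <- ncol(image)
  pad <- image[c(1, seq_len(H), H), c(1, seq_len(W), W)]
  neigh <- vapply(
    list(c(0, 0), c(0, 1), c(0, 2), c(1, 0), c(1, 1), c(1, 2),
         c(2, 0), c(2, 1), c(2, 2)),
    function(o) as.vector(pad[o[1] + seq_len(H), o[2] + seq_len(W)]),
    numeric(H * W))
  matrix(apply(neigh, 1L, stats::median), H, W)
}

#' Convert an image to the 8-bit scale
#'
#' Min-max scales intensities to [0, 255] and rounds to integers, the usual
#' preprocessing convention before histogram-based thresholding. Note that
#' rounding quantizes intensities, so run it only when the downstream
#' threshold is meant to live on the 8-bit scale.
#'
#' @param image numeric matrix.
#' @return integer-valued matrix in [0, 255].
#' @export
to8bit <- function(image) {
  rng <- range(image)
  if (rng[2] == rng[1]) return(matrix(0, nrow(image), ncol(image)))
  round((image - rng[1]) / (rng[2] - rng[1]) * 255)
}

#' Label connected components of a binary mask
#'
#' Two-pass union-find labeling with 8-connectivity by default (diagonal
#' neighbors connect), matching the behavior assumed throughout the patch
#' and nucleus quantification.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of component labels (0 = background), numbered
#'   consecutively from 1 in scan order.
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  stopIfNot(connectivity %in% c(4L, 8L), "connectivity must be 4 or 8")
  H <- nrow(mask); W <- ncol(mask)
  if (!any(mask)) return(matrix(0L, H, W))
  # provisional labels: one per vertical run of TRUE pixels
  up <- rbind(FALSE, mask[-H, , drop = FALSE])
  starts <- mask & !up
  lab <- matrix(0L, H, W)
  lab[mask] <- cumsum(starts)[mask]
  nRun <- max(lab)
  parent <- seq_len(nRun)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- findRoot(a); rb <- findRoot(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  offsets <- if (connectivity == 8L)
    list(c(0L, 1L), c(1L, 1L), c(-1L, 1L)) else list(c(0L, 1L))
  for (o in offsets) {
    rA <- seq_len(H); cA <- seq_len(W - 1L)
    rB <- rA + o[1]
    keep <- rB >= 1L & rB <= H
    a <- lab[rA[keep], cA, drop = FALSE]
    b <- lab[rB[keep], cA + 1L, drop = FALSE]
    both <- which(a > 0L & b > 0L)
    for (i in both) unite(a[i], b[i])
  }
  roots <- vapply(seq_len(nRun), findRoot, integer(1))
  dense <- match(roots, sort(unique(roots)))
  out <- matrix(0L, H, W)
  out[mask] <- dense[lab[mask]]
  out
}

#' Segment cellular patches from a binary mask
#'
#' Connected components (8-connectivity) of the mask become patches, each
#' with its pixel count, physical area and mean intensity taken from the
#' underlying image.
#'
#' @param image numeric matrix of intensities.
#' @param mask logical matrix, same shape.
#' @param pixelSize µm per pixel (default 1).
#' @param connectivity 8 (default) or 4.
#' @return data.frame with columns \code{id}, \code{nPixels}, \code{area}
#'   (µm²) and \code{meanIntensity}; the label matrix is attached as
#'   \code{attr(, "labels")}.
#' @export
segmentPatches <- function(image, mask, pixelSize = 1, connectivity = 8L) {
  stopifnot(is.matrix(image))
  stopIfNot(identical(dim(image), dim(mask)),
            "image and mask shapes differ")
  stopIfNot(pixelSize > 0, "pixelSize must be > 0")
  lab <- labelComponents(mask, connectivity)
  k <- max(lab)
  if (k == 0L) {
    out <- data.frame(id = integer(0), nPixels = integer(0),
                      area = numeric(0), meanIntensity = numeric(0))
    attr(out, "labels") <- lab
    return(out)
  }
  px <- tabulate(lab[lab > 0L], nbins = k)
  sums <- vapply(seq_len(k), function(i) sum(image[lab == i]), numeric(1))
  out <- data.frame(id = seq_len(k), nPixels = px,
                    area = px * pixelSize^2, meanIntensity = sums / px)
  attr(out, "labels") <- lab
  out
}

#' Area-weighted mean fluorescence intensity
#'
#' F = sum(A_i * Fbar_i) / sum(A_i) over the patches of an image: each
#' patch's mean intensity weighted by its area. When the patch means are
#' pixel means this equals the plain mean over the union of all patch
#' pixels.
#'
#' @param patches data.frame from [segmentPatches()] (needs columns
#'   \code{area} and \code{meanIntensity}).
#' @return weighted mean intensity.
#' @export
#' @examples
#' weightedMeanIntensity(data.frame(area = c(1, 3), meanIntensity = c(4, 8)))
weightedMeanIntensity <- function(patches) {
  stopIfNot(nrow(patches) >= 1L, "no patches: weighted mean undefined")
  stopIfNot(sum(patches$area) > 0, "total patch area must be > 0")
  sum(patches$area * patches$meanIntensity) / sum(patches$area)
}

#' Classify mitochondrial networks by size
#'
#' Splits patches at the 100 µm² boundary: networks of up to 100 µm²
#' (inclusive) are "small", larger ones "large". Every patch lands in
#' exactly one class.
#'
#' @param patches data.frame with columns \code{area} (µm²) and
#'   \code{meanIntensity}.
#' @param boundary size boundary, µm² (default 100).
#' @return the input with an added factor column \code{sizeClass}
#'   (levels small, large).
#' @export
classifyMitoNetworks <- function(patches, boundary = 100) {
  stopIfNot(all(patches$area >= 0), "areas must be >= 0")
  patches$sizeClass <- factor(
    ifelse(patches$area <= boundary, "small", "large"),
    levels = c("small", "large"))
  patches
}

#' Pixelwise JC-1 aggregate/monomer ratio
#'
#' Divides the aggregate channel by the monomer channel pixel by pixel,
#' restricted to pixels where the monomer signal exceeds \code{floor} (by
#' default the monomer channel's Li threshold, which keeps near-zero
#' denominators out). The summary is the mean ratio over the valid mask,
#' NA when no pixel qualifies.
#'
#' @param aggregateImg,monomerImg numeric matrices of equal shape.
#' @param floor monomer validity floor (default: Li threshold of the monomer
#'   channel).
#' @return a \linkS4class{RatioImage}.
#' @export
jc1Ratio <- function(aggregateImg, monomerImg, floor = NULL) {
  stopifnot(is.matrix(aggregateImg), is.matrix(monomerImg))
  stopIfNot(identical(dim(aggregateImg), dim(monomerImg)),
            "channel shapes differ")
  if (is.null(floor)) floor <- liThreshold(monomerImg)
  stopIfNot(floor >= 0, "floor must be >= 0")
  valid <- monomerImg > floor
  ratio <- matrix(NA_real_, nrow(monomerImg), ncol(monomerImg))
  ratio[valid] <- aggregateImg[valid] / monomerImg[valid]
  mr <- if (any(valid)) mean(ratio[valid]) else NA_real_
  new("RatioImage", ratioMap = ratio, validMask = valid, meanRatio = mr)
}

#' Per-nucleus mean signal intensity
#'
#' Uses a nuclear mask (e.g. from a DNA stain) to segment a signal channel
#' (e.g. a nuclear transcription factor): each connected nucleus contributes
#' the mean signal over its pixels, and the reported value is the average
#' over nucleus instances - not the pixel-population average, so large and
#' small nuclei weigh equally.
#'
#' @param nucleiMask logical matrix.
#' @param signalImg numeric matrix, same shape.
#' @param connectivity 8 (default) or 4.
#' @return list with \code{perNucleus} (data.frame id, nPixels, mean) and
#'   \code{mean}, the average over nuclei.
#' @export
nuclearMeanIntensity <- function(nucleiMask, signalImg, connectivity = 8L) {
  stopIfNot(identical(dim(nucleiMask), dim(signalImg)),
            "mask and image shapes differ")
  per <- segmentPatches(signalImg, nucleiMask, pixelSize = 1,
                        connectivity = connectivity)
  stopIfNot(nrow(per) >= 1L, "no nuclei in mask")
  list(perNucleus = data.frame(id = per$id, nPixels = per$nPixels,
                               mean = per$meanIntensity),
       mean = mean(per$meanIntensity))
}

#' Sarcomere band spacing
#'
#' Estimates the dominant band orientation from image-gradient statistics
#' (the structure tensor), projects pixel intensities onto the band normal,
#' bins them into a 1 px intensity profile, and reports the mean
#' peak-to-peak distance in physical units. At least 3 profile peaks are
#' required.
#'
#' @param image numeric matrix with a striated pattern.
#' @param pixelSize µm per pixel.
#' @return list with \code{spacing} (µm), \code{sem} (µm, over the
#'   peak-to-peak distances), \code{nPeaks} and \code{orientation}
#'   (degrees of the band normal).
#' @export
#' @examples
#' img <- simulateStriationImage(1.65, 0.1, c(64L, 256L))
#' bandSpacing(img, 0.1)$spacing  # ~1.65
bandSpacing <- function(image, pixelSize) {
  stopifnot(is.matrix(image))
  stopIfNot(pixelSize > 0, "pixelSize must be > 0")
  H <- nrow(image); W <- ncol(image)
  stopIfNot(H >= 3L && W >= 3L, "image too small for gradient estimation")
  gx <- (image[, c(2:W, W)] - image[, c(1, 1:(W - 1))]) / 2   # along columns
  gy <- (image[c(2:H, H), ] - image[c(1, 1:(H - 1)), ]) / 2   # along rows
  jxx <- mean(gx^2); jyy <- mean(gy^2); jxy <- mean(gx * gy)
  theta <- 0.5 * atan2(2 * jxy, jxx - jyy)   # band-normal direction
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  u <- cc * cos(theta) + rr * sin(theta)
  bin <- round(u - min(u)) + 1L
  counts <- tabulate(bin)
  sums <- numeric(length(counts))
  agg <- tapply(as.vector(image), bin, sum)
  sums[as.integer(names(agg))] <- as.vector(agg)
  keep <- counts >= stats::median(counts[counts > 0]) / 2
  profile <- ifelse(counts > 0, sums / counts, NA_real_)
  profile[!keep] <- NA_real_
  ok <- which(!is.na(profile))
  prof <- profile[ok]
  np <- length(prof)
  stopIfNot(np >= 5L, "profile too short for peak detection")
  level <- mean(prof)
  isPeak <- c(FALSE, prof[2:(np - 1)] > prof[1:(np - 2)] &
                     prof[2:(np - 1)] >= prof[3:np], FALSE) & prof > level
  peaks <- ok[isPeak]
  stopIfNot(length(peaks) >= 3L,
            "fewer than 3 detectable bands along the dominant orientation")
  gaps <- diff(peaks)
  list(spacing = mean(gaps) * pixelSize,
       sem = if (length(gaps) >= 2L) semOf(gaps) * pixelSize else NA_real_,
       nPeaks = length(peaks),
       orientation = theta * 180 / pi)
}

#' Ponceau-normalize a densitometry table
#'
#' Corrects each band intensity for the lane's total protein
#' (\code{bandIntensity / laneTotal}) and scales per protein to the mean
#' load-corrected expression of the reference group, whose normalized mean
#' is then exactly 1. When a protein is undetectable in the reference group
#' (zero or missing load-corrected signal), the fallback reference group is
#' used instead and recorded in the \code{referenceUsed} column.
#'
#' @param table data.frame with columns \code{sample} (group label),
#'   \code{protein}, \code{bandIntensity} and \code{laneTotal}.
#' @param referenceGroup sample label normalized to 1.
#' @param fallbackReference optional sample label used for proteins
#'   undetectable in the reference group.
#' @return the table with added columns \code{loadNormalized},
#'   \code{normalizedExpression} and \code{referenceUsed}.
#' @export
densitometryNormalize <- function(table, referenceGroup,
                                  fallbackReference = NULL) {
  need <- c("sample", "protein", "bandIntensity", "laneTotal")
  stopIfNot(all(need %in% names(table)),
            paste("table needs columns:", paste(need, collapse = ", ")))
  stopIfNot(all(table$laneTotal > 0), "all lane totals must be > 0")
  stopIfNot(referenceGroup %in% table$sample,
            sprintf("reference group '%s' absent from table", referenceGroup))
  table$loadNormalized <- table$bandIntensity / table$laneTotal
  table$normalizedExpression <- NA_real_
  table$referenceUsed <- NA_character_
  for (p in unique(table$protein)) {
    rows <- table$protein == p
    refVals <- table$loadNormalized[rows & table$sample == referenceGroup]
    refUsed <- referenceGroup
    if (length(refVals) == 0L || !any(is.finite(refVals)) ||
        mean(refVals, na.rm = TRUE) <= 0) {
      stopIfNot(!is.null(fallbackReference),
        sprintf("protein '%s' undetectable in reference group '%s' and no fallback given",
                p, referenceGroup))
      refVals <- table$loadNormalized[rows & table$sample == fallbackReference]
      stopIfNot(length(refVals) > 0L && mean(refVals, na.rm = TRUE) > 0,
        sprintf("protein '%s' also undetectable in fallback group '%s'",
                p, fallbackReference))
      refUsed <- fallbackReference
    }
    table$normalizedExpression[rows] <-
      table$loadNormalized[rows] / mean(refVals, na.rm = TRUE)
    table$referenceUsed[rows] <- refUsed
  }
  table
}
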