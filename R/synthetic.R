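# Synthetic-data generators: every input the pipeline consumes, with recorded
# ground truth, so all downstream stages are testable without real
# acquisitions.

#' Construct a BeatSpec
#'
#' @param frameRate frames per second (phase-contrast video microscopy of
#'   beating monolayers is typically recorded at 25 fps).
#' @param duration recording length, s (default 120 s).
#' @param imageShape integer (rows, cols) of each frame.
#' @param clusters data.frame with columns \code{row}, \code{col},
#'   \code{radius} (px), \code{beatPeriod}, \code{doubletGap},
#'   \code{phaseDelay} (s) and \code{amplitude} (intensity units); one row per
#'   beating cluster. Zero rows give a static (noise-only) video.
#' @param burstSigma Gaussian time-envelope sd of a single contraction or
#'   relaxation burst, s.
#' @param noiseSd additive Gaussian pixel noise sd, intensity units.
#' @param bitScale maximum intensity value of the virtual camera.
#' @return a validated \linkS4class{BeatSpec}.
#' @export
#' @examples
#' sp <- beatSpec(clusters = beatCluster(24, 24, radius = 8))
#' sp
beatSpec <- function(frameRate = 25, duration = 120,
                     imageShape = c(48L, 48L),
                     clusters = beatCluster(numeric(0), numeric(0)),
                     burstSigma = 0.04, noiseSd = 0.5, bitScale = 255) {
  new("BeatSpec", frameRate = frameRate, duration = duration,
      imageShape = as.integer(imageShape), clusters = clusters,
      burstSigma = burstSigma, noiseSd = noiseSd, bitScale = bitScale)
}

#' @rdname beatSpec
#' @param row,col cluster center, px.
#' @param radius cluster radius, px (>= 1).
#' @param beatPeriod seconds per beat.
#' @param doubletGap center-to-center separation of the contraction and
#'   relaxation bursts of one beat, s.
#' @param phaseDelay onset delay of this cluster relative to the recording
#'   start, s. Different delays across clusters emulate the asynchronous
#'   firing of immature cardiomyocyte clusters.
#' @param amplitude per-pixel perturbation amplitude, intensity units.
#' @export
beatCluster <- function(row, col, radius = 8, beatPeriod = 2,
                        doubletGap = 0.3, phaseDelay = 0, amplitude = 40) {
  n <- length(row)
  data.frame(row = row, col = col,
             radius = rep_len(radius, n),
             beatPeriod = rep_len(beatPeriod, n),
             doubletGap = rep_len(doubletGap, n),
             phaseDelay = rep_len(phaseDelay, n),
             amplitude = rep_len(amplitude, n))
}

#' Construct a VideoStack
#'
#' @param frames numeric array, dim = c(T, H, W).
#' @param frameRate frames per second.
#' @param pixelSize µm per pixel (NA if uncalibrated).
#' @param bitScale maximum representable intensity.
#' @return a validated \linkS4class{VideoStack}.
#' @export
videoStack <- function(frames, frameRate, pixelSize = NA_real_,
                       bitScale = 255) {
  new("VideoStack", frames = frames, frameRate = frameRate,
      pixelSize = pixelSize, bitScale = bitScale)
}

# disc mask center (r0, c0), radius rad, in an H x W image -> logical matrix
discMask <- function(H, W, r0, c0, rad) {
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  (rr - r0)^2 + (cc - c0)^2 <= rad^2
}

#' Simulate a beating-monolayer video with ground truth
#'
#' Generates a phase-contrast-like grayscale video in which each cluster of
#' pixels emits one contraction/relaxation burst doublet per beat. A burst is
#' a Gaussian-in-time envelope (sd \code{burstSigma}, truncated at two sigma)
#' that modulates fresh per-frame Gaussian perturbations of the cluster's
#' pixels, so the frame-difference trace rises and falls with the envelope.
#' The truncation gives every burst an exact frame support which is recorded
#' in the returned truth table.
#'
#' Cluster k fires \code{floor((duration - phaseDelay) / beatPeriod)}
#' doublets; doublet j occupies the beat window starting at
#' \code{phaseDelay + (j-1) * beatPeriod}, with the contraction burst
#' centered \code{2 * burstSigma} into the window and the relaxation burst
#' \code{doubletGap} later.
#'
#' @param spec a \linkS4class{BeatSpec}.
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @return list with \code{video} (a \linkS4class{VideoStack}) and
#'   \code{truth}, a data.frame with one row per burst: \code{cluster},
#'   \code{beat}, \code{phase} ("contraction"/"relaxation"), the frame
#'   support \code{startFrame}/\code{endFrame} (half-open), the affected
#'   trace-sample interval \code{traceStart}/\code{traceEnd} (closed, in
#'   frame-difference index space) and the burst center time \code{center}
#'   (s).
#' @export
#' @examples
#' sim <- simulateBeatingVideo(
#'   beatSpec(duration = 10, clusters = beatCluster(24, 24)), seed = 1)
#' sim$video
#' head(sim$truth)
simulateBeatingVideo <- function(spec, seed = 1L) {
  stopifnot(is(spec, "BeatSpec"))
  validObject(spec)
  fps <- spec@frameRate
  nT <- as.integer(round(spec@duration * fps))
  stopIfNot(nT >= 2L, "duration x frameRate must give at least 2 frames")
  H <- spec@imageShape[1]; W <- spec@imageShape[2]
  sig <- spec@burstSigma
  base <- spec@bitScale / 2
  tFrame <- (seq_len(nT) - 1) / fps

  withSeed(seed, {
    fr <- array(base, dim = c(nT, H, W))
    if (spec@noiseSd > 0)
      fr <- fr + array(stats::rnorm(nT * H * W, sd = spec@noiseSd),
                       dim = c(nT, H, W))
    rows <- list()
    cl <- spec@clusters
    for (ci in seq_len(nrow(cl))) {
      mask <- discMask(H, W, cl$row[ci], cl$col[ci], cl$radius[ci])
      idx <- which(mask)                      # within an H x W slice
      nPix <- length(idx)
      nBeats <- floor((spec@duration - cl$phaseDelay[ci]) / cl$beatPeriod[ci])
      for (b in seq_len(nBeats)) {
        w0 <- cl$phaseDelay[ci] + (b - 1) * cl$beatPeriod[ci]
        centers <- c(contraction = w0 + 2 * sig,
                     relaxation  = w0 + 2 * sig + cl$doubletGap[ci])
        for (ph in names(centers)) {
          cen <- centers[[ph]]
          sup <- which(tFrame >= cen - 2 * sig & tFrame <= cen + 2 * sig)
          if (length(sup) == 0L) next
          env <- exp(-(tFrame[sup] - cen)^2 / (2 * sig^2))
          for (s in seq_along(sup)) {
            k <- sup[s]
            pert <- cl$amplitude[ci] * env[s] * stats::rnorm(nPix)
            fr[(idx - 1L) * nT + k] <- fr[(idx - 1L) * nT + k] + pert
          }
          rows[[length(rows) + 1L]] <- data.frame(
            cluster = ci, beat = b, phase = ph,
            startFrame = min(sup), endFrame = max(sup) + 1L,
            traceStart = max(1L, min(sup) - 1L),
            traceEnd = min(nT - 1L, max(sup)),
            center = cen)
        }
      }
    }
    fr[fr < 0] <- 0
    fr[fr > spec@bitScale] <- spec@bitScale
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(cluster = integer(0), beat = integer(0),
                 phase = character(0), startFrame = integer(0),
                 endFrame = integer(0), traceStart = integer(0),
                 traceEnd = integer(0), center = numeric(0))
    list(video = videoStack(fr, fps, bitScale = spec@bitScale),
         truth = truth)
  })
}

#' Construct a CurveSpec
#'
#' @param eTrue true Young's modulus, Pa.
#' @param contactPoint true contact position, m.
#' @param probeRadius sphere radius, m (default 2.385 µm, a 4.77 µm diameter
#'   silica colloid).
#' @param poisson Poisson's ratio (default 0.5, incompressible, the standard
#'   choice for live cells).
#' @param maxIndentation maximum indentation depth, m.
#' @param baselineLength pre-contact travel, m.
#' @param nPoints number of samples.
#' @param noiseSd Gaussian force noise sd, N.
#' @param baselineSlope linear baseline tilt, N/m.
#' @param seed integer seed.
#' @return a validated \linkS4class{CurveSpec}.
#' @export
curveSpec <- function(eTrue = 1000, contactPoint = 1e-6,
                      probeRadius = 2.385e-6, poisson = 0.5,
                      maxIndentation = 5e-7, baselineLength = 1e-6,
                      nPoints = 200L, noiseSd = 0, baselineSlope = 0,
                      seed = 1L) {
  new("CurveSpec", eTrue = eTrue, contactPoint = contactPoint,
      probeRadius = probeRadius, poisson = poisson,
      maxIndentation = maxIndentation, baselineLength = baselineLength,
      nPoints = as.integer(nPoints), noiseSd = noiseSd,
      baselineSlope = baselineSlope, seed = as.integer(seed))
}

#' Construct a ForceCurve
#'
#' @param position approach positions, m (strictly monotone increasing).
#' @param force measured force, N.
#' @param metadata named list of grouping labels and acquisition details.
#' @param truth named list of generating parameters (simulated curves only).
#' @return a validated \linkS4class{ForceCurve}.
#' @export
forceCurve <- function(position, force, metadata = list(), truth = list()) {
  new("ForceCurve", position = position, force = force,
      metadata = metadata, truth = truth)
}

#' Simulate a Hertz approach force curve
#'
#' Forward model: positions run from \code{contactPoint - baselineLength} to
#' \code{contactPoint + maxIndentation}; force is a linear baseline before
#' contact and baseline + Hertz spherical-indenter response beyond it, plus
#' i.i.d. Gaussian noise. The generating parameters are stored in the curve's
#' \code{truth} so inverse fitting can be scored.
#'
#' @param spec a \linkS4class{CurveSpec}.
#' @param metadata optional grouping labels attached to the curve.
#' @return a \linkS4class{ForceCurve}.
#' @seealso [hertzForce()], [fitHertz()]
#' @export
#' @examples
#' fc <- simulateForceCurve(curveSpec(eTrue = 1000, noiseSd = 5e-12))
#' fc
simulateForceCurve <- function(spec, metadata = list()) {
  stopifnot(is(spec, "CurveSpec"))
  validObject(spec)
  pos <- seq(spec@contactPoint - spec@baselineLength,
             spec@contactPoint + spec@maxIndentation,
             length.out = spec@nPoints)
  delta <- pmax(pos - spec@contactPoint, 0)
  probe <- probeSpec(radius = spec@probeRadius, poisson = spec@poisson)
  f <- spec@baselineSlope * (pos - pos[1]) +
    hertzForce(spec@eTrue, probe, delta)
  if (spec@noiseSd > 0)
    f <- f + withSeed(spec@seed, stats::rnorm(length(f), sd = spec@noiseSd))
  md <- utils::modifyList(
    list(mode = "indentation", probeRadius = spec@probeRadius), metadata)
  forceCurve(pos, f, metadata = md,
             truth = list(eTrue = spec@eTrue,
                          contactPoint = spec@contactPoint,
                          probeRadius = spec@probeRadius,
                          poisson = spec@poisson,
                          noiseSd = spec@noiseSd,
                          baselineSlope = spec@baselineSlope))
}

#' Construct an ImageSpec
#'
#' @param shape integer (rows, cols).
#' @param pixelSize µm per pixel.
#' @param objects data.frame from [imageObject()] (zero rows for an empty
#'   field).
#' @param background background intensity.
#' @param noiseSd global additive Gaussian noise sd.
#' @param seed integer seed.
#' @return a validated \linkS4class{ImageSpec}.
#' @export
imageSpec <- function(shape = c(128L, 128L), pixelSize = 1,
                      objects = imageObject(numeric(0), numeric(0)),
                      background = 10, noiseSd = 0, seed = 1L) {
  new("ImageSpec", shape = as.integer(shape), pixelSize = pixelSize,
      objects = objects, background = background, noiseSd = noiseSd,
      seed = as.integer(seed))
}

#' @rdname imageSpec
#' @param row,col object center, px.
#' @param height,width object extent, px (a disc uses \code{width} as its
#'   diameter).
#' @param shapeType "rect" or "disc".
#' @param meanIntensity mean object intensity.
#' @param intensitySd per-pixel intensity sd within the object (object
#'   texture).
#' @export
imageObject <- function(row, col, height = 10, width = 10,
                        shapeType = "rect", meanIntensity = 100,
                        intensitySd = 0) {
  n <- length(row)
  data.frame(shape = rep_len(shapeType, n), row = row, col = col,
             height = rep_len(height, n), width = rep_len(width, n),
             meanIntensity = rep_len(meanIntensity, n),
             intensitySd = rep_len(intensitySd, n))
}

# paint spec objects onto a background; returns image (pre global noise),
# integer label matrix (later objects overwrite earlier on overlap) and the
# per-object truth
paintObjects <- function(spec) {
  H <- spec@shape[1]; W <- spec@shape[2]
  img <- matrix(spec@background, H, W)
  lab <- matrix(0L, H, W)
  ob <- spec@objects
  for (i in seq_len(nrow(ob))) {
    if (ob$shape[i] == "disc") {
      m <- discMask(H, W, ob$row[i], ob$col[i], ob$width[i] / 2)
    } else {
      r1 <- max(1L, ceiling(ob$row[i] - ob$height[i] / 2))
      r2 <- min(H, r1 + ob$height[i] - 1L)
      c1 <- max(1L, ceiling(ob$col[i] - ob$width[i] / 2))
      c2 <- min(W, c1 + ob$width[i] - 1L)
      m <- matrix(FALSE, H, W); m[r1:r2, c1:c2] <- TRUE
    }
    vals <- ob$meanIntensity[i]
    if (ob$intensitySd[i] > 0)
      vals <- vals + stats::rnorm(sum(m), sd = ob$intensitySd[i])
    img[m] <- vals
    lab[m] <- i
  }
  truth <- do.call(rbind, lapply(seq_len(nrow(ob)), function(i) {
    px <- lab == i
    data.frame(object = i, nPixels = sum(px),
               area = sum(px) * spec@pixelSize^2,
               meanIntensity = ob$meanIntensity[i],
               meanDrawnIntensity = if (any(px)) mean(img[px]) else NA_real_)
  }))
  if (is.null(truth))
    truth <- data.frame(object = integer(0), nPixels = integer(0),
                        area = numeric(0), meanIntensity = numeric(0),
                        meanDrawnIntensity = numeric(0))
  list(image = img, labels = lab, truth = truth)
}

#' Simulate a labeled fluorescence image with ground truth
#'
#' Paints the spec's objects (in order; later objects overwrite earlier ones
#' where they overlap) onto a flat background, draws per-pixel object texture
#' where \code{intensitySd > 0}, then adds global Gaussian noise. The truth
#' table records each object's exact visible pixel area (µm²) and the mean of
#' its drawn intensities before global noise.
#'
#' @param spec an \linkS4class{ImageSpec}.
#' @return list with \code{image} (numeric matrix), \code{labels} (integer
#'   matrix; 0 = background) and \code{truth} (data.frame: object, nPixels,
#'   area, meanIntensity, meanDrawnIntensity).
#' @export
#' @examples
#' sim <- simulateLabeledImage(imageSpec(
#'   objects = imageObject(c(30, 80), c(30, 80), 10, 10)))
#' sim$truth
simulateLabeledImage <- function(spec) {
  stopifnot(is(spec, "ImageSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    p <- paintObjects(spec)
    if (spec@noiseSd > 0)
      p$image <- p$image +
        matrix(stats::rnorm(length(p$image), sd = spec@noiseSd),
               nrow(p$image), ncol(p$image))
    p
  })
}

#' Simulate a two-channel ratiometric (JC-1-like) image pair
#'
#' The monomer channel is a labeled image drawn from \code{spec}; the
#' aggregate channel shares the same noiseless object structure scaled by
#' \code{ratio} inside the object masks, then each channel receives
#' independent global Gaussian noise of sd \code{spec@noiseSd}. Before noise,
#' the pixelwise aggregate/monomer quotient inside the masks is exactly
#' \code{ratio}.
#'
#' @param spec an \linkS4class{ImageSpec}.
#' @param ratio generating aggregate/monomer ratio (> 0).
#' @return list with \code{aggregate}, \code{monomer} (numeric matrices),
#'   \code{labels} and \code{truth} (the labeled-image truth plus the
#'   generating \code{ratio}).
#' @export
simulateRatioPair <- function(spec, ratio) {
  stopifnot(is(spec, "ImageSpec"))
  validObject(spec)
  stopIfNot(length(ratio) == 1L && ratio > 0, "ratio must be > 0")
  withSeed(spec@seed, {
    p <- paintObjects(spec)
    agg <- p$image
    inMask <- p$labels > 0L
    agg[inMask] <- ratio * p$image[inMask]
    mon <- p$image
    if (spec@noiseSd > 0) {
      mon <- mon + matrix(stats::rnorm(length(mon), sd = spec@noiseSd),
                          nrow(mon), ncol(mon))
      agg <- agg + matrix(stats::rnorm(length(agg), sd = spec@noiseSd),
                          nrow(agg), ncol(agg))
    }
    p$truth$ratio <- if (nrow(p$truth)) ratio else numeric(0)
    list(aggregate = agg, monomer = mon, labels = p$labels, truth = p$truth)
  })
}

#' Simulate a striated (sarcomere-like) band pattern
#'
#' A sinusoidal band pattern of known peak-to-peak spacing, used as ground
#' truth for band-spacing estimation. Intensity at pixel (r, c) is
#' \code{offset + amplitude * cos(2 * pi * u / periodPx)} with
#' \code{u = c * cos(theta) + r * sin(theta)}; orientation 0 gives vertical
#' bands (intensity varies along columns) and 90 the transposed pattern.
#'
#' @param period band spacing, µm; must exceed \code{2 * pixelSize}
#'   (Nyquist).
#' @param pixelSize µm per pixel.
#' @param shape integer (rows, cols).
#' @param orientation band normal direction, degrees.
#' @param amplitude,offset intensity scale of the pattern.
#' @param noiseSd additive Gaussian noise sd.
#' @param seed integer seed (used only when \code{noiseSd > 0}).
#' @return numeric matrix.
#' @export
#' @examples
#' img <- simulateStriationImage(1.65, 0.1, c(64L, 256L))
simulateStriationImage <- function(period, pixelSize, shape = c(128L, 128L),
                                   orientation = 0, amplitude = 100,
                                   offset = 110, noiseSd = 0, seed = 1L) {
  stopIfNot(is.finite(period) && period > 2 * pixelSize,
            "period must be finite and exceed 2 * pixelSize (Nyquist)")
  stopIfNot(pixelSize > 0, "pixelSize must be > 0")
  shape <- as.integer(shape)
  th <- orientation * pi / 180
  periodPx <- period / pixelSize
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  u <- cc * cos(th) + rr * sin(th)
  img <- offset + amplitude * cos(2 * pi * u / periodPx)
  if (noiseSd > 0)
    img <- img + withSeed(seed,
      matrix(stats::rnorm(length(img), sd = noiseSd), shape[1], shape[2]))
  img
}
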