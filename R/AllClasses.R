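#' @import methods
NULL

# ---------------------------------------------------------------------------
# Simulation specifications
# ---------------------------------------------------------------------------

#' Specification of a synthetic beating-monolayer video
#'
#' Describes the acquisition (frame rate, duration, image geometry, camera
#' bit scale) and the beating phenotype: one or more spatial clusters, each
#' emitting one contraction/relaxation burst doublet per beat. Bursts are
#' Gaussian-in-time intensity perturbations of the cluster pixels, truncated
#' at two standard deviations so every burst has an exact frame support that
#' the ground-truth table can record.
#'
#' @slot frameRate frames per second (> 0).
#' @slot duration recording length in seconds.
#' @slot imageShape integer (rows, cols) of each frame.
#' @slot clusters data.frame with one row per beating cluster, columns
#'   \code{row}, \code{col} (center, px), \code{radius} (px, >= 1),
#'   \code{beatPeriod} (s), \code{doubletGap} (s, center-to-center separation
#'   of the contraction and relaxation bursts), \code{phaseDelay} (s, >= 0)
#'   and \code{amplitude} (intensity units).
#' @slot burstSigma standard deviation (s) of the Gaussian time envelope of a
#'   single burst; the burst support is \code{4 * burstSigma} seconds.
#' @slot noiseSd additive Gaussian pixel noise, intensity units.
#' @slot bitScale maximum intensity value (e.g. 255 for 8-bit, 16383 for
#'   14-bit acquisition).
#' @name BeatSpec-class
#' @exportClass BeatSpec
setClass("BeatSpec",
  representation(
    frameRate  = "numeric",
    duration   = "numeric",
    imageShape = "integer",
    clusters   = "data.frame",
    burstSigma = "numeric",
    noiseSd    = "numeric",
    bitScale   = "numeric"
  )
)

setValidity("BeatSpec", function(object) {
  msg <- character()
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (length(object@duration) != 1L || object@duration <= 0)
    msg <- c(msg, "duration must be a single positive number")
  if (length(object@imageShape) != 2L || any(object@imageShape < 1L))
    msg <- c(msg, "imageShape must be two positive integers (rows, cols)")
  if (length(object@burstSigma) != 1L || object@burstSigma <= 0)
    msg <- c(msg, "burstSigma must be positive")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@bitScale <= 0) msg <- c(msg, "bitScale must be > 0")
  cl <- object@clusters
  need <- c("row", "col", "radius", "beatPeriod", "doubletGap",
            "phaseDelay", "amplitude")
  if (!all(need %in% names(cl))) {
    msg <- c(msg, paste("clusters must have columns:",
                        paste(need, collapse = ", ")))
  } else if (nrow(cl) > 0L) {
    if (any(cl$radius < 1)) msg <- c(msg, "cluster radius must be >= 1 px")
    if (any(cl$doubletGap <= 0)) msg <- c(msg, "doubletGap must be > 0")
    if (any(cl$beatPeriod <= cl$doubletGap))
      msg <- c(msg, "beatPeriod must exceed doubletGap")
    if (any(cl$phaseDelay < 0)) msg <- c(msg, "phaseDelay must be >= 0")
    if (any(cl$amplitude < 0)) msg <- c(msg, "amplitude must be >= 0")
    out <- cl$row - cl$radius < 1 | cl$row + cl$radius > object@imageShape[1] |
           cl$col - cl$radius < 1 | cl$col + cl$radius > object@imageShape[2]
    if (any(out))
      msg <- c(msg, sprintf(
        "cluster(s) %s extend outside the %d x %d image",
        paste(which(out), collapse = ", "),
        object@imageShape[1], object@imageShape[2]))
    # a whole doublet (4 sigma per burst + gap) must fit in one beat window
    span <- cl$doubletGap + 4 * object@burstSigma
    if (any(span > cl$beatPeriod))
      msg <- c(msg, "doublet span (doubletGap + 4*burstSigma) must fit within beatPeriod")
  }
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic Hertz approach force curve
#'
#' Forward model of an AFM indentation on an elastic half-space with a
#' spherical probe: force is zero (plus baseline tilt and noise) before the
#' contact point and follows the Hertz law beyond it.
#'
#' @slot eTrue true Young's modulus, Pa.
#' @slot contactPoint true contact position, m (positions beyond it indent).
#' @slot probeRadius sphere radius, m.
#' @slot poisson Poisson's ratio (0 to 0.5; 0.5 = incompressible, the value
#'   used for live cells).
#' @slot maxIndentation maximum indentation depth, m.
#' @slot baselineLength pre-contact travel included before the contact
#'   point, m.
#' @slot nPoints number of samples along the approach.
#' @slot noiseSd additive Gaussian force noise, N.
#' @slot baselineSlope linear baseline tilt, N/m.
#' @slot seed integer seed consumed by [simulateForceCurve()].
#' @name CurveSpec-class
#' @exportClass CurveSpec
setClass("CurveSpec",
  representation(
    eTrue          = "numeric",
    contactPoint   = "numeric",
    probeRadius    = "numeric",
    poisson        = "numeric",
    maxIndentation = "numeric",
    baselineLength = "numeric",
    nPoints        = "integer",
    noiseSd        = "numeric",
    baselineSlope  = "numeric",
    seed           = "integer"
  )
)

setValidity("CurveSpec", function(object) {
  msg <- character()
  if (object@eTrue <= 0) msg <- c(msg, "eTrue must be > 0")
  if (object@probeRadius <= 0) msg <- c(msg, "probeRadius must be > 0")
  if (object@poisson < 0 || object@poisson > 0.5)
    msg <- c(msg, "poisson must lie in [0, 0.5]")
  if (object@maxIndentation <= 0) msg <- c(msg, "maxIndentation must be > 0")
  if (object@baselineLength <= 0) msg <- c(msg, "baselineLength must be > 0")
  if (object@nPoints < 20L) msg <- c(msg, "nPoints must be >= 20")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic labeled fluorescence image
#'
#' A flat background plus simple geometric objects (rectangles or discs) of
#' known mean intensity, with optional per-object and global Gaussian noise.
#' The generator records each object's exact pixel mask so segmentation and
#' intensity quantification can be checked against ground truth.
#'
#' @slot shape integer (rows, cols).
#' @slot pixelSize µm per pixel.
#' @slot objects data.frame with columns \code{shape} ("rect" or "disc"),
#'   \code{row}, \code{col} (center), \code{height}, \code{width} (px; a disc
#'   uses \code{width} as its diameter), \code{meanIntensity} and
#'   \code{intensitySd}.
#' @slot background background intensity.
#' @slot noiseSd global additive Gaussian noise, intensity units.
#' @slot seed integer seed.
#' @name ImageSpec-class
#' @exportClass ImageSpec
setClass("ImageSpec",
  representation(
    shape      = "integer",
    pixelSize  = "numeric",
    objects    = "data.frame",
    background = "numeric",
    noiseSd    = "numeric",
    seed       = "integer"
  )
)

setValidity("ImageSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 2L || any(object@shape < 1L))
    msg <- c(msg, "shape must be two positive integers")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@background < 0) msg <- c(msg, "background must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  ob <- object@objects
  need <- c("shape", "row", "col", "height", "width",
            "meanIntensity", "intensitySd")
  if (!all(need %in% names(ob))) {
    msg <- c(msg, paste("objects must have columns:",
                        paste(need, collapse = ", ")))
  } else if (nrow(ob) > 0L) {
    if (!all(ob$shape %in% c("rect", "disc")))
      msg <- c(msg, "object shape must be 'rect' or 'disc'")
    if (any(ob$meanIntensity < 0)) msg <- c(msg, "object intensities must be >= 0")
    if (any(ob$intensitySd < 0)) msg <- c(msg, "object intensitySd must be >= 0")
    r1 <- ob$row - ob$height / 2; r2 <- ob$row + ob$height / 2
    c1 <- ob$col - ob$width / 2;  c2 <- ob$col + ob$width / 2
    out <- r1 < 0.5 | r2 > object@shape[1] + 0.5 |
           c1 < 0.5 | c2 > object@shape[2] + 0.5
    if (any(out))
      msg <- c(msg, sprintf("object(s) %s lie outside the image",
                            paste(which(out), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Data containers
# ---------------------------------------------------------------------------

#' Grayscale video stack
#'
#' A T x H x W array of non-negative intensities with its acquisition frame
#' rate, optional pixel size and the intensity scale of the camera.
#'
#' @slot frames numeric array, dim = c(T, H, W), T >= 2.
#' @slot frameRate frames per second.
#' @slot pixelSize µm per pixel, or NA when uncalibrated.
#' @slot bitScale maximum representable intensity.
#' @name VideoStack-class
#' @exportClass VideoStack
setClass("VideoStack",
  representation(
    frames    = "array",
    frameRate = "numeric",
    pixelSize = "numeric",
    bitScale  = "numeric"
  )
)

setValidity("VideoStack", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L) msg <- c(msg, "frames must be a 3-d array (T, H, W)")
  else if (d[1] < 2L) msg <- c(msg, "a video needs at least 2 frames")
  if (any(object@frames < 0)) msg <- c(msg, "intensities must be >= 0")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (object@bitScale <= 0) msg <- c(msg, "bitScale must be > 0")
  if (length(msg)) msg else TRUE
})

#' Frame-difference motion trace
#'
#' For a video of T frames, the length T-1 series of mean absolute pixel
#' intensity change between consecutive frames. Non-negative by construction
#' until a fitted baseline has been subtracted.
#'
#' @slot values numeric series of length T-1 (intensity units).
#' @slot frameRate frames per second of the source video.
#' @slot baselineRemoved TRUE once [baselineCorrect()] has run.
#' @name MotionTrace-class
#' @exportClass MotionTrace
setClass("MotionTrace",
  representation(
    values          = "numeric",
    frameRate       = "numeric",
    baselineRemoved = "logical"
  )
)

setValidity("MotionTrace", function(object) {
  msg <- character()
  if (length(object@values) < 1L) msg <- c(msg, "trace must be non-empty")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
  if (!object@baselineRemoved && any(object@values < -1e-12))
    msg <- c(msg, "raw trace values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Time-integrated motion map
#'
#' Per-pixel sum of absolute frame-to-frame intensity change accumulated over
#' a stated time window; highlights the regions of a monolayer that move.
#'
#' @slot map H x W non-negative matrix.
#' @slot window integration window, seconds.
#' @name MotionMap-class
#' @exportClass MotionMap
setClass("MotionMap",
  representation(map = "matrix", window = "numeric")
)

setValidity("MotionMap", function(object) {
  msg <- character()
  if (any(object@map < 0)) msg <- c(msg, "map must be non-negative")
  if (object@window <= 0) msg <- c(msg, "window must be > 0")
  if (length(msg)) msg else TRUE
})

#' AFM approach force curve
#'
#' Two-column force spectroscopy record: probe position along the approach
#' direction (strictly monotone increasing towards the sample) and measured
#' force. Metadata carries grouping labels (cell type, treatment, replicate,
#' day) and acquisition details; curves simulated by [simulateForceCurve()]
#' also carry their ground truth.
#'
#' @slot position numeric, m, strictly monotone increasing, >= 20 samples.
#' @slot force numeric, N, same length as position.
#' @slot metadata named list (cellType, treatment, replicate, day,
#'   probeRadius, mode, ...).
#' @slot truth named list with the generating parameters (empty for measured
#'   curves).
#' @name ForceCurve-class
#' @exportClass ForceCurve
setClass("ForceCurve",
  representation(
    position = "numeric",
    force    = "numeric",
    metadata = "list",
    truth    = "list"
  )
)

setValidity("ForceCurve", function(object) {
  msg <- character()
  if (length(object@position) < 20L)
    msg <- c(msg, "a force curve needs at least 20 samples")
  if (length(object@force) != length(object@position))
    msg <- c(msg, "position and force must have equal length")
  if (any(diff(object@position) <= 0))
    msg <- c(msg, "position must be strictly monotone increasing")
  if (length(msg)) msg else TRUE
})

#' Result of a Hertz spherical-indenter fit
#'
#' Least-squares estimates of Young's modulus, contact point and baseline
#' offset for one approach curve, with the residual RMS and contact-point
#' deviation used by the quality filter. \code{rejectReason} is one of
#' \code{"none"}, \code{"rms"}, \code{"contact_dev"}, \code{"e_range"} or
#' \code{"unfit"} (no post-contact force rise, so no modulus could be
#' estimated).
#'
#' @slot youngsModulus E, Pa (NA for unfit curves).
#' @slot contactPoint fitted contact position, m.
#' @slot baselineOffset fitted force offset, N.
#' @slot rmsResidual root mean square of fit residuals, N.
#' @slot contactPointDeviation |fitted contact point - threshold-crossing
#'   estimate|, m.
#' @slot accepted QC flag.
#' @slot rejectReason first failing QC criterion, or "none".
#' @slot nPoints number of samples in the fitted range.
#' @slot metadata grouping labels copied from the curve.
#' @name HertzFit-class
#' @exportClass HertzFit
setClass("HertzFit",
  representation(
    youngsModulus         = "numeric",
    contactPoint          = "numeric",
    baselineOffset        = "numeric",
    rmsResidual           = "numeric",
    contactPointDeviation = "numeric",
    accepted              = "logical",
    rejectReason          = "character",
    nPoints               = "integer",
    metadata              = "list"
  )
)

setValidity("HertzFit", function(object) {
  msg <- character()
  ok <- c("none", "rms", "contact_dev", "e_range", "unfit")
  if (!object@rejectReason %in% ok)
    msg <- c(msg, paste("rejectReason must be one of",
                        paste(ok, collapse = ", ")))
  if (isTRUE(object@accepted) &&
      (is.na(object@youngsModulus) || object@youngsModulus <= 0))
    msg <- c(msg, "accepted fits must have a positive Young's modulus")
  if (!is.na(object@rmsResidual) && object@rmsResidual < 0)
    msg <- c(msg, "rmsResidual must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Pixelwise ratiometric image (JC-1 aggregate / monomer)
#'
#' The per-pixel quotient of two fluorescence channels, defined only where
#' the denominator channel exceeds a floor; the summary statistic is the mean
#' ratio over that valid mask (NA when the mask is empty).
#'
#' @slot ratioMap numeric matrix, NA outside the valid mask.
#' @slot validMask logical matrix, TRUE where the ratio is defined.
#' @slot meanRatio mean of ratioMap over the valid mask (NA if empty).
#' @name RatioImage-class
#' @exportClass RatioImage
setClass("RatioImage",
  representation(
    ratioMap  = "matrix",
    validMask = "matrix",
    meanRatio = "numeric"
  )
)

setValidity("RatioImage", function(object) {
  msg <- character()
  if (!identical(dim(object@ratioMap), dim(object@validMask)))
    msg <- c(msg, "ratioMap and validMask must have the same shape")
  if (!is.logical(object@validMask))
    msg <- c(msg, "validMask must be logical")
  if (any(!is.na(object@ratioMap[!object@validMask])))
    msg <- c(msg, "ratioMap must be NA outside the valid mask")
  if (length(msg)) msg else TRUE
})

#' Group comparison result
#'
#' Output of the two-group t test or the one-way ANOVA + Tukey HSD wrapper:
#' the global statistic and p value, the group labels, a pairwise table when
#' three or more groups are compared, and significance stars following the
#' usual convention (* p < 0.05, ** p < 0.01, *** p < 0.001).
#'
#' @slot test name of the test performed.
#' @slot groups group labels.
#' @slot statistic global test statistic (t or F).
#' @slot pValue global p value.
#' @slot pairwise data.frame of pairwise adjusted comparisons (zero rows for
#'   two-group tests).
#' @slot stars significance stars for the global p value.
#' @name ComparisonResult-class
#' @exportClass ComparisonResult
setClass("ComparisonResult",
  representation(
    test      = "character",
    groups    = "character",
    statistic = "numeric",
    pValue    = "numeric",
    pairwise  = "data.frame",
    stars     = "character"
  )
)

setValidity("ComparisonResult", function(object) {
  msg <- character()
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (length(object@groups) >= 3L && nrow(object@pairwise) == 0L)
    msg <- c(msg, "multi-group comparisons must carry a pairwise table")
  if (length(msg)) msg else TRUE
})
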