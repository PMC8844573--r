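# Accessor generics. Slots are never reached into directly by user code.

#' @rdname VideoStack-class
#' @param object,x a MyoTrack S4 object.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname VideoStack-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname VideoStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname VideoStack-class
#' @export
setGeneric("bitScale", function(x) standardGeneric("bitScale"))

#' @rdname MotionTrace-class
#' @param x a MyoTrack S4 object.
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @rdname MotionTrace-class
#' @export
setGeneric("isBaselineCorrected",
           function(x) standardGeneric("isBaselineCorrected"))

#' @rdname MotionMap-class
#' @param x a MotionMap.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname MotionMap-class
#' @export
setGeneric("mapWindow", function(x) standardGeneric("mapWindow"))

#' @rdname ForceCurve-class
#' @param x a MyoTrack S4 object.
#' @export
setGeneric("curvePosition", function(x) standardGeneric("curvePosition"))
#' @rdname ForceCurve-class
#' @export
setGeneric("curveForce", function(x) standardGeneric("curveForce"))
#' @rdname ForceCurve-class
#' @export
setGeneric("curveMetadata", function(x) standardGeneric("curveMetadata"))
#' @rdname ForceCurve-class
#' @export
setGeneric("curveTruth", function(x) standardGeneric("curveTruth"))

#' @rdname HertzFit-class
#' @param x a MyoTrack S4 object.
#' @export
setGeneric("youngsModulus", function(x) standardGeneric("youngsModulus"))
#' @rdname HertzFit-class
#' @export
setGeneric("contactPoint", function(x) standardGeneric("contactPoint"))
#' @rdname HertzFit-class
#' @export
setGeneric("rmsResidual", function(x) standardGeneric("rmsResidual"))
#' @rdname HertzFit-class
#' @export
setGeneric("contactPointDeviation",
           function(x) standardGeneric("contactPointDeviation"))
#' @rdname HertzFit-class
#' @export
setGeneric("isAccepted", function(x) standardGeneric("isAccepted"))
#' @rdname HertzFit-class
#' @export
setGeneric("rejectReason", function(x) standardGeneric("rejectReason"))

#' @rdname RatioImage-class
#' @param x a MyoTrack S4 object.
#' @export
setGeneric("ratioMap", function(x) standardGeneric("ratioMap"))
#' @rdname RatioImage-class
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname RatioImage-class
#' @export
setGeneric("meanRatio", function(x) standardGeneric("meanRatio"))

#' @rdname ComparisonResult-class
#' @param x a MyoTrack S4 object.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname ComparisonResult-class
#' @export
setGeneric("testStatistic", function(x) standardGeneric("testStatistic"))
#' @rdname ComparisonResult-class
#' @export
setGeneric("pairwiseTable", function(x) standardGeneric("pairwiseTable"))
#' @rdname ComparisonResult-class
#' @export
setGeneric("significanceStars",
           function(x) standardGeneric("significanceStars"))

# ---------------------------------------------------------------------------
# Accessor methods
# ---------------------------------------------------------------------------

#' @rdname VideoStack-class
#' @export
setMethod("frames", "VideoStack", function(x) x@frames)
#' @rdname VideoStack-class
#' @export
setMethod("frameRate", "VideoStack", function(x) x@frameRate)
#' @rdname MotionTrace-class
#' @export
setMethod("frameRate", "MotionTrace", function(x) x@frameRate)
#' @rdname VideoStack-class
#' @export
setMethod("pixelSize", "VideoStack", function(x) x@pixelSize)
#' @rdname VideoStack-class
#' @export
setMethod("bitScale", "VideoStack", function(x) x@bitScale)

#' @rdname MotionTrace-class
#' @export
setMethod("traceValues", "MotionTrace", function(x) x@values)
#' @rdname MotionTrace-class
#' @export
setMethod("isBaselineCorrected", "MotionTrace",
          function(x) x@baselineRemoved)

#' @rdname MotionMap-class
#' @export
setMethod("mapValues", "MotionMap", function(x) x@map)
#' @rdname MotionMap-class
#' @export
setMethod("mapWindow", "MotionMap", function(x) x@window)

#' @rdname ForceCurve-class
#' @export
setMethod("curvePosition", "ForceCurve", function(x) x@position)
#' @rdname ForceCurve-class
#' @export
setMethod("curveForce", "ForceCurve", function(x) x@force)
#' @rdname ForceCurve-class
#' @export
setMethod("curveMetadata", "ForceCurve", function(x) x@metadata)
#' @rdname ForceCurve-class
#' @export
setMethod("curveTruth", "ForceCurve", function(x) x@truth)
#' @rdname HertzFit-class
#' @export
setMethod("curveMetadata", "HertzFit", function(x) x@metadata)

#' @rdname HertzFit-class
#' @export
setMethod("youngsModulus", "HertzFit", function(x) x@youngsModulus)
#' @rdname HertzFit-class
#' @export
setMethod("contactPoint", "HertzFit", function(x) x@contactPoint)
#' @rdname HertzFit-class
#' @export
setMethod("rmsResidual", "HertzFit", function(x) x@rmsResidual)
#' @rdname HertzFit-class
#' @export
setMethod("contactPointDeviation", "HertzFit",
          function(x) x@contactPointDeviation)
#' @rdname HertzFit-class
#' @export
setMethod("isAccepted", "HertzFit", function(x) x@accepted)
#' @rdname HertzFit-class
#' @export
setMethod("rejectReason", "HertzFit", function(x) x@rejectReason)

#' @rdname RatioImage-class
#' @export
setMethod("ratioMap", "RatioImage", function(x) x@ratioMap)
#' @rdname RatioImage-class
#' @export
setMethod("validMask", "RatioImage", function(x) x@validMask)
#' @rdname RatioImage-class
#' @export
setMethod("meanRatio", "RatioImage", function(x) x@meanRatio)

#' @rdname ComparisonResult-class
#' @export
setMethod("pValue", "ComparisonResult", function(x) x@pValue)
#' @rdname ComparisonResult-class
#' @export
setMethod("testStatistic", "ComparisonResult", function(x) x@statistic)
#' @rdname ComparisonResult-class
#' @export
setMethod("pairwiseTable", "ComparisonResult", function(x) x@pairwise)
#' @rdname ComparisonResult-class
#' @export
setMethod("significanceStars", "ComparisonResult", function(x) x@stars)

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "VideoStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "VideoStack: %d frames of %d x %d px, %.4g fps (%.4g s), bit scale %g\n",
    d[1], d[2], d[3], object@frameRate, d[1] / object@frameRate,
    object@bitScale))
  if (!is.na(object@pixelSize))
    cat(sprintf("  pixel size: %.4g um/px\n", object@pixelSize))
})

setMethod("show", "MotionTrace", function(object) {
  cat(sprintf(
    "MotionTrace: %d samples at %.4g fps (%.4g s)%s\n",
    length(object@values), object@frameRate,
    length(object@values) / object@frameRate,
    if (object@baselineRemoved) ", baseline-corrected" else ""))
})

setMethod("show", "MotionMap", function(object) {
  cat(sprintf("MotionMap: %d x %d px integrated over %.4g s\n",
              nrow(object@map), ncol(object@map), object@window))
})

setMethod("show", "ForceCurve", function(object) {
  md <- object@metadata
  lab <- paste(
    Filter(Negate(is.null), md[c("cellType", "treatment", "replicate")]),
    collapse = " / ")
  cat(sprintf(
    "ForceCurve: %d samples, position %.4g to %.4g um, force up to %.4g nN%s\n",
    length(object@position), min(object@position) * 1e6,
    max(object@position) * 1e6, max(object@force) * 1e9,
    if (nzchar(lab)) paste0(" [", lab, "]") else ""))
})

setMethod("show", "HertzFit", function(object) {
  if (is.na(object@youngsModulus)) {
    cat("HertzFit: unfit (no post-contact force rise)\n")
  } else {
    cat(sprintf(
      "HertzFit: E = %.4g kPa, contact point %.4g um, rms %.3g pN, cp dev %.3g nm\n",
      object@youngsModulus / 1e3, object@contactPoint * 1e6,
      object@rmsResidual * 1e12, object@contactPointDeviation * 1e9))
  }
  if (!is.na(object@accepted))
    cat(sprintf("  QC: %s (%s)\n",
                if (object@accepted) "accepted" else "rejected",
                object@rejectReason))
})

setMethod("show", "RatioImage", function(object) {
  cat(sprintf(
    "RatioImage: %d x %d px, %d valid pixels (%.1f%%), mean ratio %s\n",
    nrow(object@ratioMap), ncol(object@ratioMap), sum(object@validMask),
    100 * mean(object@validMask),
    if (is.na(object@meanRatio)) "undefined" else
      sprintf("%.4g", object@meanRatio)))
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("%s over groups: %s\n", object@test,
              paste(object@groups, collapse = ", ")))
  cat(sprintf("  statistic = %.4g, p = %.4g %s\n",
              object@statistic, object@pValue, object@stars))
  if (nrow(object@pairwise) > 0L) {
    cat("  pairwise (Tukey HSD adjusted):\n")
    print(object@pairwise, row.names = FALSE)
  }
})

setMethod("show", "BeatSpec", function(object) {
  cat(sprintf(
    "BeatSpec: %.4g s at %.4g fps, %d x %d px, %d cluster(s), noise sd %.3g\n",
    object@duration, object@frameRate, object@imageShape[1],
    object@imageShape[2], nrow(object@clusters), object@noiseSd))
})

setMethod("show", "CurveSpec", function(object) {
  cat(sprintf(
    "CurveSpec: E = %.4g Pa, R = %.4g um, nu = %.2f, %d points, noise sd %.3g pN\n",
    object@eTrue, object@probeRadius * 1e6, object@poisson,
    object@nPoints, object@noiseSd * 1e12))
})

setMethod("show", "ImageSpec", function(object) {
  cat(sprintf(
    "ImageSpec: %d x %d px at %.4g um/px, %d object(s), background %.4g\n",
    object@shape[1], object@shape[2], object@pixelSize,
    nrow(object@objects), object@background))
})
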