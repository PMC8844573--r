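# Frame-difference contractility analysis: motion traces, time-integrated
# motion maps, baseline correction, threshold-based motion-period detection,
# per-trace summaries and inter-cluster synchrony.

#' Construct a MotionTrace
#'
#' @param values frame-difference series (length T-1 for a T-frame video).
#' @param frameRate frames per second of the source video.
#' @param baselineRemoved whether a baseline has already been subtracted.
#' @return a validated \linkS4class{MotionTrace}.
#' @export
motionTrace <- function(values, frameRate, baselineRemoved = FALSE) {
  new("MotionTrace", values = as.numeric(values), frameRate = frameRate,
      baselineRemoved = baselineRemoved)
}

#' Frame-difference motion trace of a video
#'
#' For every consecutive frame pair computes the absolute per-pixel intensity
#' difference |I_k - I_(k-1)| and averages it over the field of view, giving
#' one motion value per frame pair: a T-frame video yields a length T-1
#' trace. Because the measure is intensity change, not edge displacement, it
#' responds to motion below the optical resolution limit.
#'
#' @param video a \linkS4class{VideoStack}.
#' @return a \linkS4class{MotionTrace} (baseline not yet removed).
#' @export
#' @examples
#' fr <- array(c(10, 14, 9), dim = c(3, 1, 1))
#' traceValues(frameDifferenceTrace(videoStack(fr, 25)))  # 4, 5
frameDifferenceTrace <- function(video) {
  stopifnot(is(video, "VideoStack"))
  fr <- video@frames
  nT <- dim(fr)[1]
  stopIfNot(nT >= 2L, "frame differencing needs at least 2 frames")
  d <- abs(fr[-1L, , , drop = FALSE] - fr[-nT, , , drop = FALSE])
  vals <- rowMeans(matrix(d, nrow = nT - 1L))
  motionTrace(vals, video@frameRate, baselineRemoved = FALSE)
}

#' Time-integrated motion map
#'
#' Accumulates the absolute frame-to-frame intensity change per pixel over
#' the first \code{window} seconds of the recording, mapping which regions of
#' the monolayer move. The map summed over pixels equals the motion-trace sum
#' over the same window times the pixel count.
#'
#' @param video a \linkS4class{VideoStack}.
#' @param window integration window, s (positive, at most the video
#'   duration).
#' @return a \linkS4class{MotionMap}.
#' @export
motionMap <- function(video, window = 60) {
  stopifnot(is(video, "VideoStack"))
  stopIfNot(length(window) == 1L && window > 0, "window must be > 0")
  fr <- video@frames
  nT <- dim(fr)[1]
  dur <- nT / video@frameRate
  stopIfNot(window <= dur + 1e-9,
            sprintf("window (%g s) exceeds video duration (%g s)", window, dur))
  nPairs <- min(nT - 1L, as.integer(floor(window * video@frameRate + 1e-9)))
  stopIfNot(nPairs >= 1L, "window shorter than one frame interval")
  d <- abs(fr[2:(nPairs + 1L), , , drop = FALSE] -
           fr[1:nPairs, , , drop = FALSE])
  m <- matrix(colSums(matrix(d, nrow = nPairs)), dim(fr)[2], dim(fr)[3])
  new("MotionMap", map = m, window = window)
}

#' Baseline-correct a motion trace
#'
#' Fits a line by ordinary least squares to the quiescent samples (those at
#' or below the trace median, a two-pass scheme that keeps motion peaks from
#' biasing the fit) and subtracts it from the whole trace, adjusting the
#' quiescent level to zero.
#'
#' @param trace a \linkS4class{MotionTrace}.
#' @return the corrected \linkS4class{MotionTrace}
#'   (\code{isBaselineCorrected} set).
#' @export
baselineCorrect <- function(trace) {
  stopifnot(is(trace, "MotionTrace"))
  v <- trace@values
  stopIfNot(length(v) >= 2L, "baseline correction needs at least 2 samples")
  idx <- seq_along(v)
  quiescent <- v <= stats::median(v)
  fit <- stats::lm.fit(cbind(1, idx[quiescent]), v[quiescent])
  base <- fit$coefficients[1] + fit$coefficients[2] * idx
  motionTrace(v - base, trace@frameRate, baselineRemoved = TRUE)
}

#' Detect motion periods in a baseline-corrected trace
#'
#' A motion period is a maximal contiguous run of trace samples strictly
#' above \code{threshold}. A contraction/relaxation doublet whose trace dips
#' below threshold between the two peaks therefore counts as two periods;
#' set \code{mergeGap} to the doublet gap (s) to fuse runs separated by at
#' most that much quiescence into single contraction-cycle events.
#'
#' @param trace a baseline-corrected \linkS4class{MotionTrace}.
#' @param threshold detection threshold in the trace's intensity units
#'   (default 0.1; the scale is acquisition-specific, so rescale the
#'   threshold if you rescale intensities).
#' @param mergeGap maximal sub-threshold gap (s) fused into one event
#'   (default 0 = no merging).
#' @return data.frame with one row per event: \code{startFrame},
#'   \code{endFrame} (half-open trace-sample interval),
#'   \code{peakAmplitude} and \code{width} (s).
#' @export
detectMotionPeriods <- function(trace, threshold = 0.1, mergeGap = 0) {
  stopifnot(is(trace, "MotionTrace"))
  stopIfNot(isTRUE(trace@baselineRemoved),
            "trace must be baseline-corrected first (see baselineCorrect)")
  stopIfNot(length(threshold) == 1L && threshold > 0,
            "threshold must be a single positive value")
  stopIfNot(mergeGap >= 0, "mergeGap must be >= 0")
  v <- trace@values
  above <- v > threshold
  empty <- data.frame(startFrame = integer(0), endFrame = integer(0),
                      peakAmplitude = numeric(0), width = numeric(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values] + 1L)
  if (mergeGap > 0 && nrow(runs) > 1L) {
    gapSamples <- mergeGap * trace@frameRate
    merged <- runs[1L, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] <= gapSamples) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
    runs <- merged
  }
  data.frame(
    startFrame = runs$start,
    endFrame = runs$end,
    peakAmplitude = vapply(seq_len(nrow(runs)), function(i)
      max(v[runs$start[i]:(runs$end[i] - 1L)]), numeric(1)),
    width = (runs$end - runs$start) / trace@frameRate)
}

#' Summarize contractility over a trace
#'
#' Averages the detected motion periods over the entire trace: mean and SEM
#' of peak amplitude and width (contraction cycle duration) and the event
#' frequency in events per minute. With no events the frequency is zero and
#' the means are NA; with a single event the SEMs are NA (undefined).
#'
#' @param events event table from [detectMotionPeriods()].
#' @param traceDuration trace duration, s (> 0).
#' @return one-row data.frame: \code{meanAmplitude}, \code{semAmplitude},
#'   \code{meanWidth}, \code{semWidth}, \code{frequency} (events/min),
#'   \code{nEvents}, \code{traceDuration}.
#' @export
summarizeContractility <- function(events, traceDuration) {
  stopIfNot(length(traceDuration) == 1L && traceDuration > 0,
            "traceDuration must be a single positive value")
  n <- nrow(events)
  data.frame(
    meanAmplitude = if (n) mean(events$peakAmplitude) else NA_real_,
    semAmplitude = semOf(events$peakAmplitude),
    meanWidth = if (n) mean(events$width) else NA_real_,
    semWidth = semOf(events$width),
    frequency = n / (traceDuration / 60),
    nEvents = n,
    traceDuration = traceDuration)
}

# centered, zero-padded normalized cross-correlation lag of b relative to a,
# in samples; positive when b is delayed
crossLagSamples <- function(a, b, maxLagSamples) {
  a <- a - mean(a); b <- b - mean(b)
  n <- length(a)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0L)
  lags <- seq.int(-maxLagSamples, maxLagSamples)
  cc <- vapply(lags, function(d) {
    if (d >= 0) sum(a[seq_len(n - d)] * b[seq_len(n - d) + d])
    else sum(a[seq_len(n + d) - d] * b[seq_len(n + d)])
  }, numeric(1)) / (na * nb)
  lags[which.max(cc)]
}

#' Pairwise synchrony lags between regions of interest
#'
#' Computes a frame-difference motion trace restricted to each ROI, baseline
#' corrects it, and estimates every pairwise delay as the lag maximizing the
#' normalized cross-correlation of the two traces. Lags are reported at frame
#' resolution (no sub-frame interpolation) in seconds, as an antisymmetric
#' matrix: \code{lag[i, j] > 0} means ROI j fires after ROI i.
#'
#' @param video a \linkS4class{VideoStack}.
#' @param rois list of at least two disjoint logical H x W masks.
#' @param lagMax maximal |lag| searched, s. Keep it below half the beat
#'   period so the periodic autocorrelation of regular beating cannot alias
#'   the estimate (default 0.5 s covers the hundreds-of-ms delays seen
#'   between immature cardiomyocyte clusters).
#' @return antisymmetric numeric matrix of lags, s.
#' @export
clusterSynchrony <- function(video, rois, lagMax = 0.5) {
  stopifnot(is(video, "VideoStack"))
  stopIfNot(is.list(rois) && length(rois) >= 2L,
            "need at least two ROIs")
  d <- dim(video@frames)
  for (i in seq_along(rois)) {
    m <- rois[[i]]
    stopIfNot(is.logical(m) && identical(dim(m), d[2:3]),
              sprintf("ROI %d is not a logical H x W mask", i))
    stopIfNot(any(m), sprintf("ROI %d is empty", i))
  }
  tot <- Reduce(`+`, lapply(rois, function(m) m + 0))
  stopIfNot(max(tot) <= 1, "ROIs must be disjoint")
  fr <- video@frames
  nT <- d[1]
  diffs <- abs(fr[-1L, , , drop = FALSE] - fr[-nT, , , drop = FALSE])
  dm <- matrix(diffs, nrow = nT - 1L)
  traces <- lapply(rois, function(m) {
    tr <- motionTrace(rowMeans(dm[, which(m), drop = FALSE]),
                      video@frameRate)
    traceValues(baselineCorrect(tr))
  })
  maxLagSamples <- max(1L, as.integer(floor(lagMax * video@frameRate)))
  k <- length(rois)
  lag <- matrix(0, k, k)
  nm <- names(rois)
  if (!is.null(nm)) dimnames(lag) <- list(nm, nm)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    s <- crossLagSamples(traces[[i]], traces[[j]], maxLagSamples)
    lag[i, j] <- s / video@frameRate
    lag[j, i] <- -lag[i, j]
  }
  lag
}
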