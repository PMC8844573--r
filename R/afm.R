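# Hertz spherical-indenter fitting of AFM approach force curves, the
# quality-control filters applied before pooling, and per-group aggregation.

#' Spherical probe geometry
#'
#' @slot radius probe radius, m.
#' @slot poisson Poisson's ratio of the sample (0 to 0.5).
#' @name ProbeSpec-class
#' @exportClass ProbeSpec
setClass("ProbeSpec",
  representation(radius = "numeric", poisson = "numeric"))

setValidity("ProbeSpec", function(object) {
  msg <- character()
  if (object@radius <= 0) msg <- c(msg, "radius must be > 0")
  if (object@poisson < 0 || object@poisson > 0.5)
    msg <- c(msg, "poisson must lie in [0, 0.5]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProbeSpec", function(object) {
  cat(sprintf("ProbeSpec: R = %.4g um, nu = %.2f\n",
              object@radius * 1e6, object@poisson))
})

#' Construct a ProbeSpec
#'
#' @param radius probe radius, m. The default is a 4.77 µm diameter silica
#'   colloid.
#' @param poisson Poisson's ratio (default 0.5, incompressible).
#' @return a validated \linkS4class{ProbeSpec}.
#' @export
probeSpec <- function(radius = 2.385e-6, poisson = 0.5) {
  new("ProbeSpec", radius = radius, poisson = poisson)
}

#' Hertz force for a spherical indenter
#'
#' F = 4 E sqrt(R) delta^(3/2) / (3 (1 - nu^2)): the contact force on an
#' elastic half-space of Young's modulus E indented to depth delta by a
#' sphere of radius R. Monotone increasing in both E and delta.
#'
#' @param E Young's modulus, Pa (> 0).
#' @param probe a \linkS4class{ProbeSpec}.
#' @param delta indentation depth(s), m (>= 0).
#' @return force, N (vectorized over delta).
#' @export
#' @examples
#' hertzForce(1000, probeSpec(), 5e-7)  # ~9.7e-10 N
hertzForce <- function(E, probe, delta) {
  stopifnot(is(probe, "ProbeSpec"))
  stopIfNot(length(E) == 1L && E > 0, "E must be a single positive value")
  stopIfNot(all(delta >= 0), "indentation depth must be >= 0")
  4 * E * sqrt(probe@radius) * delta^1.5 / (3 * (1 - probe@poisson^2))
}

#' Construct a HertzFit
#'
#' Mostly produced by [fitHertz()]; the constructor is exported so that QC
#' batches with known per-curve properties can be assembled programmatically
#' (e.g. when replaying fit tables from disk).
#'
#' @param youngsModulus E, Pa.
#' @param contactPoint fitted contact position, m.
#' @param baselineOffset fitted force offset, N.
#' @param rmsResidual residual RMS, N.
#' @param contactPointDeviation contact-point deviation, m.
#' @param accepted QC flag (NA until [qcFilter()] runs).
#' @param rejectReason QC reason string.
#' @param nPoints samples in the fitted range.
#' @param metadata grouping labels.
#' @return a validated \linkS4class{HertzFit}.
#' @export
hertzFit <- function(youngsModulus, contactPoint = NA_real_,
                     baselineOffset = 0, rmsResidual = 0,
                     contactPointDeviation = 0, accepted = NA,
                     rejectReason = "none", nPoints = 0L,
                     metadata = list()) {
  new("HertzFit", youngsModulus = youngsModulus, contactPoint = contactPoint,
      baselineOffset = baselineOffset, rmsResidual = rmsResidual,
      contactPointDeviation = contactPointDeviation, accepted = accepted,
      rejectReason = rejectReason, nPoints = as.integer(nPoints),
      metadata = metadata)
}

#' Estimate the contact point by sustained threshold crossing
#'
#' Fits a line to the pre-contact baseline (the first \code{baselineFraction}
#' of samples), subtracts it, and returns the position of the first sample
#' from which \code{m} consecutive detrended forces exceed \code{k} times the
#' baseline noise sd. Detrending makes the estimate invariant to constant
#' force offsets and linear baseline tilt.
#'
#' @param curve a \linkS4class{ForceCurve}.
#' @param k noise-sd multiplier of the crossing threshold (default 3).
#' @param m number of consecutive supra-threshold samples required
#'   (default 5).
#' @param baselineFraction fraction of the curve (from its start) treated as
#'   baseline for the noise estimate (default 0.4; must be pre-contact).
#' @return contact position, m. Errors when no baseline is available or no
#'   sustained rise exists (e.g. a pure-noise curve that never contacts).
#' @export
estimateContactPoint <- function(curve, k = 3, m = 5L,
                                 baselineFraction = 0.4) {
  stopifnot(is(curve, "ForceCurve"))
  pos <- curve@position; f <- curve@force
  n <- length(pos)
  nBase <- floor(n * baselineFraction)
  stopIfNot(nBase >= 10L,
            "no baseline detectable: fewer than 10 pre-contact samples")
  ib <- seq_len(nBase)
  fit <- stats::lm.fit(cbind(1, pos[ib]), f[ib])
  resid <- f - (fit$coefficients[1] + fit$coefficients[2] * pos)
  noiseSd <- stats::sd(resid[ib])
  # floor the threshold at a tiny fraction of the force range so that an
  # effectively noiseless baseline does not trigger on rounding error
  thr <- max(k * noiseSd, 1e-6 * diff(range(f)))
  above <- resid > thr
  # first index starting a run of >= m consecutive supra-threshold samples
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= m) return(pos[i - m + 1L])
  }
  stop("no sustained force rise above baseline noise: contact not detectable",
       call. = FALSE)
}

# linear profile fit at fixed contact point: force ~ offset + A * delta^1.5
profileFit <- function(pos, f, cp) {
  x <- pmax(pos - cp, 0)^1.5
  fit <- stats::lm.fit(cbind(1, x), f)
  rss <- sum(fit$residuals^2)
  list(offset = fit$coefficients[1], A = fit$coefficients[2], rss = rss,
       residuals = fit$residuals)
}

#' Fit the Hertz spherical-indenter model to an approach curve
#'
#' Least squares over (E, contact point, baseline offset) with the
#' indentation defined as max(position - contact point, 0): for each
#' candidate contact point the offset and the Hertz prefactor are solved
#' linearly (so pre-contact samples inform only the offset), and the contact
#' point minimizing the residual sum of squares is located by a coarse grid
#' followed by golden-section refinement. The residual RMS is evaluated over
#' the post-contact (fitted) range, and the contact-point deviation is the
#' absolute difference between the least-squares contact point and the
#' threshold-crossing estimate of [estimateContactPoint()].
#'
#' A curve with no detectable contact or a non-positive fitted prefactor
#' yields an unfit result (\code{youngsModulus} NA, \code{accepted} FALSE,
#' reason \code{"unfit"}); fits that converge are returned with
#' \code{accepted = NA} pending [qcFilter()].
#'
#' @param curve a \linkS4class{ForceCurve}.
#' @param probe a \linkS4class{ProbeSpec}.
#' @param nGrid coarse grid size for the contact-point search.
#' @return a \linkS4class{HertzFit}.
#' @export
#' @examples
#' fc <- simulateForceCurve(curveSpec(eTrue = 1000))
#' fitHertz(fc, probeSpec())
fitHertz <- function(curve, probe, nGrid = 41L) {
  stopifnot(is(curve, "ForceCurve"), is(probe, "ProbeSpec"))
  pos <- curve@position; f <- curve@force
  n <- length(pos)
  unfit <- function() new("HertzFit",
    youngsModulus = NA_real_, contactPoint = NA_real_,
    baselineOffset = NA_real_, rmsResidual = NA_real_,
    contactPointDeviation = NA_real_, accepted = FALSE,
    rejectReason = "unfit", nPoints = 0L, metadata = curve@metadata)

  cpEst <- tryCatch(estimateContactPoint(curve), error = function(e) NULL)
  if (is.null(cpEst)) return(unfit())

  # coarse grid over candidate contact points, keep >= 10 post-contact samples
  lo <- pos[1]
  hi <- pos[max(1L, n - 10L)]
  grid <- seq(lo, hi, length.out = nGrid)
  rssGrid <- vapply(grid, function(cp) profileFit(pos, f, cp)$rss, numeric(1))
  iBest <- which.min(rssGrid)
  lo2 <- grid[max(1L, iBest - 1L)]
  hi2 <- grid[min(nGrid, iBest + 1L)]
  opt <- stats::optimize(function(cp) profileFit(pos, f, cp)$rss,
                         interval = c(lo2, hi2),
                         tol = (pos[2] - pos[1]) / 100)
  cpFit <- opt$minimum
  pf <- profileFit(pos, f, cpFit)
  if (!is.finite(pf$A) || pf$A <= 0) return(unfit())

  E <- pf$A * 3 * (1 - probe@poisson^2) / (4 * sqrt(probe@radius))
  post <- pos > cpFit
  if (sum(post) < 2L) return(unfit())
  rms <- sqrt(mean(pf$residuals[post]^2))
  new("HertzFit",
      youngsModulus = E, contactPoint = cpFit, baselineOffset = pf$offset,
      rmsResidual = rms, contactPointDeviation = abs(cpFit - cpEst),
      accepted = NA, rejectReason = "none", nPoints = as.integer(sum(post)),
      metadata = curve@metadata)
}

#' Quality-filter Hertz fits
#'
#' Applies the curve-selection criteria in order: residual RMS strictly below
#' \code{rmsMax}, contact-point deviation strictly below \code{cpDevMax},
#' Young's modulus strictly inside \code{eRange}. Each rejected fit is tagged
#' with the first criterion it fails; unfit curves stay rejected as
#' \code{"unfit"}. The rejection tally always sums to the input size.
#'
#' @param fits list of \linkS4class{HertzFit} (non-empty).
#' @param rmsMax residual RMS bound, N (default 25 pN).
#' @param cpDevMax contact-point deviation bound, m (default 100 nm).
#' @param eRange modulus range, Pa (default c(1e2, 1e4)).
#' @return list with \code{accepted} and \code{rejected} (lists of updated
#'   fits) and \code{tally}, a named integer vector over
#'   c("accepted", "rms", "contact_dev", "e_range", "unfit").
#' @export
qcFilter <- function(fits, rmsMax = 25e-12, cpDevMax = 100e-9,
                     eRange = c(1e2, 1e4)) {
  if (is(fits, "HertzFit")) fits <- list(fits)
  stopIfNot(length(fits) >= 1L, "qcFilter needs at least one fit")
  stopifnot(all(vapply(fits, is, logical(1), "HertzFit")))
  out <- lapply(fits, function(ft) {
    if (ft@rejectReason == "unfit") return(ft)
    reason <-
      if (!(ft@rmsResidual < rmsMax)) "rms"
      else if (!(ft@contactPointDeviation < cpDevMax)) "contact_dev"
      else if (!(ft@youngsModulus > eRange[1] &&
                 ft@youngsModulus < eRange[2])) "e_range"
      else "none"
    ft@accepted <- reason == "none"
    ft@rejectReason <- reason
    ft
  })
  reasons <- vapply(out, rejectReason, character(1))
  tally <- c(accepted = sum(reasons == "none"),
             rms = sum(reasons == "rms"),
             contact_dev = sum(reasons == "contact_dev"),
             e_range = sum(reasons == "e_range"),
             unfit = sum(reasons == "unfit"))
  list(accepted = out[reasons == "none"],
       rejected = out[reasons != "none"],
       tally = tally)
}

#' Construct a one-row group elasticity summary
#'
#' Used both for aggregation output and to enter published group means (e.g.
#' from a different method) for cross-method comparison.
#'
#' @param label group label (e.g. "iCM" or "CPC/control/AFM").
#' @param meanE mean Young's modulus, Pa.
#' @param semE standard error of the mean, Pa (NA when n < 2).
#' @param n number of measurements.
#' @return one-row data.frame with columns label, meanE, semE, n.
#' @export
groupSummary <- function(label, meanE, semE = NA_real_, n = 1L) {
  stopIfNot(n >= 1L, "n must be >= 1")
  data.frame(label = label, meanE = meanE, semE = semE, n = as.integer(n))
}

#' Aggregate accepted fits into per-group summaries
#'
#' Mean, SEM and n of the Young's modulus per group, where a group is the
#' combination of the requested metadata keys (e.g. cell type x treatment).
#' Groups listed in \code{expected} but absent from the data are reported
#' with n = 0 and NA statistics rather than dropped.
#'
#' @param fits list of accepted \linkS4class{HertzFit} objects.
#' @param grouping metadata keys defining the groups (default "cellType").
#' @param expected optional character vector of group labels that must appear
#'   in the output even when empty.
#' @return data.frame with columns label, the grouping keys, meanE, semE, n.
#' @export
aggregateElasticity <- function(fits, grouping = "cellType",
                                expected = NULL) {
  if (is(fits, "HertzFit")) fits <- list(fits)
  stopIfNot(length(fits) >= 1L, "aggregateElasticity needs at least one fit")
  md <- lapply(fits, curveMetadata)
  for (key in grouping) {
    has <- vapply(md, function(x) !is.null(x[[key]]), logical(1))
    if (!all(has))
      stop(sprintf("unknown group key '%s' (missing from %d fit(s))",
                   key, sum(!has)), call. = FALSE)
  }
  tab <- data.frame(E = vapply(fits, youngsModulus, numeric(1)))
  if (length(grouping)) {
    keys <- do.call(rbind.data.frame, lapply(md, function(x) x[grouping]))
    names(keys) <- grouping
    tab <- cbind(tab, keys)
    tab$label <- do.call(paste, c(tab[grouping], sep = "/"))
  } else {
    tab$label <- "all"
  }
  agg <- do.call(rbind, lapply(split(tab, tab$label), function(g) {
    cbind(groupSummary(g$label[1], mean(g$E), semOf(g$E), nrow(g)),
          g[1, grouping, drop = FALSE])
  }))
  rownames(agg) <- NULL
  if (!is.null(expected)) {
    missing <- setdiff(expected, agg$label)
    for (lab in missing) {
      row <- agg[NA_integer_, , drop = FALSE]
      row$label <- lab; row$n <- 0L
      agg <- rbind(agg, row)
    }
    rownames(agg) <- NULL
  }
  agg
}

#' Absolute difference of group means between two methods
#'
#' Compares the mean Young's modulus of the same cell type measured by two
#' methods (e.g. AFM on adherent cells vs deformability cytometry in
#' suspension); labels must match.
#'
#' @param summaryA,summaryB one-row summaries from [groupSummary()] or rows
#'   of [aggregateElasticity()] output.
#' @return |meanE(A) - meanE(B)|, Pa.
#' @export
#' @examples
#' methodDifference(groupSummary("iCM", 1030), groupSummary("iCM", 950))
methodDifference <- function(summaryA, summaryB) {
  stopIfNot(nrow(summaryA) == 1L && nrow(summaryB) == 1L,
            "methodDifference compares two one-row summaries")
  stopIfNot(identical(summaryA$label, summaryB$label),
            sprintf("group labels differ: '%s' vs '%s'",
                    summaryA$label, summaryB$label))
  abs(summaryA$meanE - summaryB$meanE)
}
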