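# File formats: multi-page TIFF for videos/images/maps, two-column TSV with
# '#' metadata headers for force curves, CSV for tables.

#' Write / read a video as a multi-page TIFF
#'
#' Intensities are stored as 16-bit samples scaled by the video's bit scale;
#' analysis happens on floating point and quantization occurs only on
#' export. Frame rate, pixel size and bit scale are not TIFF-portable here,
#' so they are supplied again on reading.
#'
#' @param video a \linkS4class{VideoStack}.
#' @param path output .tif path.
#' @return \code{writeVideoTiff}: invisibly, the path.
#' @export
writeVideoTiff <- function(video, path) {
  stopifnot(is(video, "VideoStack"))
  fr <- video@frames
  pages <- lapply(seq_len(dim(fr)[1]), function(k) {
    m <- fr[k, , ] / video@bitScale
    m[m < 0] <- 0; m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeVideoTiff
#' @param frameRate frames per second of the recording.
#' @param bitScale intensity scale the samples map back to.
#' @param pixelSize µm per pixel (optional).
#' @return \code{readVideoTiff}: a \linkS4class{VideoStack}.
#' @export
readVideoTiff <- function(path, frameRate, bitScale = 255,
                          pixelSize = NA_real_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  fr <- array(0, dim = c(length(pages), H, W))
  for (k in seq_along(pages)) fr[k, , ] <- pages[[k]] * bitScale
  videoStack(fr, frameRate, pixelSize = pixelSize, bitScale = bitScale)
}

#' Write / read a single grayscale image as TIFF
#'
#' @param image numeric matrix (intensities in [0, bitScale]).
#' @param path .tif path.
#' @param bitScale intensity scale (default 255).
#' @return \code{writeImageTiff}: invisibly, the path;
#'   \code{readImageTiff}: a numeric matrix on the bitScale scale.
#' @export
writeImageTiff <- function(image, path, bitScale = 255) {
  m <- image / bitScale
  m[m < 0] <- 0; m[m > 1] <- 1
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeImageTiff
#' @export
readImageTiff <- function(path, bitScale = 255) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m * bitScale
}

#' Write / read a force curve as two-column TSV
#'
#' Plain-text exchange format: '#'-prefixed header lines carry metadata as
#' \code{# key: value} (keys such as cell_type, treatment, replicate,
#' probe_radius_m, mode), followed by a tab-separated table of position (m)
#' and force (N).
#'
#' @param curve a \linkS4class{ForceCurve}.
#' @param path output .tsv path.
#' @return \code{writeForceCurveTsv}: invisibly, the path.
#' @export
writeForceCurveTsv <- function(curve, path) {
  stopifnot(is(curve, "ForceCurve"))
  md <- curve@metadata
  hdr <- vapply(names(md), function(k)
    sprintf("# %s: %s", k, format(md[[k]], digits = 15)), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, "# position_m\tforce_N"), con)
  utils::write.table(
    data.frame(position = format(curve@position, digits = 15),
               force = format(curve@force, digits = 15)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeForceCurveTsv
#' @export
readForceCurveTsv <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#")]
  md <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) {
      val <- m[3]
      num <- suppressWarnings(as.numeric(val))
      md[[trimws(m[2])]] <- if (!is.na(num)) num else val
    }
  }
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("position", "force"))
  forceCurve(tab$position, tab$force, metadata = md)
}
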