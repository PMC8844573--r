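# Assembly of the end-to-end pipeline report from the per-module outputs.

reportSections <- c("contractility", "elasticity", "methodDifferences",
                    "imaging", "qc")

#' Assemble the pipeline report
#'
#' Writes one CSV per analysis section plus a markdown summary that states,
#' for each of the five sections (contractility, elasticity,
#' methodDifferences, imaging, qc), whether it is present and how many rows
#' it carries. Sections not supplied are marked absent rather than silently
#' dropped, and rerunning with identical inputs reproduces the numeric
#' tables byte for byte.
#'
#' @param sections named list; any subset of \code{contractility},
#'   \code{elasticity}, \code{methodDifferences}, \code{imaging} (each a
#'   data.frame) and \code{qc} (a named numeric tally). At least one must be
#'   present.
#' @param dir output directory (created if needed).
#' @param provenance optional named character vector mapping section names
#'   to the input files they came from; logged in the summary.
#' @return invisibly, the paths written.
#' @export
buildReport <- function(sections, dir, provenance = NULL) {
  stopIfNot(is.list(sections) && length(sections) >= 1L,
            "buildReport needs at least one analysis output")
  unknown <- setdiff(names(sections), reportSections)
  stopIfNot(length(unknown) == 0L,
            paste("unknown section(s):", paste(unknown, collapse = ", ")))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  lines <- c("# Pipeline report", "")
  for (sec in reportSections) {
    x <- sections[[sec]]
    if (is.null(x)) {
      lines <- c(lines, sprintf("- %s: absent", sec))
      next
    }
    path <- file.path(dir, paste0(sec, ".csv"))
    if (is.data.frame(x)) {
      utils::write.csv(x, path, row.names = FALSE)
      lines <- c(lines, sprintf("- %s: %d row(s) -> %s", sec, nrow(x),
                                basename(path)))
    } else {
      utils::write.csv(data.frame(key = names(x), value = as.numeric(x)),
                       path, row.names = FALSE)
      lines <- c(lines, sprintf("- %s: %d value(s) -> %s", sec, length(x),
                                basename(path)))
    }
    if (!is.null(provenance) && sec %in% names(provenance))
      lines <- c(lines, sprintf("  - input: %s", provenance[[sec]]))
    written <- c(written, path)
  }
  summaryPath <- file.path(dir, "summary.md")
  writeLines(lines, summaryPath)
  invisible(c(written, summaryPath))
}
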