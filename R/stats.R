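# Comparison statistics reported around the pipeline: two-group Student's t
# test and one-way ANOVA followed by Tukey's HSD, with the usual
# significance-star convention.

starsFor <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "n.s."
}

#' Two-group Student's t test
#'
#' Two-sided, equal-variance by default (set \code{welch = TRUE} for the
#' Welch correction). Swapping the groups flips the sign of t and leaves p
#' unchanged.
#'
#' @param groupA,groupB numeric vectors, each with at least 2 values.
#' @param labels group labels, length 2.
#' @param welch use the Welch (unequal variance) variant.
#' @return a \linkS4class{ComparisonResult}.
#' @export
#' @examples
#' tTestGroups(rnorm(8), rnorm(8) + 10)
tTestGroups <- function(groupA, groupB, labels = c("A", "B"),
                        welch = FALSE) {
  stopIfNot(length(groupA) >= 2L && length(groupB) >= 2L,
            "each group needs at least 2 values")
  ht <- stats::t.test(groupA, groupB, var.equal = !welch)
  p <- unname(ht$p.value)
  new("ComparisonResult",
      test = if (welch) "Welch t test" else "Student's t test",
      groups = labels, statistic = unname(ht$statistic), pValue = p,
      pairwise = data.frame(), stars = starsFor(p))
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Global F test across three or more groups followed by Tukey's honest
#' significant difference for every pair, with family-wise adjusted p
#' values. For two groups use [tTestGroups()].
#'
#' @param groups named list of at least 3 numeric vectors, each with at
#'   least 2 values.
#' @return a \linkS4class{ComparisonResult}; the pairwise table has columns
#'   \code{comparison}, \code{diff}, \code{lwr}, \code{upr}, \code{pAdj}
#'   and \code{stars}.
#' @export
#' @examples
#' anovaTukey(list(a = rnorm(6), b = rnorm(6), c = rnorm(6) + 5))
anovaTukey <- function(groups) {
  stopIfNot(is.list(groups) && length(groups) >= 3L,
            "need at least 3 groups (use tTestGroups for 2)")
  stopIfNot(all(vapply(groups, length, integer(1)) >= 2L),
            "each group needs at least 2 values")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)))
  fit <- stats::aov(value ~ group, data = df)
  sm <- summary(fit)[[1]]
  fStat <- sm[["F value"]][1]
  p <- sm[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$group
  pw <- data.frame(
    comparison = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
    upr = tk[, "upr"], pAdj = tk[, "p adj"],
    stars = vapply(tk[, "p adj"], starsFor, character(1)),
    row.names = NULL)
  new("ComparisonResult", test = "one-way ANOVA + Tukey HSD",
      groups = names(groups), statistic = fStat, pValue = p,
      pairwise = pw, stars = starsFor(p))
}
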