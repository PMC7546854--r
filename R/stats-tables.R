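#' Cross-tabulation of two margin-assessment methods with LTP status
#'
#' Builds the 2 x 2 x 2 count array (reference-method margin group x
#' comparison-method margin group x LTP status) from the printed layout:
#' one row per reference group, columns (comparison <= 5 mm: LTP, non-LTP;
#' comparison > 5 mm: LTP, non-LTP).
#'
#' @param counts 2 x 4 numeric matrix in the printed layout
#' @return a 2 x 2 x 2 array with dimnames (dir, conv, ltp)
#' @export
makeCrossTab <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 2L, ncol(counts) == 4L, all(counts >= 0))
  ct <- array(0, c(2, 2, 2),
              dimnames = list(dir = c("le5", "gt5"), conv = c("le5", "gt5"),
                              ltp = c("ltp", "non")))
  ct[, 1, 1] <- counts[, 1]; ct[, 1, 2] <- counts[, 2]
  ct[, 2, 1] <- counts[, 3]; ct[, 2, 2] <- counts[, 4]
  ct
}

oddsRatio <- function(ltpA, nonA, ltpB, nonB) {
  cells <- c(ltpA, nonA, ltpB, nonB)
  if (any(cells == 0)) cells <- cells + 0.5  # Haldane-Anscombe correction
  (cells[1] / cells[2]) / (cells[3] / cells[4])
}

#' Summaries of a method-comparison cross-tabulation
#'
#' Marginal group sizes per method, LTP counts per group, the overall LTP
#' proportion, between-method agreement, and the odds ratio of LTP for the
#' <= 5 mm group under each method (Haldane correction for zero cells).
#'
#' @param ct a 2 x 2 x 2 array from \code{\link{makeCrossTab}}
#' @return list of summaries
#' @export
crosstabSummaries <- function(ct) {
  stopifnot(length(dim(ct)) == 3L, all(dim(ct) == 2L), all(ct >= 0))
  total <- sum(ct)
  dirN <- apply(ct, 1, sum)
  convN <- apply(ct, 2, sum)
  ltpByDir <- apply(ct[, , 1, drop = FALSE], 1, sum)
  ltpByConv <- apply(ct[, , 1, drop = FALSE], 2, sum)
  ltpTotal <- sum(ct[, , 1])
  agreement <- sum(ct[1, 1, ]) + sum(ct[2, 2, ])
  list(total = total,
       dirN = dirN, convN = convN,
       ltpByDir = ltpByDir, ltpByConv = ltpByConv,
       ltpTotal = ltpTotal,
       ltpProportion = ltpTotal / total,
       agreement = agreement,
       agreementProportion = agreement / total,
       orDir = oddsRatio(ltpByDir[1], dirN[1] - ltpByDir[1],
                         ltpByDir[2], dirN[2] - ltpByDir[2]),
       orConv = oddsRatio(ltpByConv[1], convN[1] - ltpByConv[1],
                          ltpByConv[2], convN[2] - ltpByConv[2]))
}

#' Two-group comparison with the conventional test choice
#'
#' Continuous variables: Mann-Whitney U with normal approximation and tie
#' correction. Categorical variables: Pearson chi-square when every expected
#' cell count is at least 5 (Cochran's rule), Fisher's exact test otherwise.
#'
#' @param x values (numeric) or categories
#' @param group two-level grouping
#' @param type "auto" treats numeric input with more than two distinct
#'   values as continuous; force with "continuous"/"categorical"
#' @return list with \code{p}, \code{method} and (where defined)
#'   \code{statistic}
#' @export
groupCompare <- function(x, group, type = c("auto", "continuous", "categorical")) {
  type <- match.arg(type)
  g <- factor(group)
  if (nlevels(g) != 2L) stop("validation error: exactly two groups required")
  if (any(tabulate(g) < 1L)) stop("validation error: empty group")
  if (type == "auto")
    type <- if (is.numeric(x) && length(unique(x)) > 2L) "continuous"
            else "categorical"
  if (type == "continuous") {
    wt <- stats::wilcox.test(x ~ g, exact = FALSE)
    list(p = wt$p.value, method = "mann-whitney",
         statistic = unname(wt$statistic))
  } else {
    tab <- table(factor(x), g)
    expected <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$expected)
    if (any(expected < 5)) {
      list(p = stats::fisher.test(tab)$p.value, method = "fisher",
           statistic = NA_real_)
    } else {
      cs <- stats::chisq.test(tab, correct = FALSE)
      list(p = cs$p.value, method = "chi-square",
           statistic = unname(cs$statistic))
    }
  }
}
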