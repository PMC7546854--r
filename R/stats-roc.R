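#' DeLong comparison of two correlated ROC AUCs
#'
#' AUC via the Mann-Whitney identity (ties counted 1/2); the variance and
#' covariance of the paired AUCs from the DeLong structural components
#' (per-case placement values); two-sided normal test on the difference.
#' A degenerate zero-variance difference with equal AUCs reports p = 1.
#'
#' @param outcome 0/1 outcome vector (both classes must be present)
#' @param score1,score2 paired predictor scores
#' @return list with \code{auc1}, \code{auc2}, \code{diff}, \code{z},
#'   \code{p}
#' @export
delongCompare <- function(outcome, score1, score2) {
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary 0/1")
  pos <- outcome == 1
  m <- sum(pos); n <- sum(!pos)
  if (m < 1L || n < 1L)
    stop("validation error: both outcome classes must be present")
  if (length(score1) != length(outcome) || length(score2) != length(outcome))
    stop("scores must be paired with the outcome")

  placements <- function(s) {
    x <- s[pos]; y <- s[!pos]
    psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
    list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
  }
  p1 <- placements(score1)
  p2 <- placements(score2)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  S <- s10 / m + s01 / n
  vdiff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- p1$auc - p2$auc
  if (vdiff < 1e-14) {
    z <- if (abs(d) < 1e-14) 0 else sign(d) * Inf
  } else z <- d / sqrt(vdiff)
  p <- 2 * stats::pnorm(-abs(z))
  list(auc1 = p1$auc, auc2 = p2$auc, diff = d, z = z, p = p,
       varDiff = vdiff, nPos = m, nNeg = n)
}

#' Binary LTP status at a horizon
#'
#' Patients are evaluable at the horizon if they had the event by then or
#' were followed at least that long; events after the horizon count as
#' horizon-negative.
#'
#' @param cohort a cohort data.frame
#' @param horizonMonths the horizon (default 24 months)
#' @return list with \code{status} (0/1) and \code{eligible} (logical)
#' @export
ltpStatusAtHorizon <- function(cohort, horizonMonths = 24) {
  eligible <- cohort$months >= horizonMonths | cohort$ltp_event == 1
  status <- as.integer(cohort$ltp_event == 1 & cohort$months <= horizonMonths)
  list(status = status, eligible = eligible)
}
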