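#' Full cohort statistics report
#'
#' The statistical layer applied to one cohort table: per-margin-group
#' Kaplan-Meier cumulative LTP rates at the requested horizons, the
#' two-group log-rank test, univariate Cox hazard ratios for every
#' candidate factor, the forward-stepwise multivariate Cox model, and —
#' when a conventional-registration margin column is present — the
#' method-comparison cross-tabulation and the DeLong comparison of the two
#' margin groupings as predictors of horizon LTP status.
#'
#' @param cohort a cohort data.frame (see \code{\link{makeCohort}})
#' @param horizons months at which cumulative LTP rates are reported
#' @param covariates candidate risk factors for the Cox models
#' @param aucHorizon horizon for the DeLong ROC comparison (months)
#' @return a nested list report
#' @export
cohortStats <- function(cohort, horizons = c(6, 12, 24),
                        covariates = c("sex", "age_ge65", "comorbidity",
                                       "cirrhosis", "afp_gt200", "size_3to5",
                                       "abutting_vessel", "margin_le5"),
                        aucHorizon = 24) {
  covariates <- intersect(covariates, names(cohort))
  validateCohort(cohort, covariates)
  if (any(diff(horizons) <= 0)) stop("horizons must be strictly increasing")

  grp <- cohort$margin_le5
  kmA <- kmEstimate(cohort$months[grp == 1], cohort$ltp_event[grp == 1])
  kmB <- kmEstimate(cohort$months[grp == 0], cohort$ltp_event[grp == 0])
  ltpRates <- data.frame(horizon = horizons,
                         groupA = kmA$cumLTPAt(horizons),
                         groupB = kmB$cumLTPAt(horizons))
  lr <- logrankTest(grp, cohort$months, cohort$ltp_event)

  uni <- do.call(rbind, lapply(covariates, function(cv) {
    fit <- suppressWarnings(coxFit(cohort, cv))
    fit$table
  }))
  multi <- suppressWarnings(coxFit(cohort, covariates, forwardStepwise = TRUE))

  out <- list(n = nrow(cohort), nEvents = sum(cohort$ltp_event),
              ltpRates = ltpRates, logrank = lr, univariate = uni,
              multivariate = multi[c("table", "selected", "converged")])

  if ("margin_le5_conv" %in% names(cohort)) {
    counts <- matrix(0, 2, 4)
    for (i in 1:2) {
      d <- if (i == 1) 1 else 0
      counts[i, ] <- c(sum(grp == d & cohort$margin_le5_conv == 1 & cohort$ltp_event == 1),
                       sum(grp == d & cohort$margin_le5_conv == 1 & cohort$ltp_event == 0),
                       sum(grp == d & cohort$margin_le5_conv == 0 & cohort$ltp_event == 1),
                       sum(grp == d & cohort$margin_le5_conv == 0 & cohort$ltp_event == 0))
    }
    out$crosstab <- crosstabSummaries(makeCrossTab(counts))
    st <- ltpStatusAtHorizon(cohort, aucHorizon)
    el <- st$eligible
    if (sum(st$status[el]) > 0 && sum(st$status[el] == 0) > 0) {
      out$aucComparison <- delongCompare(st$status[el],
                                         cohort$margin_le5[el],
                                         cohort$margin_le5_conv[el])
    }
  }
  out
}
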