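# Survival layer: product-limit estimation, two-group log-rank, and Cox
# proportional-hazards fitting with optional forward-stepwise selection.
# The estimators are delegated to the survival package; this layer owns the
# interface contracts, the LTP-incidence scale, and the stepwise procedure.

#' Kaplan-Meier estimate of LTP-free probability
#'
#' Product-limit estimator with right censoring; the cumulative LTP rate at
#' each time is reported as 1 - S(t) (incidence scale).
#'
#' @param times nonnegative follow-up times (months)
#' @param events 0/1 event flags
#' @return list with a step \code{table} (time, nRisk, nEvent, nCensor,
#'   survival, cumLTP) and \code{survivalAt(t)} / \code{cumLTPAt(t)} lookup
#'   functions
#' @export
kmEstimate <- function(times, events) {
  if (length(times) < 1L) stop("validation error: no observations")
  if (any(times < 0)) stop("validation error: negative time")
  if (!all(events %in% c(0, 1))) stop("validation error: events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  tab <- data.frame(time = fit$time, nRisk = fit$n.risk, nEvent = fit$n.event,
                    nCensor = fit$n.censor, survival = fit$surv,
                    cumLTP = 1 - fit$surv)
  survivalAt <- function(t) {
    vapply(t, function(ti) {
      i <- which(tab$time <= ti)
      if (length(i)) tab$survival[max(i)] else 1
    }, 0)
  }
  list(table = tab, survivalAt = survivalAt,
       cumLTPAt = function(t) 1 - survivalAt(t), n = length(times))
}

#' Two-group log-rank test
#'
#' @param groups two-level group labels
#' @param times,events as in \code{\link{kmEstimate}}
#' @return list with \code{statistic} (chi-square, 1 df) and \code{p}
#' @export
logrankTest <- function(groups, times, events) {
  g <- factor(groups)
  if (nlevels(g) != 2L)
    stop("validation error: exactly two groups are required")
  if (any(tabulate(g) < 1L)) stop("validation error: empty group")
  if (any(times < 0)) stop("validation error: negative time")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  stat <- sd$chisq
  list(statistic = stat, df = 1L, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# likelihood-ratio p-value for adding `cand` to the model with `current`
coxLRTp <- function(cohort, current, cand) {
  f1 <- stats::as.formula(paste("survival::Surv(months, ltp_event) ~",
                                paste(c(current, cand), collapse = " + ")))
  fit1 <- survival::coxph(f1, data = cohort, ties = "efron")
  ll1 <- fit1$loglik[2]
  ll0 <- if (length(current)) {
    f0 <- stats::as.formula(paste("survival::Surv(months, ltp_event) ~",
                                  paste(current, collapse = " + ")))
    survival::coxph(f0, data = cohort, ties = "efron")$loglik[2]
  } else fit1$loglik[1]
  stats::pchisq(2 * (ll1 - ll0), df = 1, lower.tail = FALSE)
}

#' Cox proportional-hazards fit with optional forward-stepwise selection
#'
#' Partial-likelihood maximisation with Efron handling of tied event times.
#' Forward selection repeatedly adds the candidate with the smallest
#' likelihood-ratio p-value while it is below \code{alphaEnter} (pure
#' forward, no removal step). Monotone-likelihood / separation problems are
#' flagged via \code{converged}, never returned silently.
#'
#' @param cohort a cohort data.frame (see \code{\link{validateCohort}})
#' @param covariates binary-coded candidate covariate columns
#' @param forwardStepwise select covariates by forward LRT steps
#' @param alphaEnter entry threshold (default 0.05)
#' @return list with \code{table} (covariate, coef, HR, lower/upper 95\% CI,
#'   p), \code{selected}, \code{converged}, \code{nEvents}, \code{model}
#' @export
coxFit <- function(cohort, covariates, forwardStepwise = FALSE,
                   alphaEnter = 0.05) {
  validateCohort(cohort, covariates)
  nEvents <- sum(cohort$ltp_event)
  if (nEvents < 2L)
    stop("validation error: at least 2 events are required (got ", nEvents, ")")

  selected <- covariates
  if (forwardStepwise) {
    selected <- character(0)
    remaining <- covariates
    while (length(remaining)) {
      ps <- vapply(remaining, function(cv)
        suppressWarnings(coxLRTp(cohort, selected, cv)), 0)
      if (min(ps) >= alphaEnter) break
      pick <- remaining[which.min(ps)]
      selected <- c(selected, pick)
      remaining <- setdiff(remaining, pick)
    }
    if (!length(selected))
      return(list(table = data.frame(), selected = character(0),
                  converged = TRUE, nEvents = nEvents, model = NULL))
  }

  f <- stats::as.formula(paste("survival::Surv(months, ltp_event) ~",
                               paste(selected, collapse = " + ")))
  warns <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(f, data = cohort, ties = "efron"),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  converged <- !any(grepl("converge|infinite|singular", warns,
                          ignore.case = TRUE)) &&
    all(abs(stats::coef(fit)) < 15)
  if (!converged)
    warning("Cox fit did not converge cleanly (possible monotone likelihood);",
            " estimates are flagged, inspect the data")
  s <- summary(fit)
  tab <- data.frame(covariate = rownames(s$coefficients),
                    coef = s$coefficients[, "coef"],
                    HR = s$conf.int[, "exp(coef)"],
                    lower95 = s$conf.int[, "lower .95"],
                    upper95 = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  list(table = tab, selected = selected, converged = converged,
       nEvents = nEvents, model = fit)
}
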