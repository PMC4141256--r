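# Survival-analysis layer: Kaplan-Meier, log-rank, univariate/multivariate
# and stratified Cox proportional hazards. Fitting goes through the
# 'survival' package (survfit/survdiff/coxph, Efron ties by default); this
# layer standardizes inputs and returns tidy tables mirroring the usual
# HR / 95% CI / p reporting.

.survObj <- function(time, event) {
  if (any(time <= 0)) stop("survival times must be > 0")
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
  survival::Surv(time, event)
}

#' Kaplan-Meier estimate per group
#'
#' Product-limit estimator with right censoring, via
#' \code{survival::survfit}.
#'
#' @param time follow-up times (> 0).
#' @param event 0/1 indicators.
#' @param group optional grouping factor; a single curve when NULL.
#' @return data.frame: group, time, nRisk, nEvent, nCensor, surv.
#' @export
kmEstimate <- function(time, event, group = NULL) {
  srv <- .survObj(time, event)
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.factor(group)
  if (any(table(group) == 0)) stop("empty group")
  fit <- survival::survfit(srv ~ g, data = data.frame(g = group))
  strata <- if (is.null(fit$strata)) {
    rep(levels(group)[1L], length(fit$time))
  } else {
    rep(sub("^g=", "", names(fit$strata)), fit$strata)
  }
  data.frame(group = strata, time = fit$time, nRisk = fit$n.risk,
             nEvent = fit$n.event, nCensor = fit$n.censor, surv = fit$surv,
             row.names = NULL)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square (1 df for two groups) with hypergeometric
#' variance at each event time, via \code{survival::survdiff}.
#'
#' @inheritParams kmEstimate
#' @param group two-level grouping.
#' @return list: chisq, df, p, observed, expected (per group).
#' @export
logrankTest <- function(time, event, group) {
  srv <- .survObj(time, event)
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2L) stop("need two non-empty groups")
  sd_ <- survival::survdiff(srv ~ g, data = data.frame(g = group))
  df <- length(sd_$n) - 1L
  list(chisq = unname(sd_$chisq), df = df,
       p = pchisq(sd_$chisq, df, lower.tail = FALSE),
       observed = unname(sd_$obs), expected = unname(sd_$exp))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood over the supplied covariates
#' (jointly, so a single column gives the univariate fit) and reports the
#' usual table: beta, SE from the observed information, Wald Z, HR =
#' exp(beta), 95\% CI and two-sided p. Non-convergence and monotone
#' likelihood (complete separation) are surfaced through the
#' \code{converged} and \code{warnings} attributes, never silently.
#'
#' @param time,event follow-up and 0/1 indicators.
#' @param covariates data.frame of covariates (numeric or factor), one row
#'   per patient.
#' @param tiesMethod "efron" (default) or "breslow".
#' @return data.frame (one row per model term): covariate, beta, se, z,
#'   HR, ciLow, ciHigh, p. Attributes: n, nevent, scoreTest (chi-square of
#'   the score test), logLik, converged, warnings, tiesMethod.
#' @export
coxFit <- function(time, event, covariates,
                   tiesMethod = c("efron", "breslow")) {
  tiesMethod <- match.arg(tiesMethod)
  covariates <- as.data.frame(covariates)
  if (sum(event) < 1) stop("need at least one event")
  const <- vapply(covariates, function(x) length(unique(x)) < 2L, logical(1))
  if (any(const)) {
    stop("constant covariate(s): ",
         paste(colnames(covariates)[const], collapse = ", "))
  }
  srv <- .survObj(time, event)
  warns <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(srv ~ ., data = covariates, ties = tiesMethod),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  out <- data.frame(covariate = rownames(co), beta = co[, "coef"],
                    se = co[, "se(coef)"], z = co[, "z"],
                    HR = exp(co[, "coef"]),
                    ciLow = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                    ciHigh = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                    p = co[, "Pr(>|z|)"], row.names = NULL)
  diverged <- any(grepl("converge|infinite|beta may be infinite", warns,
                        ignore.case = TRUE))
  if (diverged) {
    warning("Cox fit did not converge cleanly (possible monotone ",
            "likelihood); inspect attr(, 'warnings')")
  }
  attr(out, "n") <- sm$n
  attr(out, "nevent") <- sm$nevent
  attr(out, "scoreTest") <- unname(sm$sctest["test"])
  attr(out, "logLik") <- unname(fit$loglik[2L])
  attr(out, "converged") <- !diverged
  attr(out, "warnings") <- warns
  attr(out, "tiesMethod") <- tiesMethod
  out
}

#' Univariate Cox fit of risk group on a cohort
#'
#' Convenience wrapper: Cox PH of survival on the positive-vs-negative
#' risk classification.
#'
#' @param cohort a \linkS4class{SurvivalCohort}.
#' @param risk a \linkS4class{RiskScores} for the same patients.
#' @param tiesMethod ties handling.
#' @return see \code{\link{coxFit}}; the single term is
#'   positive-vs-negative.
#' @export
coxByRiskGroup <- function(cohort, risk, tiesMethod = "efron") {
  grp <- riskGroup(risk)
  coxFit(survTime(cohort), survEvent(cohort),
         data.frame(risk = factor(grp, levels = c("negative", "positive"))),
         tiesMethod = tiesMethod)
}

#' Stratified re-analysis by a clinical factor
#'
#' Within each level of \code{factor}, re-runs the univariate Cox fit of
#' positive-vs-negative risk group plus Kaplan-Meier and log-rank. Group
#' labels are carried from the whole-cohort classification, not re-split
#' per stratum. Strata lacking both risk groups or lacking events are
#' flagged unevaluable and skipped.
#'
#' @param cohort a \linkS4class{SurvivalCohort}.
#' @param factor a factor (or covariate name in colData) partitioning the
#'   cohort.
#' @param risk a \linkS4class{RiskScores} from the whole-cohort
#'   classification.
#' @param tiesMethod ties handling.
#' @return named list per stratum: either list(cox, km, logrank, n,
#'   events) or list(unevaluable = TRUE, reason).
#' @export
stratifiedAnalysis <- function(cohort, factor, risk, tiesMethod = "efron") {
  if (is.character(factor) && length(factor) == 1L) {
    factor <- SummarizedExperiment::colData(cohort)[[factor]]
  }
  factor <- as.factor(factor)
  if (length(factor) != ncol(cohort)) {
    stop("factor must have one value per patient")
  }
  grp <- riskGroup(risk)
  tt <- survTime(cohort); ev <- survEvent(cohort)
  out <- list()
  for (lev in levels(factor)) {
    i <- which(factor == lev)
    gi <- droplevels(grp[i])
    if (nlevels(gi) < 2L) {
      out[[lev]] <- list(unevaluable = TRUE,
                         reason = "single risk group in stratum")
      next
    }
    if (min(tapply(ev[i], gi, sum)) < 1) {
      out[[lev]] <- list(unevaluable = TRUE,
                         reason = "a risk group without events")
      next
    }
    out[[lev]] <- list(
      cox = coxFit(tt[i], ev[i],
                   data.frame(risk = factor(grp[i],
                                            levels = c("negative", "positive"))),
                   tiesMethod = tiesMethod),
      km = kmEstimate(tt[i], ev[i], grp[i]),
      logrank = logrankTest(tt[i], ev[i], grp[i]),
      n = length(i), events = sum(ev[i]))
  }
  out
}
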