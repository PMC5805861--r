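#' Split a cohort at the median genetic risk score
#'
#' Individuals scoring strictly above the median form the high-genetic-risk
#' group, those strictly below form the low group. Individuals tied exactly
#' at the median are assigned deterministically, in sample-id sort order,
#' alternating into whichever group is currently smaller (low first on a
#' tie), which keeps the two halves balanced to within one individual plus
#' the tie count.
#'
#' @param scoreVec a [ScoreVector-class].
#' @param cohort a [CohortTable-class]; only individuals present in both are
#'   stratified.
#' @return A [StratifiedCohort-class] with the median cutoff recorded.
#' @export
splitByMedian <- function(scoreVec, cohort) {
  stopifnot(is(scoreVec, "ScoreVector"), is(cohort, "CohortTable"))
  d <- cohort@data
  m <- match(d$id, scoreVec@sampleIds)
  d <- d[!is.na(m), , drop = FALSE]
  d$score <- scoreVec@score[m[!is.na(m)]]
  if (nrow(d) < 2) stop("need at least 2 scored individuals")
  if (length(unique(d$score)) == 1) {
    stop("all scores identical; median stratification undefined")
  }
  med <- stats::median(d$score)
  grp <- rep(NA_character_, nrow(d))
  grp[d$score > med] <- "high"
  grp[d$score < med] <- "low"
  tied <- which(d$score == med)
  if (length(tied)) {
    tied <- tied[order(d$id[tied])]
    nHigh <- sum(grp == "high", na.rm = TRUE)
    nLow <- sum(grp == "low", na.rm = TRUE)
    for (i in tied) {
      if (nLow <= nHigh) {
        grp[i] <- "low"; nLow <- nLow + 1
      } else {
        grp[i] <- "high"; nHigh <- nHigh + 1
      }
    }
  }
  d$group <- grp
  new("StratifiedCohort", data = d, medianCutoff = med)
}

# follow-up time and event indicator under the censoring rules:
# events after censorAge are treated as non-events censored at censorAge;
# everyone else is censored at min(enrolment age, censorAge)
censorObservations <- function(enrolAge, dxAge, hasDiabetes, censorAge = 60) {
  event <- hasDiabetes %in% TRUE & !is.na(dxAge) & dxAge <= censorAge
  time <- ifelse(event, dxAge, pmin(enrolAge, censorAge))
  list(time = time, event = event)
}

#' Kaplan-Meier product-limit estimator
#'
#' Computes \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} over the distinct
#' event times \eqn{t_i}, with \eqn{d_i} events among \eqn{n_i} at risk.
#' Follow-up uses age as the timescale; events recorded after `censorAge`
#' are converted to censorings at `censorAge` (administrative censoring),
#' and tied integer event ages are handled as tied events.
#'
#' @param time ages at event or censoring (years, non-negative; diagnosis
#'   in the first year of life is age 0).
#' @param event logical event indicators.
#' @param censorAge administrative censoring age; `Inf` disables it.
#' @param label group label stored on the curve.
#' @return A [KMCurve-class].
#' @examples
#' km <- kmEstimate(c(1, 2, 3), c(TRUE, TRUE, TRUE), censorAge = Inf)
#' km@surv  # 2/3, 1/3, 0
#' @export
kmEstimate <- function(time, event, censorAge = 60, label = "all") {
  if (length(time) == 0) stop("empty input")
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(time < 0)) stop("ages must be non-negative")
  event <- as.logical(event)
  late <- event & time > censorAge
  event[late] <- FALSE
  time <- pmin(time, censorAge)

  eventTimes <- sort(unique(time[event]))
  nRisk <- numeric(length(eventTimes))
  nEvent <- numeric(length(eventTimes))
  for (k in seq_along(eventTimes)) {
    nRisk[k] <- sum(time >= eventTimes[k])
    nEvent[k] <- sum(event & time == eventTimes[k])
  }
  surv <- cumprod(1 - nEvent / pmax(nRisk, 1))
  new("KMCurve", time = eventTimes, nRisk = nRisk, nEvent = nEvent,
      surv = surv, label = label)
}

#' Evaluate a KM curve at given times
#'
#' Step-function evaluation: `S(t)` is the survival after the last event
#' time `<= t` (1 before the first event).
#'
#' @param curve a [KMCurve-class].
#' @param at times at which to evaluate.
#' @return numeric survival probabilities.
#' @export
kmSurvivalAt <- function(curve, at) {
  idx <- findInterval(at, curve@time)
  c(1, curve@surv)[idx + 1]
}

#' Per-group KM curves for a stratified cohort
#'
#' @param stratified a [StratifiedCohort-class].
#' @param censorAge administrative censoring age (default 60).
#' @return named list of [KMCurve-class] (`high`, `low`).
#' @export
kmByGroup <- function(stratified, censorAge = 60) {
  d <- stratified@data
  lapply(stats::setNames(c("high", "low"), c("high", "low")), function(g) {
    x <- d[d$group == g, ]
    cens <- censorObservations(x$enrolment_age, x$age_at_diagnosis,
                               x$has_diabetes, censorAge)
    kmEstimate(cens$time, cens$event, censorAge = censorAge, label = g)
  })
}

#' Life table of a KM curve
#'
#' @param curve a [KMCurve-class].
#' @return data.frame: group, age, n_at_risk, n_events, survival.
#' @export
kmLifeTable <- function(curve) {
  data.frame(group = rep(curve@label, length(curve@time)), age = curve@time,
             n_at_risk = curve@nRisk, n_events = curve@nEvent,
             survival = curve@surv, stringsAsFactors = FALSE)
}

#' Log-rank hazard ratio (observed/expected form) between two groups
#'
#' At each distinct event time the expected event count per group is
#' allocated in proportion to the numbers at risk; the hazard ratio is
#' \eqn{(O_H/E_H) / (O_L/E_L)} with a log-scale normal confidence interval
#' using \eqn{se(\log HR) = \sqrt{1/E_H + 1/E_L}}. No proportional-hazards
#' model is fitted.
#'
#' @param timeHigh,eventHigh follow-up and event indicator, high group.
#' @param timeLow,eventLow same for the low group.
#' @param censorAge administrative censoring age.
#' @param conf confidence level (default 0.95).
#' @return list(hr, ci, oHigh, eHigh, oLow, eLow); `hr` is `NA` when either
#'   group has no events.
#' @export
kmHazardRatio <- function(timeHigh, eventHigh, timeLow, eventLow,
                          censorAge = 60, conf = 0.95) {
  if (length(timeHigh) == 0 || length(timeLow) == 0) {
    stop("both groups must be non-empty")
  }
  prep <- function(time, event) {
    event <- as.logical(event)
    event[event & time > censorAge] <- FALSE
    list(time = pmin(time, censorAge), event = event)
  }
  h <- prep(timeHigh, eventHigh); l <- prep(timeLow, eventLow)
  times <- sort(unique(c(h$time[h$event], l$time[l$event])))
  eH <- 0; eL <- 0
  for (t in times) {
    nH <- sum(h$time >= t); nL <- sum(l$time >= t)
    d <- sum(h$event & h$time == t) + sum(l$event & l$time == t)
    eH <- eH + d * nH / (nH + nL)
    eL <- eL + d * nL / (nH + nL)
  }
  oH <- sum(h$event); oL <- sum(l$event)
  if (oH == 0 || oL == 0 || eH == 0 || eL == 0) {
    warning("zero events in one group; hazard ratio undefined")
    return(list(hr = NA_real_, ci = c(NA_real_, NA_real_),
                oHigh = oH, eHigh = eH, oLow = oL, eLow = eL))
  }
  hr <- (oH / eH) / (oL / eL)
  se <- sqrt(1 / eH + 1 / eL)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(hr = hr, ci = exp(log(hr) + c(-1, 1) * z * se),
       oHigh = oH, eHigh = eH, oLow = oL, eLow = eL)
}
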