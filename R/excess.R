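# right-closed integer age bands: first band [e0, e1], then (e_j, e_j+1]
assignBands <- function(ages, edges) {
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("band edges must be strictly increasing (overlapping bands)")
  }
  labels <- character(length(edges) - 1)
  labels[1] <- paste0(edges[1], "-", edges[2])
  if (length(edges) > 2) {
    for (j in 2:(length(edges) - 1)) {
      labels[j] <- paste0(edges[j] + 1, "-", edges[j + 1])
    }
  }
  cut(ages, breaks = edges, labels = labels, include.lowest = TRUE,
      right = TRUE)
}

# diabetes cases inside the censoring window
caseFlags <- function(d, censorAge = 60) {
  d$has_diabetes %in% TRUE & !is.na(d$age_at_diagnosis) &
    d$age_at_diagnosis <= censorAge
}

#' Excess of cases in the high-genetic-risk half
#'
#' The subtraction estimator's core: the number of genetically defined type
#' 1 diabetes cases is the number of diabetes cases in the high-score half
#' minus the number in the low-score half. A negative excess (possible
#' under sampling noise) is returned as-is, with a warning, and never
#' clamped.
#'
#' @param nHighCases,nLowCases non-negative case counts.
#' @return `nHighCases - nLowCases`.
#' @examples
#' excessCount(7268, 5982)  # 1286
#' @export
excessCount <- function(nHighCases, nLowCases) {
  if (nHighCases < 0 || nLowCases < 0) stop("case counts must be non-negative")
  ex <- nHighCases - nLowCases
  if (ex < 0) {
    warning("negative excess (", ex, "): sampling noise exceeds the signal")
  }
  ex
}

#' Excess as a proportion of all diabetes, with confidence interval
#'
#' Point estimate `100 * excess / totalCases` (percent). The default
#' confidence interval is a nonparametric bootstrap over individuals,
#' computed by multinomial resampling of the (high-case, low-case,
#' no-diabetes) cell counts, which is algebraically identical to resampling
#' individuals i.i.d.; `wald` uses the normal approximation with
#' `var(excess) = nHigh + nLow` (variance of a difference of two binomial
#' counts in the rare-outcome limit); `binomial_share` is the naive binomial
#' interval on `excess / totalCases` treated as a direct proportion.
#'
#' @param excess case excess (high minus low).
#' @param totalCases all diabetes cases (> 0).
#' @param nPopulation total cohort size; required for the full bootstrap.
#'   When `NULL`, the bootstrap resamples case group membership only.
#' @param method `"bootstrap"` (default), `"wald"` or `"binomial_share"`.
#' @param B bootstrap resamples (default 2000).
#' @param conf confidence level.
#' @return list(estimate, ci, method); estimate and ci in percent.
#' @export
proportionT1D <- function(excess, totalCases, nPopulation = NULL,
                          method = c("bootstrap", "wald", "binomial_share"),
                          B = 2000, conf = 0.95) {
  if (totalCases <= 0) stop("totalCases must be positive")
  method <- match.arg(method)
  est <- 100 * excess / totalCases
  nHigh <- (totalCases + excess) / 2
  nLow <- (totalCases - excess) / 2
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- switch(method,
    bootstrap = {
      probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
      if (!is.null(nPopulation)) {
        cells <- stats::rmultinom(B, nPopulation,
                                  c(nHigh, nLow,
                                    nPopulation - totalCases) / nPopulation)
        stat <- 100 * (cells[1, ] - cells[2, ]) / pmax(cells[1, ] + cells[2, ], 1)
      } else {
        xh <- stats::rbinom(B, totalCases, nHigh / totalCases)
        stat <- 100 * (2 * xh - totalCases) / totalCases
      }
      as.numeric(stats::quantile(stat, probs))
    },
    wald = est + c(-1, 1) * z * 100 * sqrt(nHigh + nLow) / totalCases,
    binomial_share = {
      p <- excess / totalCases
      est + c(-1, 1) * z * 100 * sqrt(max(p * (1 - p), 0) / totalCases)
    }
  )
  list(estimate = est, ci = ci, method = method)
}

#' Case excess by diagnosis-age band
#'
#' Splits the subtraction estimate across right-closed integer age bands
#' (with the defaults, 0-30 means diagnosis at age 30 or younger and 31-60
#' means 31 to 60). Per band it reports the high/low case counts, the
#' excess (genetically defined type 1 diabetes), the band total, the band's
#' share of the overall excess, and the excess's share of the band total.
#' Band excesses and totals sum exactly to the overall values.
#'
#' @param stratified a [StratifiedCohort-class].
#' @param bandEdges ascending band edges (default c(0, 30, 60)).
#' @param censorAge administrative censoring age.
#' @param method,B,conf forwarded to [proportionT1D()] for the overall CI.
#' @return An [ExcessEstimate-class].
#' @export
excessByBand <- function(stratified, bandEdges = c(0, 30, 60),
                         censorAge = 60, method = "bootstrap", B = 2000,
                         conf = 0.95) {
  d <- stratified@data
  isCase <- caseFlags(d, censorAge)
  cases <- d[isCase, ]
  nHigh <- sum(cases$group == "high")
  nLow <- sum(cases$group == "low")
  total <- nHigh + nLow
  ex <- withCallingHandlers(excessCount(nHigh, nLow),
                            warning = function(w) invokeRestart("muffleWarning"))
  if (ex < 0) warning("negative overall excess (", ex, ")")
  prop <- if (total > 0) {
    proportionT1D(ex, total, nPopulation = nrow(d), method = method,
                  B = B, conf = conf)
  } else {
    list(estimate = NA_real_, ci = c(NA_real_, NA_real_))
  }

  band <- assignBands(cases$age_at_diagnosis, bandEdges)
  byBand <- do.call(rbind, lapply(levels(band), function(b) {
    bh <- sum(band == b & cases$group == "high")
    bl <- sum(band == b & cases$group == "low")
    data.frame(band = b, n_high = bh, n_low = bl, excess = bh - bl,
               total = bh + bl,
               share_of_excess = if (ex != 0) 100 * (bh - bl) / ex else NA_real_,
               share_of_band_total = if (bh + bl > 0) {
                 100 * (bh - bl) / (bh + bl)
               } else NA_real_,
               stringsAsFactors = FALSE)
  }))
  new("ExcessEstimate", nHighCases = nHigh, nLowCases = nLow, excess = ex,
      totalCases = total, proportion = prop$estimate,
      proportionCI = as.numeric(prop$ci), byBand = byBand)
}

#' Cumulative excess of genetically defined type 1 diabetes by age
#'
#' For each age `a` in 1..`censorAge`, the number of high-group cases
#' diagnosed at or before `a` minus the number of low-group cases diagnosed
#' at or before `a`. The final value equals the overall excess; the curve
#' is a difference of two counting processes and may decrease locally.
#'
#' @param stratified a [StratifiedCohort-class].
#' @param censorAge administrative censoring age.
#' @return data.frame: age, n_high, n_low, cumulative_excess.
#' @export
cumulativeExcess <- function(stratified, censorAge = 60) {
  d <- stratified@data
  cases <- d[caseFlags(d, censorAge), ]
  ages <- seq_len(censorAge)
  nH <- vapply(ages, function(a) {
    sum(cases$group == "high" & cases$age_at_diagnosis <= a)
  }, numeric(1))
  nL <- vapply(ages, function(a) {
    sum(cases$group == "low" & cases$age_at_diagnosis <= a)
  }, numeric(1))
  data.frame(age = ages, n_high = nH, n_low = nL,
             cumulative_excess = nH - nL)
}

#' Per-decade incidence of genetically defined type 1 and type 2 diabetes
#'
#' Per decade of diagnosis age, the type 1 count is the band excess and the
#' type 2 count is the band total minus the band excess (equivalently twice
#' the low-group band count when the decades partition the censored range),
#' so the two series sum to the observed totals.
#'
#' @param stratified a [StratifiedCohort-class].
#' @param decadeEdges ascending decade edges (default seq(0, 60, 10)).
#' @param censorAge administrative censoring age.
#' @return data.frame: decade, n_high, n_low, t1d (excess), t2d, total.
#' @export
incidenceByDecade <- function(stratified, decadeEdges = seq(0, 60, 10),
                              censorAge = 60) {
  est <- excessByBand(stratified, bandEdges = decadeEdges,
                      censorAge = censorAge, method = "wald")
  b <- est@byBand
  data.frame(decade = b$band, n_high = b$n_high, n_low = b$n_low,
             t1d = b$excess, t2d = b$total - b$excess, total = b$total,
             stringsAsFactors = FALSE)
}
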