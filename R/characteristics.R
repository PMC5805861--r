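#' Derived mean of the latent excess (type 1) group
#'
#' The high-score half's cases are a mixture of the latent type 1 group and
#' a type 2 group whose distribution is that of the low-score half, so the
#' latent group's mean follows by subtraction:
#' \deqn{\bar x_{T1D} = (n_H \bar x_H - n_L \bar x_L) / n_{T1D},}
#' with \eqn{n_{T1D} = n_H - n_L}.
#'
#' @param nHigh,meanHigh count and mean of the characteristic in the
#'   high-group cases (counts are of non-missing values).
#' @param nLow,meanLow same for the low-group cases.
#' @param nT1d latent group size; defaults to `nHigh - nLow` and must be
#'   positive.
#' @return the derived mean.
#' @examples
#' derivedMean(4, 2, 2, 0)  # latent group {4, 4}: mean 4
#' @export
derivedMean <- function(nHigh, meanHigh, nLow, meanLow, nT1d = nHigh - nLow) {
  if (nT1d <= 0) {
    stop("derivation undefined: n_T1D = ", nT1d,
         " (sampling noise dominates the excess)")
  }
  (nHigh * meanHigh - nLow * meanLow) / nT1d
}

#' Derived standard deviation of the latent excess group
#'
#' In `moment_subtraction` mode the second moment of each group is
#' reconstructed from its mean and SD using population (divide-by-n)
#' moments, subtracted exactly as for means, and the latent SD recovered as
#' \eqn{\sqrt{E[X^2]_{T1D} - \bar x_{T1D}^2}}. Sample (divide-by-n-1) SDs
#' are accepted on input and returned on output, so an explicit latent
#' decomposition is recovered exactly. `borrow_low_sd` returns the
#' low-group SD unchanged — the convention used for BMI, whose bimodal
#' mixture distribution in the high group makes moment subtraction
#' unreliable.
#'
#' @param nHigh,meanHigh,sdHigh high-group case count, mean and sample SD.
#' @param nLow,meanLow,sdLow low-group equivalents.
#' @param nT1d latent group size (default `nHigh - nLow`).
#' @param mode `"moment_subtraction"` or `"borrow_low_sd"`.
#' @return the derived sample SD.
#' @export
derivedSd <- function(nHigh, meanHigh, sdHigh, nLow, meanLow, sdLow,
                      nT1d = nHigh - nLow,
                      mode = c("moment_subtraction", "borrow_low_sd")) {
  mode <- match.arg(mode)
  if (nT1d <= 0) stop("derivation undefined: n_T1D = ", nT1d)
  if (sdHigh < 0 || sdLow < 0) stop("standard deviations must be non-negative")
  if (mode == "borrow_low_sd") return(sdLow)

  popVar <- function(n, s) if (n > 1) s^2 * (n - 1) / n else 0
  m2H <- popVar(nHigh, sdHigh) + meanHigh^2
  m2L <- popVar(nLow, sdLow) + meanLow^2
  meanT <- derivedMean(nHigh, meanHigh, nLow, meanLow, nT1d)
  m2T <- (nHigh * m2H - nLow * m2L) / nT1d
  varT <- m2T - meanT^2
  tol <- 1e-8 * max(1, abs(m2T))
  if (varT < -tol) {
    stop("negative reconstructed variance (", format(varT, digits = 4),
         "): inconsistent summaries or sampling noise")
  }
  varT <- max(varT, 0)
  if (nT1d < 2) return(sqrt(varT))
  sqrt(varT * nT1d / (nT1d - 1))
}

#' Derived categorical excess
#'
#' Per category, the latent group's count is the excess of the high-group
#' count over the low-group count; a negative per-category excess is
#' flagged but returned unchanged.
#'
#' @param countHigh,countLow non-negative category counts.
#' @return `countHigh - countLow`.
#' @export
derivedCategorical <- function(countHigh, countLow) {
  if (countHigh < 0 || countLow < 0) stop("counts must be non-negative")
  ex <- countHigh - countLow
  if (ex < 0) warning("negative category excess (", ex, ")")
  ex
}

#' Welch two-sample t test from summary statistics
#'
#' @param n1,mean1,sd1 first group summaries (sample SD).
#' @param n2,mean2,sd2 second group summaries.
#' @return list(statistic, df, p) with the Welch-Satterthwaite degrees of
#'   freedom.
#' @export
welchTestSummary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  if (se == 0) return(list(statistic = 0, df = n1 + n2 - 2, p = 1))
  tstat <- (mean1 - mean2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = tstat, df = df,
       p = 2 * stats::pt(-abs(tstat), df = df))
}

#' Chi-square test of homogeneity for two groups of category counts
#'
#' Pearson chi-square without continuity correction on the 2 x k table of
#' counts; invalid (zero expected count) tables return `NA` with a warning.
#'
#' @param countsA,countsB category counts per group (equal length >= 2).
#' @return list(statistic, df, p).
#' @export
chisqCounts <- function(countsA, countsB) {
  tab <- rbind(countsA, countsB)
  if (any(tab < 0)) {
    warning("negative count in contingency table; test invalid")
    return(list(statistic = NA_real_, df = NA_real_, p = NA_real_))
  }
  exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp == 0)) {
    warning("zero expected cell count; chi-square invalid")
    return(list(statistic = NA_real_, df = NA_real_, p = NA_real_))
  }
  stat <- sum((tab - exp)^2 / exp)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Bonferroni adjustment over the tested characteristics
#'
#' @param p raw p-value(s).
#' @param nTested number of characteristics tested (default 7).
#' @return `min(1, p * nTested)`, elementwise.
#' @export
bonferroni <- function(p, nTested = 7) pmin(1, p * nTested)

#' Compare two group summaries for one characteristic
#'
#' Continuous characteristics are compared with a Welch t test from summary
#' statistics (`n`, `mean`, `sd`); categorical characteristics with a
#' Pearson chi-square (no continuity correction) on the category `counts`.
#'
#' @param a,b group summary lists: continuous need `n`, `mean`, `sd`;
#'   categorical need `counts` (same categories, same order).
#' @param type `"continuous"` or `"categorical"`.
#' @param nTested Bonferroni denominator.
#' @return c(raw = p, adjusted = min(1, p * nTested)).
#' @export
compareGroups <- function(a, b, type = c("continuous", "categorical"),
                          nTested = 7) {
  type <- match.arg(type)
  p <- if (type == "continuous") {
    welchTestSummary(a$n, a$mean, a$sd, b$n, b$mean, b$sd)$p
  } else {
    chisqCounts(a$counts, b$counts)$p
  }
  c(raw = p, adjusted = bonferroni(p, nTested))
}

CONTINUOUS_CHARACTERISTICS <- c(age_at_entry = "enrolment_age",
                                age_at_diagnosis = "age_at_diagnosis",
                                bmi = "bmi")
CATEGORICAL_CHARACTERISTICS <- c(sex_male = "sex",
                                 insulin_at_1yr = "insulin_within_1yr",
                                 insulin_at_entry = "insulin_at_entry",
                                 dka_admission = "dka_admission")

charValues <- function(d, column) {
  if (column == "sex") d$sex == "male" else d[[column]]
}

# derived summaries of the latent type 1 group among the cases of one band
derivedBandSummary <- function(high, low, B = 1000, conf = 0.95) {
  out <- list()
  qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  bootIdxH <- if (B > 0) {
    matrix(sample.int(nrow(high), nrow(high) * B, replace = TRUE), ncol = B)
  }
  bootIdxL <- if (B > 0) {
    matrix(sample.int(nrow(low), nrow(low) * B, replace = TRUE), ncol = B)
  }
  bootDerived <- function(f) {
    vapply(seq_len(B), function(b) {
      f(high[bootIdxH[, b], ], low[bootIdxL[, b], ])
    }, numeric(1))
  }

  for (nm in names(CONTINUOUS_CHARACTERISTICS)) {
    col <- CONTINUOUS_CHARACTERISTICS[[nm]]
    sdMode <- if (col == "bmi") "borrow_low_sd" else "moment_subtraction"
    stat <- function(h, l) {
      xh <- charValues(h, col); xh <- xh[!is.na(xh)]
      xl <- charValues(l, col); xl <- xl[!is.na(xl)]
      if (length(xh) - length(xl) <= 0) return(NA_real_)
      derivedMean(length(xh), mean(xh), length(xl), mean(xl))
    }
    xh <- charValues(high, col); xh <- xh[!is.na(xh)]
    xl <- charValues(low, col); xl <- xl[!is.na(xl)]
    n1 <- length(xh) - length(xl)
    if (n1 <= 0) {
      out[[nm]] <- list(type = "continuous", n = n1, estimate = NA_real_,
                        sd = NA_real_, ci = c(NA_real_, NA_real_))
      next
    }
    est <- derivedMean(length(xh), mean(xh), length(xl), mean(xl))
    sdT <- tryCatch(
      derivedSd(length(xh), mean(xh), stats::sd(xh),
                length(xl), mean(xl), stats::sd(xl), mode = sdMode),
      error = function(e) NA_real_)
    ci <- if (B > 0) {
      bs <- bootDerived(stat)
      as.numeric(stats::quantile(bs, qs, na.rm = TRUE))
    } else c(NA_real_, NA_real_)
    out[[nm]] <- list(type = "continuous", n = n1, estimate = est,
                      sd = sdT, ci = ci)
  }

  for (nm in names(CATEGORICAL_CHARACTERISTICS)) {
    col <- CATEGORICAL_CHARACTERISTICS[[nm]]
    stat <- function(h, l) {
      xh <- charValues(h, col); xh <- xh[!is.na(xh)]
      xl <- charValues(l, col); xl <- xl[!is.na(xl)]
      nT <- length(xh) - length(xl)
      if (nT <= 0) return(NA_real_)
      100 * (sum(xh) - sum(xl)) / nT
    }
    xh <- charValues(high, col); xh <- xh[!is.na(xh)]
    xl <- charValues(low, col); xl <- xl[!is.na(xl)]
    nT <- length(xh) - length(xl)
    if (nT <= 0) {
      out[[nm]] <- list(type = "categorical", n = nT, count = NA_real_,
                        estimate = NA_real_, ci = c(NA_real_, NA_real_))
      next
    }
    cnt <- withCallingHandlers(derivedCategorical(sum(xh), sum(xl)),
                               warning = function(w) invokeRestart("muffleWarning"))
    ci <- if (B > 0) {
      bs <- bootDerived(stat)
      as.numeric(stats::quantile(bs, qs, na.rm = TRUE))
    } else c(NA_real_, NA_real_)
    out[[nm]] <- list(type = "categorical", n = nT, count = cnt,
                      estimate = 100 * cnt / nT, ci = ci)
  }
  out
}

# summaries of the type 2 comparison group: the low-group case distribution
# applied at weight (band total - band excess) = 2 x low count
t2dBandSummary <- function(low) {
  out <- list()
  for (nm in names(CONTINUOUS_CHARACTERISTICS)) {
    x <- charValues(low, CONTINUOUS_CHARACTERISTICS[[nm]])
    x <- x[!is.na(x)]
    out[[nm]] <- list(type = "continuous", n = 2 * length(x),
                      estimate = mean(x), sd = stats::sd(x),
                      ci = mean(x) + c(-1, 1) * 1.96 * stats::sd(x) /
                        sqrt(max(2 * length(x), 1)))
  }
  for (nm in names(CATEGORICAL_CHARACTERISTICS)) {
    x <- charValues(low, CATEGORICAL_CHARACTERISTICS[[nm]])
    x <- x[!is.na(x)]
    n <- 2 * length(x); cnt <- 2 * sum(x)
    p <- if (n > 0) cnt / n else NA_real_
    out[[nm]] <- list(type = "categorical", n = n, count = cnt,
                      estimate = 100 * p,
                      ci = 100 * (p + c(-1, 1) * 1.96 *
                                    sqrt(max(p * (1 - p), 0) / max(n, 1))))
  }
  out
}

summaryRow <- function(table, group, nm, s, pRaw = NA_real_,
                       pAdj = NA_real_) {
  data.frame(table = table, group = group, characteristic = nm,
             type = s$type, n = s$n,
             count = if (is.null(s$count)) NA_real_ else s$count,
             estimate = s$estimate, sd = if (is.null(s$sd)) NA_real_ else s$sd,
             ci_low = s$ci[1], ci_high = s$ci[2],
             p_raw = pRaw, p_bonferroni = pAdj, stringsAsFactors = FALSE)
}

comparePair <- function(sa, sb, nTested) {
  if (sa$type == "continuous") {
    if (is.na(sa$estimate) || is.na(sb$estimate) ||
        is.na(sa$sd) || is.na(sb$sd) || sa$n < 2 || sb$n < 2) {
      return(c(NA_real_, NA_real_))
    }
    p <- welchTestSummary(sa$n, sa$estimate, sa$sd,
                          sb$n, sb$estimate, sb$sd)$p
  } else {
    if (is.na(sa$count) || is.na(sb$count)) return(c(NA_real_, NA_real_))
    p <- chisqCounts(c(sa$count, sa$n - sa$count),
                     c(sb$count, sb$n - sb$count))$p
  }
  c(p, bonferroni(p, nTested))
}

#' Clinical-characteristic report tables for the derived type 1 group
#'
#' Builds two tables. Table 1 compares genetically defined type 1 diabetes
#' with type 2 diabetes among cases diagnosed in the upper age band
#' (default 31-60): the type 1 column holds subtraction-derived summaries
#' and the type 2 column holds the low-group case distribution weighted to
#' `band total - band excess` individuals. Table 2 compares derived type 1
#' summaries between the lower (default 0-30) and upper diagnosis-age
#' bands. Continuous cells are mean (bootstrap 95% CI) with a derived SD
#' (moment subtraction, except BMI which borrows the type 2 SD); categorical
#' cells are derived count and percentage. p-values are Welch t tests /
#' chi-square without continuity correction, Bonferroni-adjusted over
#' `nTested` characteristics.
#'
#' @param stratified a [StratifiedCohort-class].
#' @param bandEdges two bands (default c(0, 30, 60)).
#' @param censorAge administrative censoring age.
#' @param B bootstrap resamples for derived CIs (0 disables).
#' @param nTested Bonferroni denominator (default 7).
#' @return list(table1, table2) of data.frames; a band whose excess is not
#'   positive yields NA rows with a message.
#' @export
buildTables <- function(stratified, bandEdges = c(0, 30, 60), censorAge = 60,
                        B = 1000, nTested = 7) {
  d <- stratified@data
  cases <- d[caseFlags(d, censorAge), ]
  band <- assignBands(cases$age_at_diagnosis, bandEdges)
  if (nlevels(band) != 2) stop("buildTables needs exactly two age bands")
  lower <- levels(band)[1]; upper <- levels(band)[2]
  sub <- function(b, g) cases[band == b & cases$group == g, ]

  dUpper <- derivedBandSummary(sub(upper, "high"), sub(upper, "low"), B = B)
  dLower <- derivedBandSummary(sub(lower, "high"), sub(lower, "low"), B = B)
  t2Upper <- t2dBandSummary(sub(upper, "low"))

  allChars <- c(names(CONTINUOUS_CHARACTERISTICS),
                names(CATEGORICAL_CHARACTERISTICS))
  table1 <- do.call(rbind, lapply(allChars, function(nm) {
    p <- comparePair(dUpper[[nm]], t2Upper[[nm]], nTested)
    rbind(summaryRow("table1", paste0("T1D_", upper), nm, dUpper[[nm]],
                     p[1], p[2]),
          summaryRow("table1", paste0("T2D_", upper), nm, t2Upper[[nm]],
                     p[1], p[2]))
  }))
  table2 <- do.call(rbind, lapply(allChars, function(nm) {
    p <- comparePair(dLower[[nm]], dUpper[[nm]], nTested)
    rbind(summaryRow("table2", paste0("T1D_", lower), nm, dLower[[nm]],
                     p[1], p[2]),
          summaryRow("table2", paste0("T1D_", upper), nm, dUpper[[nm]],
                     p[1], p[2]))
  }))
  list(table1 = table1, table2 = table2)
}
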