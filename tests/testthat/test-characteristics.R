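# explicit latent decomposition: the high group is the union of the low
# group's values and a known latent block
latentDecomposition <- function(nLow, nLatent, seed) {
  set.seed(seed)
  low <- rnorm(nLow, 30, 5)
  latent <- rnorm(nLatent, 25, 3)
  list(low = low, latent = latent, high = c(low, latent))
}

test_that("the derived mean follows the subtraction identity", {
  expect_equal(derivedMean(4, 2, 2, 0), 4)          # latent {4, 4}
  expect_equal(derivedMean(10, 7.3, 4, 7.3), 7.3)   # shift invariance
  expect_error(derivedMean(5, 1, 5, 1), "undefined")
  expect_error(derivedMean(4, 1, 6, 1), "undefined")
})

test_that("derived mean and SD recover any explicit latent decomposition", {
  for (seed in 1:50) {
    nLow <- sample(2:40, 1); nLatent <- sample(2:40, 1)
    dec <- latentDecomposition(nLow, nLatent, seed)
    nH <- length(dec$high); nL <- length(dec$low); nT <- nLatent
    m <- derivedMean(nH, mean(dec$high), nL, mean(dec$low))
    expect_equal(m, mean(dec$latent), tolerance = 1e-12)
    s <- derivedSd(nH, mean(dec$high), sd(dec$high),
                   nL, mean(dec$low), sd(dec$low))
    expect_equal(s, sd(dec$latent), tolerance = 1e-10)
    # recombination: n_L xbar_L + n_T1D xbar_T1D = n_H xbar_H
    expect_equal(nL * mean(dec$low) + nT * m, nH * mean(dec$high),
                 tolerance = 1e-9)
  }
})

test_that("derived SD handles the documented special cases", {
  # latent {4,4} from high {0,0,4,4} vs low {0,0}: zero-variance latent
  expect_equal(derivedSd(4, 2, sd(c(0, 0, 4, 4)), 2, 0, 0), 0,
               tolerance = 1e-10)
  # BMI convention: borrow the type 2 (low-group) SD unchanged
  expect_equal(derivedSd(10, 30, 5, 4, 32, 6.0, mode = "borrow_low_sd"), 6.0)
  # inconsistent summaries surface as a negative reconstructed variance
  expect_error(derivedSd(4, 10, 0.1, 2, 0, 0.1), "negative reconstructed")
})

test_that("categorical excess subtracts counts and flags negatives", {
  expect_equal(derivedCategorical(537, 0), 537)
  expect_equal(derivedCategorical(50, 50), 0)
  expect_warning(ex <- derivedCategorical(10, 14), "negative")
  expect_equal(ex, -4)
})

test_that("the summary-statistic Welch t test matches a raw-data oracle", {
  set.seed(50)
  for (i in 1:10) {
    x <- rnorm(sample(10:60, 1), 0, 1 + runif(1))
    y <- rnorm(sample(10:60, 1), 0.5, 1 + runif(1))
    ours <- welchTestSummary(length(x), mean(x), sd(x),
                             length(y), mean(y), sd(y))
    ref <- t.test(x, y)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
  }
})

test_that("the chi-square comparison matches chisq.test without correction", {
  set.seed(51)
  for (i in 1:10) {
    tab <- matrix(sample(5:200, 4), 2, 2)
    ours <- chisqCounts(tab[1, ], tab[2, ])
    ref <- chisq.test(tab, correct = FALSE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
  expect_equal(chisqCounts(c(10, 10), c(10, 10))$statistic, 0)
  expect_equal(chisqCounts(c(10, 10), c(10, 10))$p, 1)
  expect_warning(bad <- chisqCounts(c(0, 10), c(0, 5)), "zero expected")
  expect_true(is.na(bad$p))
})

test_that("the ketoacidosis worked example is overwhelmingly significant", {
  p <- compareGroups(list(counts = c(61, 537 - 61)),
                     list(counts = c(30, 11696 - 30)),
                     type = "categorical")
  expect_lt(p[["raw"]], 1e-4)
  expect_lt(p[["adjusted"]], 1e-4)
  expect_equal(p[["adjusted"]], min(1, p[["raw"]] * 7))
})

test_that("Bonferroni adjustment is monotone and capped at one", {
  p <- c(0.001, 0.01, 0.2, 0.9)
  adj <- bonferroni(p, 7)
  expect_equal(adj, pmin(1, p * 7))
  expect_true(all(diff(adj) >= 0))
  expect_equal(bonferroni(0.5, 7), 1)
})

test_that("report tables match hand arithmetic on a constructed cohort", {
  # upper band: low cases 40 at BMI 32, high cases = the same 40 plus a
  # latent block of 10 at BMI 24; lower band kept minimal
  mkCase <- function(id, grp, dx, bmi, ins1) {
    data.frame(id = id, sex = "male", enrolment_age = 69, has_diabetes = TRUE,
               age_at_diagnosis = dx, insulin_within_1yr = ins1,
               insulin_at_entry = ins1, bmi = bmi, dka_admission = FALSE,
               score = ifelse(grp == "high", 2, 1), group = grp,
               stringsAsFactors = FALSE)
  }
  mkCtl <- function(id, grp) {
    data.frame(id = id, sex = "female", enrolment_age = 69,
               has_diabetes = FALSE, age_at_diagnosis = NA_real_,
               insulin_within_1yr = NA, insulin_at_entry = NA, bmi = 27,
               dka_admission = FALSE,
               score = ifelse(grp == "high", 2, 1), group = grp,
               stringsAsFactors = FALSE)
  }
  d <- rbind(
    mkCase(sprintf("h%03d", 1:40), "high", 45, 32, FALSE),
    mkCase(sprintf("hl%03d", 1:10), "high", 50, 24, TRUE),   # latent block
    mkCase(sprintf("hy%03d", 1:6), "high", 20, 25, TRUE),
    mkCase(sprintf("l%03d", 1:40), "low", 45, 32, FALSE),
    mkCase(sprintf("ly%03d", 1:2), "low", 20, 25, TRUE),
    mkCtl(sprintf("ch%03d", 1:20), "high"),
    mkCtl(sprintf("cl%03d", 1:34), "low"))   # balances the group sizes
  st <- new("StratifiedCohort", data = d, medianCutoff = 1.5)
  tabs <- quietly(buildTables(st, B = 0))
  t1 <- tabs$table1
  bmiT1 <- t1[t1$group == "T1D_31-60" & t1$characteristic == "bmi", ]
  expect_equal(bmiT1$n, 10)
  expect_equal(bmiT1$estimate, 24)            # exact latent recovery
  bmiT2 <- t1[t1$group == "T2D_31-60" & t1$characteristic == "bmi", ]
  expect_equal(bmiT2$estimate, 32)
  expect_equal(bmiT2$n, 80)                   # band total - excess = 2 x low
  insT1 <- t1[t1$group == "T1D_31-60" & t1$characteristic == "insulin_at_1yr", ]
  expect_equal(insT1$count, 10)
  expect_equal(insT1$estimate, 100)           # all latent cases on insulin
  t2 <- tabs$table2
  young <- t2[t2$group == "T1D_0-30" & t2$characteristic == "age_at_diagnosis", ]
  expect_equal(young$n, 4)                    # 6 high - 2 low young cases
  expect_equal(young$estimate, 20)
})

test_that("a band without positive excess yields NA rows, not an error", {
  st <- makeStratifiedFromCases(highAges = c(rep(45, 5)),
                                lowAges = rep(45, 5), nPerGroup = 20)
  tabs <- quietly(buildTables(st, B = 0))
  upper <- tabs$table1[tabs$table1$group == "T1D_31-60", ]
  expect_true(all(is.na(upper$estimate)))
})
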