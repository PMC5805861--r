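smallConfig <- function(n = 20000, seed = 1, ...) {
  simulationConfig(nIndividuals = n, rngSeed = seed, ...)
}

test_that("identical seeds give identical cohorts; different seeds differ", {
  a <- simulateCohort(smallConfig(3000, seed = 5))
  b <- simulateCohort(smallConfig(3000, seed = 5))
  expect_identical(dosages(a@genotypes), dosages(b@genotypes))
  expect_identical(cohortData(a), cohortData(b))
  expect_identical(a@truth, b@truth)
  c <- simulateCohort(smallConfig(3000, seed = 6))
  expect_false(identical(dosages(a@genotypes), dosages(c@genotypes)))
})

test_that("realized class counts follow the configured prevalences", {
  n <- 50000
  synth <- simulateCohort(smallConfig(n, seed = 2))
  tab <- table(synth@truth$class)
  for (spec in list(c("T1D", 0.0034), c("T2D", 0.031))) {
    expected <- n * as.numeric(spec[2])
    sdBin <- sqrt(expected * (1 - as.numeric(spec[2])))
    expect_lt(abs(tab[[spec[1]]] - expected), 3 * sdBin)
  }
})

test_that("cohort invariants hold by construction", {
  synth <- simulateCohort(smallConfig(10000, seed = 3))
  d <- cohortData(synth)
  expect_equal(nrow(removedRows(synth@cohort)), 0)
  dia <- d[d$has_diabetes, ]
  expect_true(all(dia$age_at_diagnosis <= dia$enrolment_age))
  non <- d[!d$has_diabetes, ]
  expect_true(all(is.na(non$age_at_diagnosis)))
  expect_true(all(is.na(non$insulin_within_1yr)))
  expect_true(all(d$enrolment_age >= 40 & d$enrolment_age <= 69))
  # genotypes are valid hard calls
  expect_true(all(dosages(synth@genotypes) %in% 0:2))
})

test_that("type 2 onset rises with age and type 1 onset spans 0-60", {
  synth <- simulateCohort(smallConfig(100000, seed = 4))
  d <- cohortData(synth)
  cls <- truthLabels(synth)[d$id]
  t2 <- d$age_at_diagnosis[cls == "T2D"]
  expect_gt(mean(t2 > 30), 0.85)        # rejection against enrolment shifts
                                        # the 0.95 target down a little
  expect_true(all(t2 > 20 & t2 <= 60))
  t1 <- d$age_at_diagnosis[cls == "T1D"]
  expect_true(min(t1) <= 5 && max(t1) >= 50)
  expect_gt(mean(t1 <= 30), 0.5)
})

test_that("scores of type 2 and unaffected individuals share one distribution", {
  synth <- simulateCohort(smallConfig(50000, seed = 9))
  sv <- computeGRS(synth@genotypes, defaultWeights())
  s <- scores(sv)
  cls <- truthLabels(synth)[names(s)]
  ks <- suppressWarnings(ks.test(s[cls == "T2D"], s[cls == "none"]))
  expect_gt(ks$p.value, 0.01)
  # and the T1D group is strongly enriched above the population median
  med <- median(s)
  expect_gt(mean(s[cls == "T1D"] > med), 0.9)
})

test_that("the configured fraction of type 1 scores falls below the median", {
  synth <- simulateCohort(smallConfig(100000, seed = 10))
  sv <- computeGRS(synth@genotypes, defaultWeights())
  s <- scores(sv)
  cls <- truthLabels(synth)[names(s)]
  below <- mean(s[cls == "T1D"] < median(s))
  nT1 <- sum(cls == "T1D")
  expect_lt(abs(below - 0.04), 3 * sqrt(0.04 * 0.96 / nT1) + 0.01)
})

test_that("a null cohort (no type 1) leaves only sampling-noise excess", {
  synth <- simulateCohort(smallConfig(50000, seed = 11, t1dPrevalence = 0))
  expect_false(any(synth@truth$class == "T1D"))
  sv <- computeGRS(synth@genotypes, defaultWeights())
  st <- splitByMedian(sv, synth@cohort)
  est <- quietly(excessByBand(st, B = 200))
  expect_lt(abs(est@excess), 3 * sqrt(est@totalCases) + 1)
})

test_that("truth report conserves counts and is deterministic", {
  synth <- simulateCohort(smallConfig(20000, seed = 12))
  rep1 <- truthReport(synth)
  rep2 <- truthReport(simulateCohort(smallConfig(20000, seed = 12)))
  expect_identical(rep1, rep2)
  cc <- rep1$classCounts
  expect_equal(sum(cc$n), 20000)
  bc <- rep1$bandCounts
  for (cl in c("T1D", "T2D")) {
    expect_equal(sum(bc$n[bc$class == cl]), cc$n[cc$class == cl])
  }
  # empty (diabetes-free) cohort gives empty band counts
  none <- simulateCohort(smallConfig(500, seed = 13, t1dPrevalence = 0,
                                     t2dPrevalence = 0))
  repN <- truthReport(none)
  expect_equal(nrow(repN$bandCounts), 0)
  expect_equal(repN$classCounts$n[repN$classCounts$class == "none"], 500)
})

test_that("phenotype missingness can be injected for IO-rule testing", {
  synth <- simulateCohort(smallConfig(5000, seed = 14, missingRate = 0.2))
  d <- cohortData(synth)
  expect_gt(mean(is.na(d$bmi)), 0.1)
  expect_gt(mean(is.na(d$sex)), 0.1)
  expect_equal(nrow(removedRows(synth@cohort)), 0)   # still invariant-clean
})

test_that("an infeasible score arrangement fails with a bounded-attempts error", {
  w0 <- makeToyWeights(2, weights = c(0, 0))
  w0@diplotypeWeights[] <- 0              # degenerate: every score identical
  cfg <- smallConfig(400, seed = 15, alleleFreqs = c(0.3, 0.3),
                     t1dPrevalence = 0.05, fracT1dBelowMedian = 1)
  expect_error(simulateCohort(cfg, weights = w0, maxResample = 25),
               "attempts")
})
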