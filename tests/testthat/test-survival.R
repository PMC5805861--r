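scoreVectorFor <- function(ids, values) {
  new("ScoreVector", sampleIds = ids, score = values,
      hlaPart = rep(0, length(values)), additivePart = values,
      excluded = character(0))
}

cohortFor <- function(ids) {
  n <- length(ids)
  CohortTable(data.frame(
    id = ids, sex = "male", enrolment_age = 60, has_diabetes = FALSE,
    age_at_diagnosis = NA_real_, insulin_within_1yr = NA,
    insulin_at_entry = NA, bmi = 25, dka_admission = FALSE,
    stringsAsFactors = FALSE))
}

test_that("the median split separates clear scores and balances exact ties", {
  ids <- sprintf("s%d", 1:4)
  st <- splitByMedian(scoreVectorFor(ids, c(1, 2, 3, 4)), cohortFor(ids))
  expect_equal(medianCutoff(st), 2.5)
  g <- groupLabels(st)
  expect_identical(unname(g[c("s3", "s4")]), c("high", "high"))
  expect_identical(unname(g[c("s1", "s2")]), c("low", "low"))

  # ties exactly at the median are alternated deterministically by id order
  st2 <- splitByMedian(scoreVectorFor(ids, c(5, 5, 5, 7)), cohortFor(ids))
  g2 <- groupLabels(st2)
  expect_equal(sum(g2 == "high"), 2)
  expect_equal(sum(g2 == "low"), 2)
  expect_identical(unname(g2["s4"]), "high")
  # deterministic: same inputs, same assignment
  st3 <- splitByMedian(scoreVectorFor(ids, c(5, 5, 5, 7)), cohortFor(ids))
  expect_identical(groupLabels(st3), g2)

  expect_error(splitByMedian(scoreVectorFor(ids, rep(1, 4)), cohortFor(ids)),
               "identical")
})

test_that("group sizes stay near-balanced under heavy tying", {
  set.seed(30)
  for (rep in 1:5) {
    n <- sample(50:150, 1)
    ids <- sprintf("s%03d", seq_len(n))
    vals <- sample(1:4, n, replace = TRUE)   # many ties, incl. at the median
    st <- splitByMedian(scoreVectorFor(ids, as.numeric(vals)), cohortFor(ids))
    g <- groupLabels(st)
    nTied <- sum(st@data$score == medianCutoff(st))
    expect_lte(abs(sum(g == "high") - sum(g == "low")), max(1, nTied))
  }
})

test_that("the product-limit estimator matches closed forms", {
  km <- kmEstimate(c(1, 2, 3), c(TRUE, TRUE, TRUE), censorAge = Inf)
  expect_equal(km@surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km@nRisk, c(3, 2, 1))

  # all censored: S stays 1 (no event times at all)
  km0 <- kmEstimate(c(5, 10, 20), c(FALSE, FALSE, FALSE))
  expect_length(km0@time, 0)
  expect_equal(kmSurvivalAt(km0, c(1, 50)), c(1, 1))

  # events past the censoring age become censored at that age
  km60 <- kmEstimate(c(30, 65), c(TRUE, TRUE), censorAge = 60)
  expect_equal(km60@time, 30)
  expect_equal(km60@nEvent, 1)
  expect_equal(km60@surv, 0.5)

  expect_error(kmEstimate(numeric(0), logical(0)), "empty")
})

test_that("without censoring 1 - S(t) is exactly the empirical CDF", {
  set.seed(31)
  ages <- sample(1:60, 500, replace = TRUE)
  km <- kmEstimate(ages, rep(TRUE, 500), censorAge = Inf)
  for (t in c(5, 17, 33, 60)) {
    expect_equal(1 - kmSurvivalAt(km, t), mean(ages <= t), tolerance = 1e-12)
  }
})

test_that("KM agrees with an independent oracle and the survival package", {
  set.seed(32)
  n <- 1000
  time <- sample(1:60, n, replace = TRUE)
  event <- runif(n) < 0.4
  km <- kmEstimate(time, event, censorAge = 60)
  orc <- kmOracle(pmin(time, 60), event)
  expect_equal(km@time, orc$time)
  expect_equal(km@surv, orc$surv, tolerance = 1e-12)

  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  atEvents <- summary(fit, times = km@time)
  expect_equal(km@surv, atEvents$surv, tolerance = 1e-12)
})

test_that("KM is invariant to permutation of the input order", {
  set.seed(33)
  time <- sample(1:50, 300, replace = TRUE)
  event <- runif(300) < 0.3
  km1 <- kmEstimate(time, event)
  perm <- sample(300)
  km2 <- kmEstimate(time[perm], event[perm])
  expect_equal(km1@time, km2@time)
  expect_equal(km1@surv, km2@surv)
})

test_that("identical event patterns give hazard ratio 1", {
  time <- c(10, 20, 30, 40, 50, 60)
  event <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  hr <- kmHazardRatio(time, event, time, event)
  expect_equal(hr$hr, 1, tolerance = 1e-12)
  expect_true(hr$ci[1] < 1 && hr$ci[2] > 1)
})

test_that("a doubled constant hazard is recovered by the O/E estimator", {
  set.seed(34)
  n <- 30000
  lam <- 0.01
  tLow <- rexp(n, lam); tHigh <- rexp(n, 2 * lam)
  cens <- runif(n, 20, 60)
  obsL <- pmin(tLow, cens); evL <- tLow <= cens
  obsH <- pmin(tHigh, cens); evH <- tHigh <= cens
  hr <- kmHazardRatio(obsH, evH, obsL, evL, censorAge = Inf)
  expect_lt(abs(hr$hr - 2), 0.2)
  # cross-check against a proportional-hazards fit
  fit <- survival::coxph(survival::Surv(c(obsH, obsL), c(evH, evL)) ~
                           rep(c(1, 0), each = n))
  expect_lt(abs(hr$hr / exp(coef(fit)) - 1), 0.05)
})

test_that("zero events in a group yields an undefined hazard ratio", {
  expect_warning(
    hr <- kmHazardRatio(c(10, 20), c(TRUE, FALSE), c(15, 25), c(FALSE, FALSE)),
    "undefined")
  expect_true(is.na(hr$hr))
})

test_that("per-group curves use the paper's censoring rules", {
  d <- data.frame(
    id = sprintf("s%d", 1:6), sex = "male",
    enrolment_age = c(65, 65, 50, 50, 69, 45),
    has_diabetes = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
    age_at_diagnosis = c(30, 62, NA, 45, NA, NA),
    insulin_within_1yr = c(TRUE, TRUE, NA, TRUE, NA, NA),
    insulin_at_entry = c(TRUE, TRUE, NA, TRUE, NA, NA),
    bmi = 25, dka_admission = FALSE,
    score = c(2, 2, 2, 1, 1, 1),
    group = rep(c("high", "low"), each = 3), stringsAsFactors = FALSE)
  st <- new("StratifiedCohort", data = d, medianCutoff = 1.5)
  curves <- kmByGroup(st, censorAge = 60)
  # the age-62 diagnosis is censored at 60, not an event
  expect_equal(curves$high@time, 30)
  expect_equal(sum(curves$high@nEvent), 1)
  expect_equal(curves$low@time, 45)
  lt <- kmLifeTable(curves$low)
  expect_identical(names(lt),
                   c("group", "age", "n_at_risk", "n_events", "survival"))
})
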