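test_that("score components behave as documented on degenerate inputs", {
  w <- makeToyWeights(3)
  # all additive dosages zero, tags (0,0): pure HLA weight
  g0 <- GenotypeMatrix(matrix(0, 1, 5,
                              dimnames = list("s1", variantIds(w))))
  sv <- computeGRS(g0, w)
  expect_equal(unname(scores(sv)), w@diplotypeWeights[1, 1])
  # all dosage 2, equal weights, zero HLA weight: score = 2 * sum(w) = 2*3*w
  wEq <- makeToyWeights(3, weights = rep(0.2, 3))
  wEq@diplotypeWeights[] <- 0
  g2 <- GenotypeMatrix(matrix(c(2, 2, 2, 0, 0), 1, 5,
                              dimnames = list("s1", variantIds(wEq))))
  expect_equal(unname(scores(computeGRS(g2, wEq))), 6 * 0.2)
})

test_that("vectorised scoring matches a per-sample per-variant double loop", {
  set.seed(11)
  w <- makeToyWeights(29, weights = round(rnorm(29, 0.2, 0.1), 3))
  g <- makeToyGenotypes(10, w, seed = 12)
  sv <- computeGRS(g, w)
  d <- dosages(g)
  for (s in sampleIds(g)) {
    acc <- 0
    for (k in seq_len(nrow(w@additive))) {
      acc <- acc + d[s, w@additive$variant_id[k]] * w@additive$weight[k]
    }
    acc <- acc + w@diplotypeWeights[d[s, "t1"] + 1, d[s, "t2"] + 1]
    expect_equal(unname(scores(sv)[s]), acc, tolerance = 1e-12)
  }
  expect_equal(sv@score, sv@hlaPart + sv@additivePart)
})

test_that("the score is affine in each dosage and monotone for positive weights", {
  w <- makeToyWeights(5, weights = c(0.1, 0.2, 0.3, 0.4, 0.5))
  g <- makeToyGenotypes(6, w, seed = 4)
  base <- scores(computeGRS(g, w))
  d <- dosages(g)
  for (v in c("v2", "v5")) {
    delta <- ifelse(d[, v] <= 1, 0.5, -0.5)
    d2 <- d; d2[, v] <- d2[, v] + delta
    shifted <- scores(computeGRS(GenotypeMatrix(d2), w))
    wv <- w@additive$weight[w@additive$variant_id == v]
    expect_equal(unname(shifted - base), unname(delta * wv), tolerance = 1e-12)
    # raising a dosage never lowers the score when weights are positive
    up <- d; up[, v] <- pmin(up[, v] + 0.25, 2)
    expect_true(all(scores(computeGRS(GenotypeMatrix(up), w)) >= base - 1e-12))
  }
})

test_that("samples with missing genotypes are excluded unless imputation is enabled", {
  w <- makeToyWeights(2)
  d <- matrix(c(1, NA, 0, 1, 2, 2, 1, 1), 2, 4,
              dimnames = list(c("s1", "s2"), variantIds(w)))
  sv <- computeGRS(GenotypeMatrix(d), w)
  expect_identical(sv@excluded, "s2")
  expect_identical(sv@sampleIds, "s1")
  svImp <- computeGRS(GenotypeMatrix(d), w, impute = TRUE)
  expect_length(svImp@excluded, 0)
  # mean imputation: missing v1 dosage for s2 becomes the observed mean (1)
  expect_equal(unname(scores(svImp)["s2"] - scores(svImp)["s1"]),
               (1 - 1) * 0.1 + (1 - 0) * 0.2 +
                 (w@diplotypeWeights[3, 2] - w@diplotypeWeights[3, 2]),
               tolerance = 1e-12)
})

test_that("non-integer tag dosages are rounded ties-to-even with a warning when far off", {
  w <- makeToyWeights(1)
  d <- matrix(c(0, 0, 0.5, 1.5, 0.04, 0.3), 2, 3,
              dimnames = list(c("s1", "s2"), variantIds(w)))
  expect_warning(sv <- computeGRS(GenotypeMatrix(d), w), "hard call")
  # 0.5 -> 0 and 1.5 -> 2 (ties to even)
  expect_equal(sv@hlaPart,
               c(w@diplotypeWeights[1, 1], w@diplotypeWeights[3, 1]))
})

test_that("the HWE chi-square matches closed forms and the exact-test oracle", {
  r <- hweTest(c(25, 50, 25))
  expect_equal(r@chiSquare, 0)
  expect_equal(r@pValue, 1)

  r <- hweTest(c(50, 0, 50))          # complete heterozygote deficit: chi^2 = n
  expect_equal(r@chiSquare, 100)
  expect_lt(r@pValue, 1e-20)
  expect_lt(hweExactOracle(c(50, 0, 50)), 1e-10)

  expect_equal(hweTest(c(0, 0, 10))@pValue, 1)   # monomorphic
  expect_equal(hweTest(c(7, 0, 0))@chiSquare, 0)

  # agreement with the exact test where expected counts are comfortable
  set.seed(5)
  for (i in 1:20) {
    p <- runif(1, 0.2, 0.8); n <- 500
    counts <- as.vector(rmultinom(1, n, c((1 - p)^2, 2 * p * (1 - p), p^2)))
    pc <- hweTest(counts)@pValue
    pe <- hweExactOracle(counts)
    expect_lt(abs(log10(max(pc, 1e-12)) - log10(max(pe, 1e-12))), 1)
  }
})

test_that("HWE p-values are approximately uniform under equilibrium", {
  set.seed(21)
  pvals <- replicate(2000, {
    p <- runif(1, 0.1, 0.9)
    counts <- as.vector(rmultinom(1, 1e5, c((1 - p)^2, 2 * p * (1 - p), p^2)))
    hweTest(counts)@pValue
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.04)
})

test_that("HWE exclusion removes only departing variants and reports them", {
  w <- makeToyWeights(3)
  set.seed(8)
  n <- 2000
  d <- cbind(
    v1 = rbinom(n, 2, 0.3),
    v2 = sample(rep(c(0, 2), each = n / 2)),   # no heterozygotes at all
    v3 = rbinom(n, 2, 0.5),
    t1 = rbinom(n, 2, 0.1), t2 = rbinom(n, 2, 0.1)
  )
  rownames(d) <- sprintf("s%04d", seq_len(n))
  g <- GenotypeMatrix(d)
  out <- applyHweExclusions(w, g, threshold = 1e-6)
  expect_identical(out@additive$variant_id, c("v1", "v3"))
  excl <- attr(out, "hwe_exclusions")
  expect_identical(excl$variant_id, "v2")
  expect_lt(excl$p_value, 1e-40)
  # all in equilibrium: identity
  ok <- applyHweExclusions(makeToyWeights(1),
                           GenotypeMatrix(d[, c("v1", "t1", "t2")]),
                           threshold = 1e-6)
  expect_equal(nrow(ok@additive), 1)
  expect_error(applyHweExclusions(w, g, threshold = 0), "threshold")
  expect_warning(applyHweExclusions(w, g, threshold = 1), "removes every")
})
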