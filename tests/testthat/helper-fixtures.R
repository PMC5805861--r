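# fixtures and independent oracles used across the suite; everything is
# built in code at test time

makeToyWeights <- function(nVariants = 3,
                           weights = seq(0.1, by = 0.1,
                                         length.out = nVariants)) {
  VariantWeightSet(
    additive = data.frame(
      variant_id = sprintf("v%d", seq_len(nVariants)),
      effect_allele = rep(c("G", "C", "A"), length.out = nVariants),
      other_allele = rep(c("A", "T", "G"), length.out = nVariants),
      weight = weights,
      stringsAsFactors = FALSE
    ),
    hlaTagIds = c("t1", "t2"),
    diplotypeWeights = matrix(c(0, 1.6, 2.0, 1.5, 3.3, 2.7, 1.9, 2.6, 2.2),
                              3, 3)
  )
}

makeToyGenotypes <- function(nSamples, weightSet, seed = 1) {
  set.seed(seed)
  ids <- variantIds(weightSet)
  m <- matrix(sample(0:2, nSamples * length(ids), replace = TRUE),
              nSamples, length(ids),
              dimnames = list(sprintf("s%03d", seq_len(nSamples)), ids))
  GenotypeMatrix(m)
}

makeToyCohortData <- function(n = 10, seed = 1) {
  set.seed(seed)
  enrol <- sample(40:69, n, replace = TRUE)
  dia <- runif(n) < 0.3
  dx <- ifelse(dia, pmin(sample(1:60, n, replace = TRUE), enrol), NA)
  data.frame(
    id = sprintf("s%03d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    enrolment_age = enrol,
    has_diabetes = dia,
    age_at_diagnosis = dx,
    insulin_within_1yr = ifelse(dia, runif(n) < 0.5, NA),
    insulin_at_entry = ifelse(dia, runif(n) < 0.5, NA),
    bmi = round(rnorm(n, 28, 4), 2),
    dka_admission = dia & runif(n) < 0.1,
    stringsAsFactors = FALSE
  )
}

# stratified cohort constructed directly from per-group case ages, for
# worked-example arithmetic (non-cases padded so group sizes match)
makeStratifiedFromCases <- function(highAges, lowAges, nPerGroup = NULL) {
  if (is.null(nPerGroup)) nPerGroup <- max(length(highAges), length(lowAges))
  mk <- function(ages, grp, scoreVal, offset) {
    n <- nPerGroup
    dia <- c(rep(TRUE, length(ages)), rep(FALSE, n - length(ages)))
    data.frame(
      id = sprintf("%s%07d", grp, seq_len(n) + offset),
      sex = "male", enrolment_age = 69,
      has_diabetes = dia,
      age_at_diagnosis = c(ages, rep(NA, n - length(ages))),
      insulin_within_1yr = ifelse(dia, TRUE, NA),
      insulin_at_entry = ifelse(dia, TRUE, NA),
      bmi = 27, dka_admission = FALSE,
      score = scoreVal, group = grp, stringsAsFactors = FALSE
    )
  }
  d <- rbind(mk(highAges, "high", 2, 0), mk(lowAges, "low", 1, nPerGroup))
  new("StratifiedCohort", data = d, medianCutoff = 1.5)
}

# independent product-limit oracle: sequential at-risk bookkeeping over
# individuals sorted by follow-up time (ties: events processed together)
kmOracle <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- as.logical(event)[ord]
  n <- length(time)
  atRisk <- n
  s <- 1
  outT <- numeric(0); outS <- numeric(0)
  i <- 1
  while (i <= n) {
    t <- time[i]
    d <- 0; cns <- 0
    while (i <= n && time[i] == t) {
      if (event[i]) d <- d + 1 else cns <- cns + 1
      i <- i + 1
    }
    if (d > 0) {
      s <- s * (1 - d / atRisk)
      outT <- c(outT, t); outS <- c(outS, s)
    }
    atRisk <- atRisk - d - cns
  }
  list(time = outT, surv = outS)
}

# Levene-Haldane exact Hardy-Weinberg test (sum of probabilities <= that of
# the observed heterozygote count, conditional on the allele count)
hweExactOracle <- function(counts) {
  n <- sum(counts)
  nA <- 2 * counts[1] + counts[2]   # rarer-or-not allele count; symmetric
  nB <- 2 * n - nA
  het <- counts[2]
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  logProb <- function(h) {
    nAA <- (nA - h) / 2; nBB <- (nB - h) / 2
    lgamma(n + 1) - lgamma(nAA + 1) - lgamma(h + 1) - lgamma(nBB + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  }
  lp <- vapply(hets, logProb, numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- p[match(het, hets)]
  sum(p[p <= obs + 1e-12])
}

writeToyVcf <- function(path,
                        gtRows = list(
                          c("v1", "A", "G", "0/1", "1/1"),
                          c("v2", "G", "A", "1/1", "0/0"),
                          c("v3", "T", "C", "0/1", "1/1"),
                          c("t1", "T", "C", "0/0", "0/1"),
                          c("t2", "C", "T", "0/1", "./.")
                        )) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t")
  )
  body <- vapply(seq_along(gtRows), function(i) {
    r <- gtRows[[i]]
    paste(c("1", as.character(100 * i), r[1], r[2], r[3], ".", "PASS", ".",
            "GT", r[4], r[5]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

quietly <- function(expr) suppressWarnings(suppressMessages(expr))
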