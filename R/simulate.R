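#' Construct a SimulationConfig
#'
#' Defaults describe the study conditions the analysis assumes: a biobank of
#' 380,000 individuals enrolled at ages 40-69, type 1 diabetes prevalence
#' 0.34% with onset spread over ages 0-60 (60% at 30 or younger), type 2
#' diabetes prevalence 3.1% with onset incidence rising steeply with age
#' (95% diagnosed after 30), 4% of type 1 individuals scoring below the
#' population median genetic risk score, and class-conditional clinical
#' characteristics (BMI 27.4 (4.5) for type 1 vs 32.4 (6.0) kg/m^2 for
#' type 2; insulin within a year of diagnosis 97%/89% for young-/old-onset
#' type 1 vs 5.5% for type 2; ketoacidosis admission 10% vs 0.3%).
#'
#' @param nIndividuals cohort size (default 380,000).
#' @param alleleFreqs effect-allele frequencies for the additive variants;
#'   default `NULL` takes them from the weight set's `eaf` column at
#'   simulation time.
#' @param tagAlleleFreqs frequencies of the two HLA tag risk alleles.
#' @param t1dPrevalence,t2dPrevalence marginal class probabilities.
#' @param fracT1dBelowMedian expected fraction of type 1 individuals below
#'   the population median score.
#' @param t1dOnset,t2dOnset onset-age distribution specs (see
#'   [SimulationConfig-class]).
#' @param enrolmentAgeRange integer enrolment-age range.
#' @param bmiParams,insulin1yrProb,insulinEntryProb,dkaProb,maleProb
#'   class-conditional phenotype parameters.
#' @param missingRate uniform missingness rate for sex/BMI/insulin fields.
#' @param rngSeed integer seed.
#' @return A validated [SimulationConfig-class].
#' @export
simulationConfig <- function(nIndividuals = 380000,
                             alleleFreqs = numeric(0),
                             tagAlleleFreqs = c(0.12, 0.10),
                             t1dPrevalence = 0.0034,
                             t2dPrevalence = 0.031,
                             fracT1dBelowMedian = 0.04,
                             t1dOnset = list(prob_young = 0.6,
                                             young = c(0, 30),
                                             old = c(31, 60)),
                             t2dOnset = list(range = c(20, 60),
                                             prob_after_30 = 0.95),
                             enrolmentAgeRange = c(40, 69),
                             bmiParams = list(T1D = c(27.4, 4.5),
                                              T2D = c(32.4, 6.0),
                                              none = c(27, 4.5)),
                             insulin1yrProb = c(T1D_young = 0.97,
                                                T1D_old = 0.89,
                                                T2D = 0.055),
                             insulinEntryProb = c(T1D_young = 0.99,
                                                  T1D_old = 1.00,
                                                  T2D = 0.16),
                             dkaProb = c(T1D = 0.10, T2D = 0.003, none = 0),
                             maleProb = c(T1D = 0.59, T2D = 0.66, none = 0.46),
                             missingRate = 0,
                             rngSeed = 1) {
  new("SimulationConfig", nIndividuals = nIndividuals,
      alleleFreqs = alleleFreqs, tagAlleleFreqs = tagAlleleFreqs,
      t1dPrevalence = t1dPrevalence, t2dPrevalence = t2dPrevalence,
      fracT1dBelowMedian = fracT1dBelowMedian, t1dOnset = t1dOnset,
      t2dOnset = t2dOnset, enrolmentAgeRange = enrolmentAgeRange,
      bmiParams = bmiParams, insulin1yrProb = insulin1yrProb,
      insulinEntryProb = insulinEntryProb, dkaProb = dkaProb,
      maleProb = maleProb, missingRate = missingRate, rngSeed = rngSeed)
}

#' The synthetic weight fixture shipped with the package
#'
#' Loads the placeholder weight set under `inst/extdata` (29 additive
#' variants with plausible ln-OR magnitudes plus a 3 x 3 HLA diplotype
#' table whose largest weight is the compound heterozygote at both tags).
#' The values are synthetic stand-ins, not published constants; every
#' analysis in the package is weight-table-agnostic.
#'
#' @return A [VariantWeightSet-class].
#' @export
defaultWeights <- function() {
  readWeights(
    system.file("extdata", "grs_weights_synthetic.tsv", package = "grsExcess"),
    system.file("extdata", "hla_diplotype_weights_synthetic.tsv",
                package = "grsExcess")
  )
}

# integer onset-age sampler for the tilted-exponential type 2 distribution;
# rate solved so that P(onset > 30) = prob_after_30 on the integer support
t2dOnsetSampler <- function(spec) {
  ages <- seq(spec$range[1] + 1L, spec$range[2])
  target <- spec$prob_after_30
  f <- function(lam) {
    w <- exp(lam * ages)
    sum(w[ages > 30]) / sum(w) - target
  }
  lam <- stats::uniroot(f, c(1e-6, 1), tol = 1e-10)$root
  w <- exp(lam * ages)
  function(n) sample(ages, n, replace = TRUE, prob = w)
}

t1dOnsetSampler <- function(spec) {
  young <- seq(spec$young[1], spec$young[2])
  old <- seq(spec$old[1], spec$old[2])
  function(n) {
    isYoung <- stats::runif(n) < spec$prob_young
    out <- integer(n)
    out[isYoung] <- sample(young, sum(isYoung), replace = TRUE)
    out[!isYoung] <- sample(old, sum(!isYoung), replace = TRUE)
    out
  }
}

# redraw onset ages until onset <= enrolment, in vectorised rounds
rejectOnset <- function(onset, enrol, sampler, maxRounds = 1000) {
  bad <- which(onset > enrol)
  round <- 0
  while (length(bad) > 0) {
    round <- round + 1
    if (round > maxRounds) {
      stop("could not satisfy onset <= enrolment after ", maxRounds, " rounds")
    }
    onset[bad] <- sampler(length(bad))
    bad <- bad[onset[bad] > enrol[bad]]
  }
  onset
}

#' Simulate a synthetic biobank cohort
#'
#' Generates genotypes per variant under Hardy-Weinberg equilibrium at the
#' configured allele frequencies, assigns latent class labels (T1D / T2D /
#' none) by prevalence, and arranges type 1 individuals' scores by rejection
#' resampling of their genotype vectors so that an expected
#' `fracT1dBelowMedian` of them score below the population median; type 2
#' and unaffected individuals' genotypes are independent of their label, so
#' their score distributions are identical by construction. Onset ages,
#' enrolment ages and class-conditional clinical characteristics are then
#' drawn, with onset <= enrolment enforced by rejection redraw. The whole
#' cohort is reproducible from `rngSeed`.
#'
#' @param config a [SimulationConfig-class].
#' @param weights a [VariantWeightSet-class]; defaults to the synthetic
#'   fixture.
#' @param maxResample bound on per-individual genotype resampling attempts
#'   when arranging type 1 scores.
#' @return A [SyntheticCohort-class].
#' @export
simulateCohort <- function(config = simulationConfig(),
                           weights = defaultWeights(),
                           maxResample = 1000) {
  validObject(config)
  set.seed(config@rngSeed)
  n <- as.integer(config@nIndividuals)
  addIds <- weights@additive$variant_id
  freqs <- config@alleleFreqs
  if (length(freqs) == 0) {
    if (is.null(weights@additive$eaf)) {
      stop("no allele frequencies: supply alleleFreqs or a weight table with eaf")
    }
    freqs <- weights@additive$eaf
  }
  if (length(freqs) != length(addIds)) {
    stop("alleleFreqs must have one entry per additive variant")
  }
  allIds <- c(addIds, weights@hlaTagIds)
  allFreqs <- c(freqs, config@tagAlleleFreqs)
  nv <- length(allIds)

  dos <- matrix(0, n, nv,
                dimnames = list(sprintf("S%07d", seq_len(n)), allIds))
  for (j in seq_len(nv)) dos[, j] <- stats::rbinom(n, 2, allFreqs[j])

  addW <- weights@additive$weight
  scoreOf <- function(m) {
    g1 <- m[, length(addIds) + 1L]
    g2 <- m[, length(addIds) + 2L]
    hla <- weights@diplotypeWeights[cbind(g1 + 1, g2 + 1)]
    addp <- if (length(addIds)) {
      as.numeric(m[, seq_along(addIds), drop = FALSE] %*% addW)
    } else 0
    hla + addp
  }
  score <- scoreOf(dos)
  med <- stats::median(score)

  cls <- sample(c("T1D", "T2D", "none"), n, replace = TRUE,
                prob = c(config@t1dPrevalence, config@t2dPrevalence,
                         1 - config@t1dPrevalence - config@t2dPrevalence))

  # arrange type 1 scores around the median
  t1dIdx <- which(cls == "T1D")
  if (length(t1dIdx) > 0) {
    targetBelow <- stats::runif(length(t1dIdx)) < config@fracT1dBelowMedian
    for (k in seq_along(t1dIdx)) {
      i <- t1dIdx[k]
      want <- targetBelow[k]
      ok <- (score[i] < med) == want
      tries <- 0
      while (!ok) {
        tries <- tries + 1
        if (tries > maxResample) {
          stop("could not place a type 1 individual on the ",
               if (want) "low" else "high",
               " side of the median after ", maxResample, " attempts")
        }
        g <- stats::rbinom(nv, 2, allFreqs)
        s <- scoreOf(matrix(g, 1))
        if ((s < med) == want) {
          dos[i, ] <- g
          score[i] <- s
          ok <- TRUE
        }
      }
    }
  }

  enrol <- sample(seq(config@enrolmentAgeRange[1], config@enrolmentAgeRange[2]),
                  n, replace = TRUE)
  onset <- rep(NA_real_, n)
  s1 <- t1dOnsetSampler(config@t1dOnset)
  s2 <- t2dOnsetSampler(config@t2dOnset)
  i1 <- which(cls == "T1D"); i2 <- which(cls == "T2D")
  if (length(i1)) onset[i1] <- rejectOnset(s1(length(i1)), enrol[i1], s1)
  if (length(i2)) onset[i2] <- rejectOnset(s2(length(i2)), enrol[i2], s2)

  young <- !is.na(onset) & onset <= 30
  p1 <- config@insulin1yrProb; pe <- config@insulinEntryProb
  ins1 <- rep(NA, n); insE <- rep(NA, n)
  pick <- function(idx, p) as.logical(stats::rbinom(length(idx), 1, p))
  ins1[i1] <- pick(i1, ifelse(young[i1], p1[["T1D_young"]], p1[["T1D_old"]]))
  ins1[i2] <- pick(i2, p1[["T2D"]])
  insE[i1] <- pick(i1, ifelse(young[i1], pe[["T1D_young"]], pe[["T1D_old"]]))
  insE[i2] <- pick(i2, pe[["T2D"]])

  bp <- config@bmiParams
  bmi <- numeric(n)
  for (cl in c("T1D", "T2D", "none")) {
    idx <- which(cls == cl)
    bmi[idx] <- stats::rnorm(length(idx), bp[[cl]][1], bp[[cl]][2])
  }
  dka <- as.logical(stats::rbinom(n, 1, config@dkaProb[
    match(cls, c("T1D", "T2D", "none"))]))
  sex <- ifelse(stats::runif(n) < config@maleProb[
    match(cls, c("T1D", "T2D", "none"))], "male", "female")

  if (config@missingRate > 0) {
    blank <- function(x) {
      x[stats::runif(n) < config@missingRate] <- NA
      x
    }
    sex <- blank(sex); bmi <- blank(bmi)
    ins1 <- blank(ins1); insE <- blank(insE)
    # keep non-diabetic insulin fields missing regardless
    ins1[cls == "none"] <- NA; insE[cls == "none"] <- NA
  }

  d <- data.frame(
    id = rownames(dos), sex = sex, enrolment_age = enrol,
    has_diabetes = cls != "none", age_at_diagnosis = onset,
    insulin_within_1yr = ins1, insulin_at_entry = insE,
    bmi = bmi, dka_admission = dka, stringsAsFactors = FALSE
  )
  new("SyntheticCohort", genotypes = GenotypeMatrix(dos),
      cohort = CohortTable(d),
      truth = data.frame(id = rownames(dos), class = cls,
                         stringsAsFactors = FALSE))
}

#' Truth summary of a synthetic cohort
#'
#' The recovery target for downstream estimates: per-class counts, diagnosed
#' counts per age band, and class-conditional phenotype summaries.
#'
#' @param synth a [SyntheticCohort-class].
#' @param bandEdges diagnosis-age band edges (right-closed bands).
#' @return list of data.frames: `classCounts`, `bandCounts`,
#'   `phenotypes`.
#' @export
truthReport <- function(synth, bandEdges = c(0, 30, 60)) {
  stopifnot(is(synth, "SyntheticCohort"))
  d <- synth@cohort@data
  tr <- synth@truth
  cls <- tr$class[match(d$id, tr$id)]
  classCounts <- as.data.frame(table(class = factor(cls, c("T1D", "T2D", "none"))),
                               responseName = "n")
  dia <- d[cls != "none", ]
  diaCls <- cls[cls != "none"]
  if (nrow(dia) > 0) {
    band <- assignBands(dia$age_at_diagnosis, bandEdges)
    bandCounts <- as.data.frame(table(class = factor(diaCls, c("T1D", "T2D")),
                                      band = band), responseName = "n")
    phen <- do.call(rbind, lapply(c("T1D", "T2D"), function(cl) {
      x <- dia[diaCls == cl, ]
      data.frame(class = cl, n = nrow(x),
                 mean_onset_age = mean(x$age_at_diagnosis),
                 mean_bmi = mean(x$bmi, na.rm = TRUE),
                 prop_insulin_1yr = mean(x$insulin_within_1yr, na.rm = TRUE),
                 prop_insulin_entry = mean(x$insulin_at_entry, na.rm = TRUE),
                 prop_dka = mean(x$dka_admission), stringsAsFactors = FALSE)
    }))
  } else {
    bandCounts <- data.frame(class = character(0), band = character(0),
                             n = integer(0))
    phen <- data.frame()
  }
  list(classCounts = classCounts, bandCounts = bandCounts, phenotypes = phen)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `genotypes.tsv` (sample id + one dosage column per variant),
#' `cohort.csv` and `truth.csv` into a directory.
#'
#' @param synth a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticCohort <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- as.data.frame(synth@genotypes@dosages)
  g <- cbind(sample_id = rownames(g), g)
  utils::write.table(g, file.path(dir, "genotypes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeCohort(synth@cohort, file.path(dir, "cohort.csv"))
  utils::write.csv(synth@truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
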