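#' @import methods
NULL

VALID_BASES <- c("A", "C", "G", "T")

#' VariantWeightSet: the weights defining a type 1 diabetes genetic risk score
#'
#' Holds the additive component of the score (one row per variant: effect
#' allele, other allele and a weight in natural-log odds-ratio units) together
#' with the non-additive HLA-DR diplotype component: a 3 x 3 weight table
#' indexed by the hard-call genotypes (0, 1 or 2 copies of the effect allele)
#' at the two HLA tag variants (by default rs2187668, tagging DR3, and
#' rs7454108, tagging DR4-DQ8).
#'
#' @slot additive data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `weight` and optionally `eaf` (effect-allele frequency,
#'   used only by the simulator and by mean-imputation).
#' @slot hlaTagIds character(2), variant ids of the two HLA tag variants.
#' @slot diplotypeWeights 3 x 3 numeric matrix; `diplotypeWeights[g1 + 1,
#'   g2 + 1]` is the HLA score contribution for genotype `g1` at the first tag
#'   and `g2` at the second. All nine cells must be present.
#'
#' @seealso [readWeights()], [computeGRS()]
#' @export
setClass("VariantWeightSet",
  slots = c(
    additive = "data.frame",
    hlaTagIds = "character",
    diplotypeWeights = "matrix"
  )
)

setValidity("VariantWeightSet", function(object) {
  msg <- character()
  add <- object@additive
  need <- c("variant_id", "effect_allele", "other_allele", "weight")
  if (!all(need %in% names(add))) {
    return(paste("additive table must have columns:", paste(need, collapse = ", ")))
  }
  dup <- add$variant_id[duplicated(add$variant_id)]
  if (length(dup) > 0) {
    msg <- c(msg, paste0("duplicate additive variant id(s): ",
                         paste(unique(dup), collapse = ", ")))
  }
  if (length(object@hlaTagIds) != 2) {
    msg <- c(msg, "hlaTagIds must have length 2")
  }
  inboth <- intersect(object@hlaTagIds, add$variant_id)
  if (length(inboth) > 0) {
    msg <- c(msg, paste0("HLA tag variant(s) also listed as additive: ",
                         paste(inboth, collapse = ", ")))
  }
  if (nrow(add) > 0) {
    badA <- !(add$effect_allele %in% VALID_BASES) | !(add$other_allele %in% VALID_BASES)
    if (any(badA)) {
      msg <- c(msg, paste0("non-ACGT allele for variant(s): ",
                           paste(add$variant_id[badA], collapse = ", ")))
    }
    if (!is.numeric(add$weight) || anyNA(add$weight)) {
      msg <- c(msg, "additive weights must be numeric and non-missing")
    }
  }
  dw <- object@diplotypeWeights
  if (!is.numeric(dw) || !identical(dim(dw), c(3L, 3L))) {
    msg <- c(msg, "diplotypeWeights must be a numeric 3 x 3 matrix")
  } else if (anyNA(dw)) {
    idx <- which(is.na(dw), arr.ind = TRUE)
    pairs <- apply(idx, 1L, function(i) paste0("(", i[1] - 1L, ",", i[2] - 1L, ")"))
    msg <- c(msg, paste0("missing diplotype weight for genotype pair(s): ",
                         paste(pairs, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a VariantWeightSet
#'
#' @param additive data.frame of additive variants (see class slots).
#' @param hlaTagIds character(2) tag variant ids.
#' @param diplotypeWeights 3 x 3 numeric matrix of HLA diplotype weights,
#'   rows = genotype at the first tag (0,1,2), columns = genotype at the
#'   second tag.
#' @return A validated [VariantWeightSet-class] object.
#' @export
VariantWeightSet <- function(additive,
                             hlaTagIds = c("rs2187668", "rs7454108"),
                             diplotypeWeights) {
  additive <- as.data.frame(additive)
  if (nrow(additive) > 0) {
    additive$variant_id <- as.character(additive$variant_id)
    additive$effect_allele <- toupper(as.character(additive$effect_allele))
    additive$other_allele <- toupper(as.character(additive$other_allele))
    additive$weight <- as.numeric(additive$weight)
  }
  dw <- as.matrix(diplotypeWeights)
  storage.mode(dw) <- "double"
  dimnames(dw) <- list(g1 = 0:2, g2 = 0:2)
  new("VariantWeightSet", additive = additive,
      hlaTagIds = as.character(hlaTagIds), diplotypeWeights = dw)
}

#' GenotypeMatrix: effect-allele dosages per sample and variant
#'
#' A thin validated container around a numeric samples x variants matrix of
#' effect-allele dosages. Values are hard calls (0/1/2) or imputed dosages in
#' \[0, 2\]; `NA` marks a missing call. Orientation relative to a weight
#' set's effect alleles is resolved at read time (see [readGenotypes()]).
#'
#' @slot dosages numeric matrix, rownames = sample ids, colnames = variant ids.
#' @export
setClass("GenotypeMatrix", slots = c(dosages = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosages
  msg <- character()
  if (!is.numeric(d)) msg <- c(msg, "dosages must be numeric")
  if (is.null(rownames(d)) || is.null(colnames(d))) {
    msg <- c(msg, "dosages must have sample ids as rownames and variant ids as colnames")
  } else {
    if (anyDuplicated(rownames(d))) msg <- c(msg, "sample ids must be unique")
    if (anyDuplicated(colnames(d))) msg <- c(msg, "variant ids must be unique")
  }
  rng <- suppressWarnings(range(d, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    msg <- c(msg, "dosages must lie in [0, 2]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosages numeric matrix (samples x variants) with dimnames.
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(dosages) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  new("GenotypeMatrix", dosages = dosages)
}

#' CohortTable: per-individual phenotypes with censoring information
#'
#' One row per individual: `id`, `sex` ("male"/"female"/NA),
#' `enrolment_age` (years), `has_diabetes`, `age_at_diagnosis` (years, NA for
#' unaffected), `insulin_within_1yr`, `insulin_at_entry`, `bmi` (kg/m^2) and
#' `dka_admission` (hospital-coded diabetic ketoacidosis admission).
#' Rows violating the table invariants (diagnosis age after enrolment,
#' diagnosis fields present without a diabetes diagnosis, non-positive
#' enrolment age) are removed at construction and kept, with the rule that
#' fired, in the `removed` slot.
#'
#' @slot data data.frame of retained rows.
#' @slot removed data.frame of removed rows plus a `removal_rule` column.
#' @export
setClass("CohortTable", slots = c(data = "data.frame", removed = "data.frame"))

COHORT_COLUMNS <- c("id", "sex", "enrolment_age", "has_diabetes",
                    "age_at_diagnosis", "insulin_within_1yr",
                    "insulin_at_entry", "bmi", "dka_admission")

setValidity("CohortTable", function(object) {
  d <- object@data
  msg <- character()
  miss <- setdiff(COHORT_COLUMNS, names(d))
  if (length(miss)) {
    return(paste0("missing cohort column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(d$id)) msg <- c(msg, "individual ids must be unique")
  if (nrow(d) > 0) {
    if (any(d$enrolment_age <= 0, na.rm = TRUE)) {
      msg <- c(msg, "enrolment_age must be positive")
    }
    dia <- which(d$has_diabetes %in% TRUE)
    if (length(dia)) {
      bad <- is.na(d$age_at_diagnosis[dia]) |
        d$age_at_diagnosis[dia] > d$enrolment_age[dia]
      if (any(bad)) {
        msg <- c(msg, "diabetic rows must have age_at_diagnosis <= enrolment_age")
      }
    }
    non <- which(!(d$has_diabetes %in% TRUE))
    if (length(non)) {
      present <- !is.na(d$age_at_diagnosis[non]) |
        !is.na(d$insulin_within_1yr[non]) | !is.na(d$insulin_at_entry[non])
      if (any(present)) {
        msg <- c(msg, "non-diabetic rows must have diagnosis-dependent fields missing")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CohortTable, removing invariant-violating rows
#'
#' @param data data.frame with the cohort columns (see class description).
#' @return A [CohortTable-class]; removed rows are logged in `removed(x)`.
#' @export
CohortTable <- function(data) {
  data <- as.data.frame(data)
  miss <- setdiff(COHORT_COLUMNS, names(data))
  if (length(miss)) {
    stop("missing cohort column(s): ", paste(miss, collapse = ", "))
  }
  data <- data[COHORT_COLUMNS]
  data$id <- as.character(data$id)

  rule <- rep(NA_character_, nrow(data))
  mark <- function(cond, label) ifelse(is.na(rule) & cond, label, rule)
  rule <- mark(is.na(data$enrolment_age) | data$enrolment_age <= 0,
               "nonpositive_enrolment_age")
  isDia <- data$has_diabetes %in% TRUE
  rule <- mark(isDia & is.na(data$age_at_diagnosis), "diabetic_missing_diagnosis_age")
  rule <- mark(isDia & !is.na(data$age_at_diagnosis) &
                 data$age_at_diagnosis > data$enrolment_age,
               "diagnosis_after_enrolment")
  rule <- mark(!isDia & (!is.na(data$age_at_diagnosis) |
                           !is.na(data$insulin_within_1yr) |
                           !is.na(data$insulin_at_entry)),
               "diagnosis_fields_without_diabetes")
  rule <- mark(duplicated(data$id), "duplicate_id")

  keep <- is.na(rule)
  removed <- data[!keep, , drop = FALSE]
  if (nrow(removed) > 0) removed$removal_rule <- rule[!keep]
  else removed$removal_rule <- character(0)
  new("CohortTable", data = data[keep, , drop = FALSE], removed = removed)
}

#' ScoreVector: per-sample genetic risk scores
#'
#' @slot sampleIds character ids of scored samples.
#' @slot score numeric total score (HLA part + additive part), ln-OR units.
#' @slot hlaPart,additivePart numeric score components, same order.
#' @slot excluded character ids of samples that could not be scored (missing
#'   genotypes with imputation disabled).
#' @export
setClass("ScoreVector",
  slots = c(sampleIds = "character", score = "numeric",
            hlaPart = "numeric", additivePart = "numeric",
            excluded = "character")
)

setValidity("ScoreVector", function(object) {
  n <- length(object@sampleIds)
  if (length(object@score) != n || length(object@hlaPart) != n ||
      length(object@additivePart) != n) {
    return("score, hlaPart and additivePart must match sampleIds in length")
  }
  if (anyDuplicated(object@sampleIds)) return("sample ids must be unique")
  if (n > 0) {
    if (any(!is.finite(object@score))) return("scores must be finite")
    if (max(abs(object@score - (object@hlaPart + object@additivePart))) > 1e-9) {
      return("score must equal hlaPart + additivePart")
    }
  }
  TRUE
})

#' HweResult: Hardy-Weinberg equilibrium test for one variant
#'
#' @slot variantId character(1).
#' @slot counts integer(3): homozygous-reference, heterozygous,
#'   homozygous-alternate genotype counts.
#' @slot chiSquare 1-df goodness-of-fit statistic.
#' @slot pValue upper-tail p-value.
#' @export
setClass("HweResult",
  slots = c(variantId = "character", counts = "numeric",
            chiSquare = "numeric", pValue = "numeric")
)

setValidity("HweResult", function(object) {
  if (length(object@counts) != 3 || any(object@counts < 0)) {
    return("counts must be three non-negative genotype counts")
  }
  if (object@pValue < 0 || object@pValue > 1) return("pValue must be in [0, 1]")
  if (object@chiSquare < 0) return("chiSquare must be non-negative")
  TRUE
})

#' StratifiedCohort: cohort joined to scores and split at the median score
#'
#' @slot data data.frame: cohort columns plus `score` and `group`
#'   ("high"/"low").
#' @slot medianCutoff numeric(1), the median score used as the cutpoint.
#' @export
setClass("StratifiedCohort",
  slots = c(data = "data.frame", medianCutoff = "numeric")
)

setValidity("StratifiedCohort", function(object) {
  d <- object@data
  if (!all(c("id", "score", "group") %in% names(d))) {
    return("data must contain id, score and group columns")
  }
  if (!all(d$group %in% c("high", "low"))) {
    return("group must be 'high' or 'low' for every individual")
  }
  nTied <- sum(d$score == object@medianCutoff)
  if (abs(sum(d$group == "high") - sum(d$group == "low")) > max(1L, nTied)) {
    return("group sizes may differ by at most the number of median ties")
  }
  TRUE
})

#' KMCurve: a Kaplan-Meier product-limit survival curve
#'
#' @slot time ascending distinct event ages (years).
#' @slot nRisk number at risk just before each time.
#' @slot nEvent number of events at each time.
#' @slot surv product-limit survival estimate at each time.
#' @slot label group label (e.g. "high"/"low").
#' @export
setClass("KMCurve",
  slots = c(time = "numeric", nRisk = "numeric", nEvent = "numeric",
            surv = "numeric", label = "character")
)

setValidity("KMCurve", function(object) {
  n <- length(object@time)
  if (length(object@nRisk) != n || length(object@nEvent) != n ||
      length(object@surv) != n) {
    return("time, nRisk, nEvent and surv must have equal length")
  }
  if (n > 0) {
    if (is.unsorted(object@time, strictly = TRUE)) return("times must be strictly ascending")
    if (any(object@nEvent > object@nRisk)) return("events cannot exceed number at risk")
    if (any(object@surv < 0 | object@surv > 1)) return("survival must lie in [0, 1]")
    if (any(diff(object@surv) > 1e-12)) return("survival must be non-increasing")
  }
  TRUE
})

#' ExcessEstimate: the subtraction estimate of genetically defined type 1 diabetes
#'
#' @slot nHighCases,nLowCases diabetes case counts (within the censoring
#'   window) in the high- and low-score halves.
#' @slot excess `nHighCases - nLowCases`; may be negative under sampling
#'   noise and is never clamped.
#' @slot totalCases all diabetes cases in the censoring window.
#' @slot proportion excess as a percentage of all cases.
#' @slot proportionCI numeric(2) confidence interval for the percentage.
#' @slot byBand per-age-band breakdown (see [excessByBand()]).
#' @export
setClass("ExcessEstimate",
  slots = c(nHighCases = "numeric", nLowCases = "numeric", excess = "numeric",
            totalCases = "numeric", proportion = "numeric",
            proportionCI = "numeric", byBand = "data.frame")
)

setValidity("ExcessEstimate", function(object) {
  if (object@excess != object@nHighCases - object@nLowCases) {
    return("excess must equal nHighCases - nLowCases")
  }
  if (nrow(object@byBand) > 0) {
    if (sum(object@byBand$excess) != object@excess) {
      return("band excesses must sum to the overall excess")
    }
    if (sum(object@byBand$total) != object@totalCases) {
      return("band totals must sum to totalCases")
    }
  }
  TRUE
})

#' SimulationConfig: parameters of the synthetic biobank cohort generator
#'
#' Defaults emulate the study conditions of a UK-Biobank-scale cross-sectional
#' cohort: genotypes in Hardy-Weinberg equilibrium, a small type 1 diabetes
#' subpopulation whose genetic risk scores almost all lie above the
#' population median, a type 2 diabetes subpopulation whose scores are
#' distributed exactly as the unaffected population, onset ages spread over
#' 0-60 for type 1 and rising steeply with age for type 2, enrolment between
#' ages 40 and 69, and class-conditional clinical characteristics.
#'
#' @slot nIndividuals cohort size.
#' @slot alleleFreqs effect-allele frequencies of the additive variants.
#' @slot tagAlleleFreqs effect-allele frequencies of the two HLA tag variants.
#' @slot t1dPrevalence,t2dPrevalence marginal class probabilities.
#' @slot fracT1dBelowMedian expected fraction of type 1 individuals whose
#'   score falls below the population median (default 0.04).
#' @slot t1dOnset list(prob_young, young = c(lo, hi), old = c(lo, hi)):
#'   mixture of uniforms for type 1 onset age.
#' @slot t2dOnset list(range = c(lo, hi), prob_after_30): exponential-tilted
#'   onset density on `range` with rate solved so
#'   P(onset > 30) = prob_after_30.
#' @slot enrolmentAgeRange integer uniform enrolment-age range (years).
#' @slot bmiParams list of c(mean, sd) per class (T1D, T2D, none), kg/m^2.
#' @slot insulin1yrProb probabilities of insulin within 1 year of diagnosis:
#'   T1D_young (onset <= 30), T1D_old, T2D.
#' @slot insulinEntryProb probabilities of insulin use at study entry, same
#'   classes.
#' @slot dkaProb probability of a ketoacidosis admission per class.
#' @slot maleProb probability male per class.
#' @slot missingRate optional uniform missingness rate applied to sex, bmi
#'   and insulin fields (default 0).
#' @slot rngSeed integer seed; identical seeds give identical cohorts.
#' @export
setClass("SimulationConfig",
  slots = c(
    nIndividuals = "numeric", alleleFreqs = "numeric",
    tagAlleleFreqs = "numeric", t1dPrevalence = "numeric",
    t2dPrevalence = "numeric", fracT1dBelowMedian = "numeric",
    t1dOnset = "list", t2dOnset = "list", enrolmentAgeRange = "numeric",
    bmiParams = "list", insulin1yrProb = "numeric",
    insulinEntryProb = "numeric", dkaProb = "numeric", maleProb = "numeric",
    missingRate = "numeric", rngSeed = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@t1dPrevalence < 0 || object@t2dPrevalence < 0 ||
      object@t1dPrevalence + object@t2dPrevalence >= 1) {
    msg <- c(msg, "prevalences must be non-negative and sum to < 1")
  }
  if (object@fracT1dBelowMedian < 0 || object@fracT1dBelowMedian > 1) {
    msg <- c(msg, "fracT1dBelowMedian must lie in [0, 1]")
  }
  fr <- c(object@alleleFreqs, object@tagAlleleFreqs)
  if (any(fr <= 0 | fr >= 1)) msg <- c(msg, "allele frequencies must lie in (0, 1)")
  pr <- c(object@insulin1yrProb, object@insulinEntryProb, object@dkaProb,
          object@maleProb, object@missingRate)
  if (any(pr < 0 | pr > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: simulated genotypes, phenotypes and truth labels
#'
#' @slot genotypes a [GenotypeMatrix-class].
#' @slot cohort a [CohortTable-class].
#' @slot truth data.frame (id, class) with class in T1D/T2D/none; truth
#'   labels exist only in simulation and are used for recovery checks.
#' @export
setClass("SyntheticCohort",
  slots = c(genotypes = "GenotypeMatrix", cohort = "CohortTable",
            truth = "data.frame")
)

setValidity("SyntheticCohort", function(object) {
  tr <- object@truth
  if (!all(c("id", "class") %in% names(tr))) return("truth needs id and class")
  if (!all(tr$class %in% c("T1D", "T2D", "none"))) {
    return("truth class must be T1D, T2D or none")
  }
  d <- object@cohort@data
  m <- match(d$id, tr$id)
  if (anyNA(m)) return("every cohort individual needs a truth label")
  if (any((tr$class[m] != "none") != (d$has_diabetes %in% TRUE))) {
    return("truth label inconsistent with has_diabetes")
  }
  TRUE
})

#' PipelineConfig: analysis-stage settings
#'
#' @slot censorAge administrative censoring age (years, default 60).
#' @slot ageBandEdges edges of the headline diagnosis-age bands
#'   (default c(0, 30, 60): bands 0-30 and 31-60, right-closed on integer
#'   ages).
#' @slot decadeEdges edges for per-decade incidence output.
#' @slot nTestedCharacteristics Bonferroni denominator (default 7).
#' @slot alpha nominal test level.
#' @slot rngSeed seed for bootstrap resampling.
#' @slot hweExclusionP Hardy-Weinberg exclusion threshold (default 1e-6).
#' @export
setClass("PipelineConfig",
  slots = c(censorAge = "numeric", ageBandEdges = "numeric",
            decadeEdges = "numeric", nTestedCharacteristics = "numeric",
            alpha = "numeric", rngSeed = "numeric", hweExclusionP = "numeric"),
  prototype = prototype(censorAge = 60, ageBandEdges = c(0, 30, 60),
                        decadeEdges = seq(0, 60, 10),
                        nTestedCharacteristics = 7, alpha = 0.05,
                        rngSeed = 1, hweExclusionP = 1e-6)
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (is.unsorted(object@ageBandEdges, strictly = TRUE)) {
    msg <- c(msg, "ageBandEdges must be strictly increasing")
  }
  if (is.unsorted(object@decadeEdges, strictly = TRUE)) {
    msg <- c(msg, "decadeEdges must be strictly increasing")
  }
  if (object@alpha <= 0 || object@alpha >= 1) msg <- c(msg, "alpha must be in (0, 1)")
  if (object@hweExclusionP <= 0 || object@hweExclusionP > 1) {
    msg <- c(msg, "hweExclusionP must be in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PipelineConfig
#'
#' @param ... named slot overrides, e.g. `censorAge = 60`.
#' @return A [PipelineConfig-class] object.
#' @export
pipelineConfig <- function(...) new("PipelineConfig", ...)
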