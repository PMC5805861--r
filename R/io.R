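MISSING_MARKERS <- c("don't know", "do not know", "prefer not to answer",
                     "na", "n/a", "")

BASE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# delimiter sniffing: tab, comma, else any whitespace
readDelimAuto <- function(path, colClasses = NA) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = colClasses)
}

#' Read a variant-weight table (and its HLA diplotype companion)
#'
#' The additive table is tab- or comma-separated with a header and columns
#' `variant_id`, `effect_allele`, `other_allele`, `weight` (ln odds-ratio
#' units) and optionally `eaf`. The HLA diplotype weights come either from a
#' companion table with columns `g1`, `g2`, `weight` covering all nine
#' genotype pairs, or inline as rows whose `variant_id` has the form
#' `"g1,g2"`.
#'
#' @param path path to the additive weight table.
#' @param diplotypePath path to the diplotype weight table.
#' @param hlaTagIds character(2), ids of the HLA tag variants.
#' @return A validated [VariantWeightSet-class]; additive row order is
#'   preserved.
#' @export
readWeights <- function(path, diplotypePath,
                        hlaTagIds = c("rs2187668", "rs7454108")) {
  if (!file.exists(path)) stop("weights file not found: ", path)
  if (!file.exists(diplotypePath)) {
    stop("diplotype weights file not found: ", diplotypePath)
  }
  add <- readDelimAuto(path)
  dip <- readDelimAuto(diplotypePath)
  need <- c("g1", "g2", "weight")
  if (!all(need %in% names(dip))) {
    stop("diplotype table must have columns g1, g2, weight")
  }
  dw <- matrix(NA_real_, 3, 3)
  for (i in seq_len(nrow(dip))) {
    g1 <- dip$g1[i]; g2 <- dip$g2[i]
    if (!(g1 %in% 0:2) || !(g2 %in% 0:2)) {
      stop("diplotype genotypes must be 0, 1 or 2 (row ", i, ")")
    }
    dw[g1 + 1, g2 + 1] <- dip$weight[i]
  }
  VariantWeightSet(additive = add, hlaTagIds = hlaTagIds, diplotypeWeights = dw)
}

parseLogical <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[x %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

mapMissing <- function(x) {
  x <- as.character(x)
  x[tolower(trimws(x)) %in% MISSING_MARKERS] <- NA
  x
}

#' Read a cohort phenotype table
#'
#' Reads a delimited phenotype table with the columns of
#' [CohortTable-class]. Questionnaire non-answers ("don't know",
#' "prefer not to answer") are mapped to missing; rows violating the cohort
#' invariants are removed and logged (retrievable via [removedRows()]).
#'
#' @param path path to a CSV/TSV phenotype file.
#' @return A [CohortTable-class].
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- readDelimAuto(path, colClasses = "character")
  miss <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(miss)) stop("missing cohort column(s): ", paste(miss, collapse = ", "))
  for (col in COHORT_COLUMNS) raw[[col]] <- mapMissing(raw[[col]])
  d <- data.frame(
    id = raw$id,
    sex = tolower(raw$sex),
    enrolment_age = as.numeric(raw$enrolment_age),
    has_diabetes = parseLogical(raw$has_diabetes),
    age_at_diagnosis = as.numeric(raw$age_at_diagnosis),
    insulin_within_1yr = parseLogical(raw$insulin_within_1yr),
    insulin_at_entry = parseLogical(raw$insulin_at_entry),
    bmi = as.numeric(raw$bmi),
    dka_admission = parseLogical(raw$dka_admission),
    stringsAsFactors = FALSE
  )
  d$sex[!(d$sex %in% c("male", "female"))] <- NA
  d$has_diabetes[is.na(d$has_diabetes)] <- FALSE
  d$dka_admission[is.na(d$dka_admission)] <- FALSE
  CohortTable(d)
}

#' Write a cohort table to CSV
#'
#' @param cohort a [CohortTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  stopifnot(is(cohort, "CohortTable"))
  utils::write.csv(cohort@data, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read genotypes from a plain matrix or a VCF, oriented to a weight set
#'
#' For a plain table (rows = samples, first column = sample id, remaining
#' columns = variants) values are taken to be effect-allele dosages already.
#' For a VCF (`.vcf` / `.vcf.gz`), the count of the weight set's effect
#' allele is derived from the GT field: if the effect/other alleles match
#' REF/ALT swapped, dosages are flipped (`d -> 2 - d`); alleles that match
#' only on the opposite strand are complemented first; strand-ambiguous A/T
#' and C/G variants are rejected because their orientation cannot be
#' resolved.
#'
#' @param path genotype file.
#' @param weights a [VariantWeightSet-class]; its additive and tag variants
#'   are the wanted set and define effect-allele orientation for VCF input.
#' @return A [GenotypeMatrix-class] restricted to the wanted variants, in
#'   weight-set order.
#' @export
readGenotypes <- function(path, weights) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  stopifnot(is(weights, "VariantWeightSet"))
  wanted <- variantIds(weights)
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE)) {
    gm <- readGenotypesVcf(path, weights)
  } else {
    tab <- readDelimAuto(path)
    ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    missing <- setdiff(wanted, colnames(m))
    if (length(missing)) {
      stop("wanted variant(s) absent from genotype file: ",
           paste(missing, collapse = ", "))
    }
    gm <- GenotypeMatrix(m[, wanted, drop = FALSE])
  }
  gm
}

gtToAltCount <- function(gt) {
  # GT strings like 0/1, 1|1, ./.
  out <- rep(NA_real_, length(gt))
  out[gt %in% c("0/0", "0|0")] <- 0
  out[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  out[gt %in% c("1/1", "1|1")] <- 2
  out
}

readGenotypesVcf <- function(path, weights) {
  vcf <- VariantAnnotation::readVcf(path)
  ids <- rownames(vcf)
  wanted <- variantIds(weights)
  missing <- setdiff(wanted, ids)
  if (length(missing)) {
    stop("wanted variant(s) absent from VCF: ", paste(missing, collapse = ", "))
  }
  keep <- match(wanted, ids)
  ref <- as.character(VariantAnnotation::ref(vcf))[keep]
  altList <- VariantAnnotation::alt(vcf)[keep]
  alt <- vapply(seq_along(altList), function(i) {
    a <- as.character(altList[[i]])
    if (length(a) != 1) {
      stop("multi-allelic record not supported for variant ", wanted[i])
    }
    a
  }, character(1))

  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  altCount <- matrix(gtToAltCount(as.vector(gt)), nrow = nrow(gt),
                     dimnames = dimnames(gt))   # variants x samples

  # effect/other alleles per wanted variant
  addIdx <- match(wanted, weights@additive$variant_id)
  ea <- ifelse(is.na(addIdx), NA_character_, weights@additive$effect_allele[addIdx])
  oa <- ifelse(is.na(addIdx), NA_character_, weights@additive$other_allele[addIdx])
  # tag variants: orient by the ALT allele as effect (no weight-table alleles);
  # treated as already effect-oriented in the VCF
  tagIdx <- which(is.na(addIdx))

  flip <- logical(length(wanted))
  for (i in setdiff(seq_along(wanted), tagIdx)) {
    if (ea[i] == BASE_COMPLEMENT[[oa[i]]]) {
      stop("variant ", wanted[i], " is strand-ambiguous (", ea[i], "/", oa[i],
           "); orientation cannot be resolved")
    }
    if (ea[i] == alt[i] && oa[i] == ref[i]) {
      flip[i] <- FALSE
    } else if (ea[i] == ref[i] && oa[i] == alt[i]) {
      flip[i] <- TRUE
    } else {
      cea <- BASE_COMPLEMENT[[ea[i]]]; coa <- BASE_COMPLEMENT[[oa[i]]]
      if (cea == alt[i] && coa == ref[i]) {
        flip[i] <- FALSE
      } else if (cea == ref[i] && coa == alt[i]) {
        flip[i] <- TRUE
      } else {
        stop("alleles for variant ", wanted[i], " (", ea[i], "/", oa[i],
             ") do not match VCF ", ref[i], "/", alt[i])
      }
    }
  }
  dos <- t(altCount)                         # samples x variants
  if (any(flip)) dos[, flip] <- 2 - dos[, flip, drop = FALSE]
  rownames(dos) <- colnames(gt)
  colnames(dos) <- wanted
  GenotypeMatrix(dos)
}

#' Flip effect-allele orientation of selected variants
#'
#' Replaces dosages `d` by `2 - d` for the given variants. Flipping twice is
#' the identity.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param variants variant ids to flip (default: all).
#' @return A [GenotypeMatrix-class].
#' @export
flipDosages <- function(genotypes, variants = variantIds(genotypes)) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  d <- genotypes@dosages
  miss <- setdiff(variants, colnames(d))
  if (length(miss)) stop("unknown variant(s): ", paste(miss, collapse = ", "))
  d[, variants] <- 2 - d[, variants, drop = FALSE]
  GenotypeMatrix(d)
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys (all optional): `censor_age`, `age_band_edges`,
#' `decade_edges`, `n_tested_characteristics`, `alpha`, `rng_seed`,
#' `hwe_exclusion_p`.
#'
#' @param path YAML file.
#' @return A [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  pick <- function(key, slot) {
    if (!is.null(y[[key]])) args[[slot]] <<- as.numeric(unlist(y[[key]]))
  }
  pick("censor_age", "censorAge")
  pick("age_band_edges", "ageBandEdges")
  pick("decade_edges", "decadeEdges")
  pick("n_tested_characteristics", "nTestedCharacteristics")
  pick("alpha", "alpha")
  pick("rng_seed", "rngSeed")
  pick("hwe_exclusion_p", "hweExclusionP")
  do.call(pipelineConfig, args)
}

# shared output convention: floats at 6 significant digits
writeResultTable <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
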