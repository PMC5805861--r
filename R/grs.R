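#' Compute the type 1 diabetes genetic risk score
#'
#' Per sample, the score is the HLA-DR diplotype weight looked up from the
#' hard-call genotypes at the two tag variants, plus the sum over the
#' additive variants of effect-allele dosage times weight (ln odds ratio):
#' \deqn{s_i = w_{HLA}(g_{i,tag1}, g_{i,tag2}) + \sum_v d_{iv} w_v .}
#' Tag dosages are rounded to the nearest integer (ties to even) for the
#' diplotype lookup; dosages farther than `hardCallTolerance` from an
#' integer raise a warning. Samples missing any required genotype are
#' excluded (and reported in the `excluded` slot) unless `impute = TRUE`,
#' in which case missing additive and tag dosages are mean-imputed from
#' 2 x the observed allele frequency at that variant.
#'
#' @param genotypes a [GenotypeMatrix-class] containing every weight-set
#'   variant.
#' @param weights a [VariantWeightSet-class].
#' @param impute mean-impute missing dosages instead of excluding samples.
#' @param hardCallTolerance warn when a tag dosage is farther than this from
#'   an integer (default 0.1).
#' @return A [ScoreVector-class] with `hla_part + additive_part = score`.
#' @examples
#' w <- VariantWeightSet(
#'   additive = data.frame(variant_id = "v1", effect_allele = "A",
#'                         other_allele = "G", weight = 0.5),
#'   hlaTagIds = c("t1", "t2"),
#'   diplotypeWeights = matrix(0:8 / 2, 3, 3))
#' g <- GenotypeMatrix(matrix(c(2, 0, 0), 1, 3,
#'                            dimnames = list("s1", c("v1", "t1", "t2"))))
#' scores(computeGRS(g, w))
#' @export
computeGRS <- function(genotypes, weights, impute = FALSE,
                       hardCallTolerance = 0.1) {
  stopifnot(is(genotypes, "GenotypeMatrix"), is(weights, "VariantWeightSet"))
  addIds <- weights@additive$variant_id
  tagIds <- weights@hlaTagIds
  needed <- c(addIds, tagIds)
  absent <- setdiff(needed, variantIds(genotypes))
  if (length(absent)) {
    stop("weight-set variant(s) absent from genotype matrix: ",
         paste(absent, collapse = ", "))
  }
  d <- genotypes@dosages[, needed, drop = FALSE]
  if (impute && anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)          # = 2 x observed allele frequency
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  complete <- !rowSums(is.na(d))
  excluded <- rownames(d)[!complete]
  d <- d[complete, , drop = FALSE]

  addPart <- if (length(addIds)) {
    as.numeric(d[, addIds, drop = FALSE] %*% weights@additive$weight)
  } else {
    numeric(nrow(d))
  }

  g1 <- round(d[, tagIds[1]])
  g2 <- round(d[, tagIds[2]])
  off <- abs(d[, tagIds[1]] - g1) > hardCallTolerance |
    abs(d[, tagIds[2]] - g2) > hardCallTolerance
  if (any(off)) {
    warning(sum(off), " sample(s) have tag dosages farther than ",
            hardCallTolerance, " from a hard call")
  }
  hlaPart <- weights@diplotypeWeights[cbind(g1 + 1, g2 + 1)]

  new("ScoreVector", sampleIds = rownames(d), score = hlaPart + addPart,
      hlaPart = hlaPart, additivePart = addPart, excluded = excluded)
}

#' Genotype counts for one variant from hard-call dosages
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param variantId one variant id.
#' @return integer(3): counts of dosage 0, 1 and 2 (missing calls dropped).
#' @export
genotypeCounts <- function(genotypes, variantId) {
  d <- genotypes@dosages[, variantId]
  d <- round(d[!is.na(d)])
  c(sum(d == 0), sum(d == 1), sum(d == 2))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' `(n0, n1, n2)` against the Hardy-Weinberg expectation at the observed
#' allele frequency `p = (2 n2 + n1) / 2n`. A monomorphic variant carries no
#' information about departure and returns `chiSquare = 0, p = 1`.
#'
#' @param counts numeric(3): homozygous-reference, heterozygous,
#'   homozygous-alternate counts.
#' @param variantId optional variant id carried into the result.
#' @return An [HweResult-class].
#' @examples
#' hweTest(c(25, 50, 25))  # exact equilibrium at p = 0.5: chi-square 0
#' hweTest(c(50, 0, 50))   # complete heterozygote deficit: chi-square = n
#' @export
hweTest <- function(counts, variantId = NA_character_) {
  counts <- as.numeric(counts)
  if (length(counts) != 3 || any(counts < 0)) {
    stop("counts must be three non-negative genotype counts")
  }
  n <- sum(counts)
  if (n <= 0) stop("total genotype count must be positive")
  p <- (2 * counts[3] + counts[2]) / (2 * n)
  if (p == 0 || p == 1) {
    return(new("HweResult", variantId = variantId, counts = counts,
               chiSquare = 0, pValue = 1))
  }
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi <- sum((counts - expected)^2 / expected)
  new("HweResult", variantId = variantId, counts = counts,
      chiSquare = chi, pValue = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Hardy-Weinberg QC for every additive variant of a weight set
#'
#' @param weights a [VariantWeightSet-class].
#' @param genotypes a [GenotypeMatrix-class].
#' @return data.frame: variant_id, n0, n1, n2, chi_square, p_value.
#' @export
hweReport <- function(weights, genotypes) {
  ids <- weights@additive$variant_id
  rows <- lapply(ids, function(v) {
    r <- hweTest(genotypeCounts(genotypes, v), v)
    data.frame(variant_id = v, n0 = r@counts[1], n1 = r@counts[2],
               n2 = r@counts[3], chi_square = r@chiSquare,
               p_value = r@pValue, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Exclude additive variants out of Hardy-Weinberg equilibrium
#'
#' Variants with HWE p below `threshold` are dropped from the additive part
#' of the weight set; the exclusion report is attached as attribute
#' `"hwe_exclusions"`.
#'
#' @param weights a [VariantWeightSet-class].
#' @param genotypes a [GenotypeMatrix-class].
#' @param threshold exclusion p-value threshold (default 1e-6).
#' @return The filtered [VariantWeightSet-class].
#' @export
applyHweExclusions <- function(weights, genotypes, threshold = 1e-6) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  if (threshold == 1) {
    warning("threshold 1 removes every variant with p < 1")
  }
  rep <- hweReport(weights, genotypes)
  drop <- rep$variant_id[rep$p_value < threshold]
  out <- VariantWeightSet(
    additive = weights@additive[!(weights@additive$variant_id %in% drop), ,
                                drop = FALSE],
    hlaTagIds = weights@hlaTagIds,
    diplotypeWeights = weights@diplotypeWeights
  )
  attr(out, "hwe_exclusions") <- rep[rep$variant_id %in% drop, , drop = FALSE]
  out
}
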