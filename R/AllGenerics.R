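#' Accessor generics
#'
#' Small accessor family for the package's containers: `sampleIds()` and
#' `variantIds()` for genotype matrices, `dosages()` for the underlying
#' dosage matrix, `scores()` for score vectors, `cohortData()` for the
#' retained phenotype rows, `removedRows()` for rows dropped at validation,
#' `groupLabels()` and `medianCutoff()` for stratified cohorts, and
#' `truthLabels()` for synthetic cohorts.
#'
#' @param x an object of the appropriate class.
#' @return The slot contents; see each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("cohortData", function(x) standardGeneric("cohortData"))

#' @rdname accessors
#' @export
setGeneric("removedRows", function(x) standardGeneric("removedRows"))

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname accessors
#' @export
setGeneric("medianCutoff", function(x) standardGeneric("medianCutoff"))

#' @rdname accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@dosages))

#' @rdname accessors
#' @export
setMethod("variantIds", "GenotypeMatrix", function(x) colnames(x@dosages))

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' @rdname accessors
#' @export
setMethod("sampleIds", "ScoreVector", function(x) x@sampleIds)

#' @rdname accessors
#' @export
setMethod("scores", "ScoreVector", function(x) {
  stats::setNames(x@score, x@sampleIds)
})

#' @rdname accessors
#' @export
setMethod("variantIds", "VariantWeightSet", function(x) {
  c(x@additive$variant_id, x@hlaTagIds)
})

#' @rdname accessors
#' @export
setMethod("cohortData", "CohortTable", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("removedRows", "CohortTable", function(x) x@removed)

#' @rdname accessors
#' @export
setMethod("cohortData", "StratifiedCohort", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("groupLabels", "StratifiedCohort", function(x) {
  stats::setNames(x@data$group, x@data$id)
})

#' @rdname accessors
#' @export
setMethod("medianCutoff", "StratifiedCohort", function(x) x@medianCutoff)

#' @rdname accessors
#' @export
setMethod("cohortData", "SyntheticCohort", function(x) x@cohort@data)

#' @rdname accessors
#' @export
setMethod("truthLabels", "SyntheticCohort", function(x) {
  stats::setNames(x@truth$class, x@truth$id)
})

setMethod("show", "VariantWeightSet", function(object) {
  cat("VariantWeightSet with", nrow(object@additive), "additive variant(s)\n")
  cat("  HLA tag variants:", paste(object@hlaTagIds, collapse = ", "), "\n")
  cat("  diplotype weight range: [",
      format(min(object@diplotypeWeights), digits = 4), ", ",
      format(max(object@diplotypeWeights), digits = 4), "]\n", sep = "")
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosages), "sample(s) x",
      ncol(object@dosages), "variant(s);",
      sum(is.na(object@dosages)), "missing call(s)\n")
})

setMethod("show", "CohortTable", function(object) {
  cat("CohortTable:", nrow(object@data), "individual(s) retained,",
      nrow(object@removed), "removed\n")
  if (nrow(object@removed) > 0) {
    tab <- table(object@removed$removal_rule)
    for (r in names(tab)) cat("   ", r, ":", tab[[r]], "\n")
  }
  cat("  diabetes cases:", sum(object@data$has_diabetes %in% TRUE), "\n")
})

setMethod("show", "ScoreVector", function(object) {
  cat("ScoreVector:", length(object@sampleIds), "scored sample(s)")
  if (length(object@excluded)) cat(",", length(object@excluded), "excluded")
  cat("\n")
  if (length(object@score)) {
    q <- stats::quantile(object@score, c(0, 0.5, 1))
    cat("  score min/median/max:", paste(format(q, digits = 4), collapse = " / "), "\n")
  }
})

setMethod("show", "HweResult", function(object) {
  cat("HweResult for ", object@variantId, ": counts (",
      paste(object@counts, collapse = ", "), "), chi-square ",
      format(object@chiSquare, digits = 4), ", p = ",
      format(object@pValue, digits = 3), "\n", sep = "")
})

setMethod("show", "StratifiedCohort", function(object) {
  g <- table(object@data$group)
  cat("StratifiedCohort: median cutoff", format(object@medianCutoff, digits = 4),
      "\n  high:", g[["high"]], " low:", g[["low"]], "\n")
})

setMethod("show", "KMCurve", function(object) {
  cat("KMCurve [", object@label, "]: ", length(object@time),
      " distinct event time(s)", sep = "")
  if (length(object@time)) {
    cat("; final S(", max(object@time), ") = ",
        format(object@surv[length(object@surv)], digits = 4), sep = "")
  }
  cat("\n")
})

setMethod("show", "ExcessEstimate", function(object) {
  cat("ExcessEstimate: ", object@nHighCases, " high vs ", object@nLowCases,
      " low cases; excess ", object@excess, " of ", object@totalCases,
      " (", format(object@proportion, digits = 3), "%, 95% CI ",
      format(object@proportionCI[1], digits = 3), "-",
      format(object@proportionCI[2], digits = 3), ")\n", sep = "")
})

setMethod("show", "SyntheticCohort", function(object) {
  tab <- table(object@truth$class)
  cat("SyntheticCohort:", nrow(object@truth), "individuals\n  truth: ")
  cat(paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
})
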