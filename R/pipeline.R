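#' Run the full genetically stratified excess pipeline
#'
#' Orchestrates the stages score -> median split -> Kaplan-Meier -> excess
#' -> derived characteristics over the three input artifacts, writing all
#' tabular outputs plus a run manifest into `outDir`. The run is
#' deterministic given identical inputs and `config@rngSeed`; on any stage
#' error the partially written outputs are removed and the error is
#' re-raised with the stage name.
#'
#' @param weightsPath,diplotypePath additive and HLA diplotype weight tables.
#' @param genotypesPath genotype matrix (TSV) or VCF.
#' @param cohortPath phenotype table.
#' @param outDir output directory (created if needed).
#' @param config a [PipelineConfig-class].
#' @return `outDir` invisibly; files written: `scores.csv`, `hwe.csv`,
#'   `lifetable.csv`, `excess_overall.csv`, `excess_by_band.csv`,
#'   `cumulative_excess.csv`, `incidence_by_decade.csv`, `table1.csv`,
#'   `table2.csv`, `manifest.json`.
#' @export
runPipeline <- function(weightsPath, diplotypePath, genotypesPath, cohortPath,
                        outDir, config = pipelineConfig()) {
  validObject(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(outDir, name)
    writeResultTable(df, path)
    written <<- c(written, path)
    path
  }
  manifest <- list(
    software = paste0("grsExcess ", as.character(utils::packageVersion("grsExcess"))),
    seed = config@rngSeed,
    config = list(censor_age = config@censorAge,
                  age_band_edges = config@ageBandEdges,
                  decade_edges = config@decadeEdges,
                  n_tested_characteristics = config@nTestedCharacteristics,
                  alpha = config@alpha,
                  hwe_exclusion_p = config@hweExclusionP),
    inputs = as.list(tools::md5sum(c(weights = weightsPath,
                                     diplotype = diplotypePath,
                                     genotypes = genotypesPath,
                                     cohort = cohortPath))),
    stages = list()
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  weights <- stage("read_weights", readWeights(weightsPath, diplotypePath))
  cohort <- stage("read_cohort", readCohort(cohortPath))
  genotypes <- stage("read_genotypes", readGenotypes(genotypesPath, weights))
  manifest$stages$read <- list(
    cohort_rows_in = nrow(cohort@data) + nrow(cohort@removed),
    cohort_rows_retained = nrow(cohort@data),
    cohort_rows_removed = nrow(cohort@removed),
    removal_rules = as.list(table(cohort@removed$removal_rule)),
    n_samples = length(sampleIds(genotypes)),
    n_additive_variants_in = nrow(weights@additive)
  )

  weights <- stage("hwe_qc", applyHweExclusions(weights, genotypes,
                                                config@hweExclusionP))
  hweTab <- hweReport(weights, genotypes)
  excl <- attr(weights, "hwe_exclusions")
  manifest$stages$hwe <- list(
    n_excluded = if (is.null(excl)) 0L else nrow(excl),
    excluded_variants = if (is.null(excl)) character(0) else excl$variant_id,
    n_additive_variants_retained = nrow(weights@additive)
  )
  emit(hweTab, "hwe.csv")

  scoreVec <- stage("grs", computeGRS(genotypes, weights))
  emit(data.frame(sample_id = scoreVec@sampleIds, score = scoreVec@score,
                  hla_part = scoreVec@hlaPart,
                  additive_part = scoreVec@additivePart), "scores.csv")
  manifest$stages$grs <- list(n_scored = length(scoreVec@sampleIds),
                              n_excluded = length(scoreVec@excluded))

  strat <- stage("split", splitByMedian(scoreVec, cohort))
  manifest$stages$split <- list(
    median_cutoff = strat@medianCutoff,
    n_high = sum(strat@data$group == "high"),
    n_low = sum(strat@data$group == "low"))

  curves <- stage("km", kmByGroup(strat, config@censorAge))
  emit(rbind(kmLifeTable(curves$high), kmLifeTable(curves$low)),
       "lifetable.csv")

  set.seed(config@rngSeed)
  est <- stage("excess", excessByBand(strat, config@ageBandEdges,
                                      config@censorAge))
  emit(data.frame(n_high_cases = est@nHighCases, n_low_cases = est@nLowCases,
                  excess = est@excess, total_cases = est@totalCases,
                  proportion_t1d_pct = est@proportion,
                  ci_low = est@proportionCI[1], ci_high = est@proportionCI[2]),
       "excess_overall.csv")
  emit(est@byBand, "excess_by_band.csv")
  emit(stage("cumulative_excess", cumulativeExcess(strat, config@censorAge)),
       "cumulative_excess.csv")
  emit(stage("incidence", incidenceByDecade(strat, config@decadeEdges,
                                            config@censorAge)),
       "incidence_by_decade.csv")
  manifest$stages$excess <- list(n_cases = est@totalCases,
                                 excess = est@excess)

  if (est@totalCases > 0 && est@excess > 0) {
    tabs <- stage("characteristics",
                  buildTables(strat, config@ageBandEdges, config@censorAge,
                              nTested = config@nTestedCharacteristics))
    emit(tabs$table1, "table1.csv")
    emit(tabs$table2, "table2.csv")
    manifest$stages$characteristics <- list(built = TRUE)
  } else {
    message("characteristics stage skipped: no positive case excess")
    manifest$stages$characteristics <- list(
      built = FALSE, reason = "no positive case excess")
  }

  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outDir)
}

#' Draw the pipeline's figures from a stage-output directory
#'
#' Kaplan-Meier diabetes-free survival per genetic-risk group, the
#' cumulative excess of genetically defined type 1 diabetes by age, and
#' per-decade stacked incidence of genetically defined type 1 and type 2
#' diabetes. Figures whose stage CSV is absent are skipped with a warning.
#'
#' @param outDir directory holding the pipeline CSVs.
#' @param format "pdf" or "png".
#' @return character vector of figure paths written.
#' @export
makeFigures <- function(outDir, format = c("pdf", "png")) {
  format <- match.arg(format)
  paths <- character(0)
  save <- function(plot, name) {
    f <- file.path(outDir, paste0(name, ".", format))
    ggplot2::ggsave(f, plot, width = 6, height = 4)
    paths <<- c(paths, f)
  }

  lt <- file.path(outDir, "lifetable.csv")
  if (file.exists(lt)) {
    d <- utils::read.csv(lt)
    steps <- do.call(rbind, lapply(split(d, d$group), function(g) {
      g <- g[order(g$age), ]
      rbind(data.frame(group = g$group[1], age = 0, survival = 1), g[
        , c("group", "age", "survival")])
    }))
    save(ggplot2::ggplot(steps,
                         ggplot2::aes(x = .data$age, y = .data$survival,
                                      colour = .data$group)) +
           ggplot2::geom_step() +
           ggplot2::labs(x = "Age (years)", y = "Diabetes-free survival",
                         colour = "Genetic risk") +
           ggplot2::theme_minimal(),
         "km_survival")
  } else {
    warning("lifetable.csv missing; survival figure skipped")
  }

  ce <- file.path(outDir, "cumulative_excess.csv")
  if (file.exists(ce)) {
    d <- utils::read.csv(ce)
    save(ggplot2::ggplot(d, ggplot2::aes(x = .data$age,
                                         y = .data$cumulative_excess)) +
           ggplot2::geom_line() +
           ggplot2::labs(x = "Age at diagnosis (years)",
                         y = "Cumulative excess cases (type 1)") +
           ggplot2::theme_minimal(),
         "cumulative_excess")
  } else {
    warning("cumulative_excess.csv missing; cumulative figure skipped")
  }

  dec <- file.path(outDir, "incidence_by_decade.csv")
  if (file.exists(dec)) {
    d <- utils::read.csv(dec)
    long <- rbind(data.frame(decade = d$decade, type = "type 1", n = d$t1d),
                  data.frame(decade = d$decade, type = "type 2", n = d$t2d))
    long$decade <- factor(long$decade, levels = d$decade)
    save(ggplot2::ggplot(long, ggplot2::aes(x = .data$decade, y = .data$n,
                                            fill = .data$type)) +
           ggplot2::geom_col() +
           ggplot2::labs(x = "Decade of diagnosis", y = "Cases",
                         fill = NULL) +
           ggplot2::theme_minimal(),
         "incidence_by_decade")
  } else {
    warning("incidence_by_decade.csv missing; incidence figure skipped")
  }
  paths
}
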