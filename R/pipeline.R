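#' Run the full burden-analysis pipeline
#'
#' Orchestrates the analysis end to end: read inputs, quality control,
#' functional classification and frequency computation, gene-set and
#' gene-wide burden scan (kernel + collapsing regression), accumulation
#' rate tests, and Westfall-Young family-wise error adjustment within each
#' trait and across all traits. All outputs are tab-separated tables with
#' fixed column order, written to the configured output directory together
#' with a structured run log (one line per stage with in/out counts), so a
#' rerun with the same configuration is byte-identical.
#'
#' @param config a named list or path to a YAML file with entries:
#'   `vcf`, `annotations`, `phenotypes`, `gene_sets` (paths);
#'   optional `traits` (trait names to analyse), `covariates`, `classes`,
#'   `tiers`, `weights` (`"beta"`/`"uniform"`), `units`
#'   (burden-scan units), `rate_units`, `fwer_units` (`"sets"` and/or
#'   `"genes"`; which unit types enter the FWER families), `qc`
#'   (list: `sample_call_rate`, `variant_call_rate`, `hwe_p`),
#'   `resamples` (B), `seed`, `out_dir`.
#' @return invisibly, a list with the cohort, the result tables and the
#'   output paths.
#' @export
runPipeline <- function(config) {
  cfg <- loadRunConfig(config)
  outDir <- cfg$out_dir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  logPath <- file.path(outDir, "run_log.txt")
  logLines <- character()
  logStage <- function(...) {
    logLines <<- c(logLines, sprintf(...))
  }
  logStage("rvburden version=%s R=%s",
           as.character(utils::packageVersion("rvburden")),
           paste(R.version$major, R.version$minor, sep = "."))
  logStage("config seed=%d resamples=%d weights=%s qc=%s", cfg$seed,
           cfg$resamples, cfg$weights,
           paste(sprintf("%s=%g", names(cfg$qc), unlist(cfg$qc)),
                 collapse = ","))

  stage <- "read_inputs"
  result <- tryCatch({
    cohort <- readCohort(cfg$vcf, cfg$annotations, cfg$phenotypes,
                         cfg$gene_sets)
    logStage("stage=read_inputs variants=%d samples=%d gene_sets=%d",
             nrow(cohort), ncol(cohort), length(geneSets(cohort)))

    stage <- "qc"
    qc <- applyQC(cohort, sampleCallRate = cfg$qc$sample_call_rate,
                  variantCallRate = cfg$qc$variant_call_rate,
                  hwePThreshold = cfg$qc$hwe_p)
    cohort <- qc$cohort
    tsvWrite(qc$report, file.path(outDir, "qc_report.tsv"))
    logStage("stage=qc excluded=%d variants=%d samples=%d",
             nrow(qc$report), nrow(cohort), ncol(cohort))

    stage <- "classify"
    cs <- classificationSummary(cohort)
    tsvWrite(cs, file.path(outDir, "classification_summary.tsv"))
    logStage("stage=classify genes=%d rare=%d singletons=%d",
             length(unique(rowData(cohort)$gene)),
             sum(rowData(cohort)$is_rare),
             sum(rowData(cohort)$is_singleton))

    stage <- "burden_scan"
    traits <- cfg$traits %||% names(traitTypes(cohort))
    burden <- runBurdenScan(cohort, traits = traits, units = cfg$units,
                            classes = cfg$classes, tiers = cfg$tiers,
                            covariates = cfg$covariates,
                            weights = cfg$weights)
    tsvWrite(burden, file.path(outDir, "burden_results.tsv"))
    logStage("stage=burden_scan tests=%d", nrow(burden))

    stage <- "rate_tests"
    tt <- traitTypes(cohort)
    binTraits <- intersect(traits, names(tt)[tt == "binary"])
    rates <- runRateTests(cohort, traits = binTraits,
                          units = cfg$rate_units, classes = cfg$classes,
                          tiers = cfg$tiers)
    tsvWrite(rates, file.path(outDir, "rate_results.tsv"))
    logStage("stage=rate_tests tests=%d", nrow(rates))

    stage <- "fwer"
    keepB <- burden$unit_type %in% unitTypesFor(cfg$fwer_units)
    keepR <- rates$unit_type %in% unitTypesFor(cfg$fwer_units)
    bSub <- burden[keepB, , drop = FALSE]
    attr(bSub, "variantIds") <- attr(burden, "variantIds")[keepB]
    rSub <- rates[keepR, , drop = FALSE]
    attr(rSub, "variantIds") <- attr(rates, "variantIds")[keepR]
    adjusted <- adjustResults(cohort, bSub, rSub, B = cfg$resamples,
                              seed = cfg$seed, weights = cfg$weights,
                              covariates = cfg$covariates)
    tsvWrite(adjusted, file.path(outDir, "adjusted_results.tsv"))
    nHits <- sum(adjusted$fwer_across_p < 0.05, na.rm = TRUE)
    logStage("stage=fwer members=%d B=%d hits_across=%d",
             nrow(adjusted), cfg$resamples, nHits)

    list(cohort = cohort, qc = qc, burden = burden, rates = rates,
         adjusted = adjusted,
         paths = file.path(outDir, c("qc_report.tsv",
                                     "classification_summary.tsv",
                                     "burden_results.tsv",
                                     "rate_results.tsv",
                                     "adjusted_results.tsv",
                                     "run_log.txt")))
  }, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
  writeLines(logLines, logPath)
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unitTypesFor <- function(units)
  c(sets = "set", genes = "gene")[units]

loadRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s",
                                           config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  for (f in c("vcf", "annotations", "phenotypes", "gene_sets", "out_dir"))
    if (is.null(config[[f]])) stop(sprintf("config field '%s' is required",
                                           f))
  qc <- config$qc %||% list()
  list(vcf = config$vcf, annotations = config$annotations,
       phenotypes = config$phenotypes,
       gene_sets = unlist(config$gene_sets),
       out_dir = config$out_dir,
       traits = config$traits,
       covariates = config$covariates %||% character(),
       classes = config$classes %||% CLASS_TIERS,
       tiers = config$tiers %||% FREQ_TIERS,
       weights = config$weights %||% "beta",
       units = config$units %||% c("sets", "genes"),
       rate_units = config$rate_units %||% "sets",
       fwer_units = config$fwer_units %||% c("sets", "genes"),
       qc = list(sample_call_rate = qc$sample_call_rate %||% 0.9,
                 variant_call_rate = qc$variant_call_rate %||% 0.9,
                 hwe_p = qc$hwe_p %||% 1e-6),
       resamples = as.integer(config$resamples %||% 10000L),
       seed = as.integer(config$seed %||%
                           stop("config field 'seed' is required")))
}

#' Simulate a cohort and write it as a pipeline fixture
#'
#' @param simConfig a [SimulationConfig-class], or path to a YAML file with
#'   fields matching [simulationConfig()] arguments (planted effects as a
#'   list of mappings with keys target_set, target_class, target_tier,
#'   mode, magnitude, target_trait).
#' @param dir output directory.
#' @return invisibly, the file paths written.
#' @export
simulateFixture <- function(simConfig, dir) {
  if (is.character(simConfig) && length(simConfig) == 1L)
    simConfig <- simulationConfigFromYaml(simConfig)
  writeFixture(simulateCohort(simConfig), dir)
}

simulationConfigFromYaml <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  args <- list()
  map1 <- c(n_controls = "nControls", n_genes = "nGenes",
            variants_per_gene = "variantsPerGene", sfs_max = "sfsMax",
            predictor_damage_prob = "predictorDamageProb",
            quant_controls_only = "quantControlsOnly",
            missing_rate = "missingRate", seed = "seed")
  for (nm in names(map1))
    if (!is.null(y[[nm]])) args[[map1[[nm]]]] <- y[[nm]]
  if (!is.null(y$n_cases_by_trait))
    args$nCasesByTrait <- unlist(y$n_cases_by_trait)
  if (!is.null(y$genes_per_set)) args$genesPerSet <- unlist(y$genes_per_set)
  if (!is.null(y$class_proportions))
    args$classProportions <- unlist(y$class_proportions)
  if (!is.null(y$quant_traits)) args$quantTraits <- unlist(y$quant_traits)
  if (!is.null(y$planted_effects))
    args$plantedEffects <- lapply(y$planted_effects, function(pe)
      plantedEffect(pe$target_set, pe$target_class, pe$target_tier,
                    pe$mode, pe$magnitude, pe$target_trait))
  do.call(simulationConfig, args)
}
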