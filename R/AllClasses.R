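#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   rowData<- colData colData<-
NULL

FUNCTIONAL_CLASSES <- c("DISRUPTIVE", "NS_STRICT", "NS_BROAD",
                        "NEUTRAL_MISSENSE", "SILENT", "OTHER")
CLASS_TIERS  <- c("Disruptive", "NS_strict", "NS_broad")
FREQ_TIERS   <- c("singleton", "rare")
CONSEQUENCES <- c("silent", "missense", "nonsense", "splice", "other")
PREDICTORS   <- c("sift", "pph2_div", "pph2_var", "lrt", "mutation_taster")

#' Cohort of diploid genotypes with variant annotation and phenotypes
#'
#' `BurdenCohort` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `"dosage"` assay holding minor-allele dosages in \{0, 1, 2, NA\}.
#' Rows are variants (with gene, consequence, predictor verdicts, derived
#' functional class and allele-frequency summaries in `rowData`), columns are
#' samples (with binary and quantitative traits in `colData`). Gene-set
#' definitions and trait types live in `metadata`.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @aliases BurdenCohort-class
#' @exportClass BurdenCohort
setClass("BurdenCohort", contains = "SummarizedExperiment")

setValidity("BurdenCohort", function(object) {
  msg <- character()
  if (!"dosage" %in% names(assays(object)))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    chk <- d * (d - 1) * (d - 2)      # zero iff dosage in {0, 1, 2}
    if (!all(chk == 0, na.rm = TRUE))
      msg <- c(msg, "dosages must be in {0, 1, 2} or NA")
  }
  gs <- metadata(object)$geneSets
  if (!is.null(gs)) {
    if (is.null(names(gs)) || any(!nzchar(names(gs))))
      msg <- c(msg, "gene sets must be named")
    for (nm in names(gs)) {
      g <- gs[[nm]]
      if (!length(g)) msg <- c(msg, sprintf("gene set '%s' is empty", nm))
      if (anyDuplicated(g))
        msg <- c(msg, sprintf("gene set '%s' has duplicate symbols", nm))
    }
  }
  tt <- metadata(object)$traitTypes
  if (!is.null(tt) && !all(tt %in% c("binary", "quantitative")))
    msg <- c(msg, "trait types must be 'binary' or 'quantitative'")
  if (length(msg)) msg else TRUE
})

#' Covariates-only null model for a trait
#'
#' Holds the maximum-likelihood fit of one phenotype on covariates alone
#' (logistic for binary traits, ordinary least squares for quantitative
#' traits), the ingredients needed by the kernel score test: per-sample
#' fitted means, per-sample variance function values, and the covariate
#' design matrix (intercept always included).
#'
#' @slot trait trait name.
#' @slot traitType `"binary"` or `"quantitative"`.
#' @slot sampleIds samples with non-missing phenotype, in cohort order.
#' @slot y observed phenotype for those samples.
#' @slot mu fitted means under the covariates-only model.
#' @slot varFun per-sample variance function: `mu*(1-mu)` (binary) or the
#'   residual variance (quantitative, constant).
#' @slot X covariate design matrix (n x p, first column the intercept).
#' @slot sigma2 residual variance (quantitative) or `NA`.
#' @slot dropped sample ids removed for missing phenotype.
#' @aliases NullModel-class
#' @exportClass NullModel
setClass("NullModel", representation(
  trait = "character", traitType = "character", sampleIds = "character",
  y = "numeric", mu = "numeric", varFun = "numeric", X = "matrix",
  sigma2 = "numeric", dropped = "character"))

setValidity("NullModel", function(object) {
  msg <- character()
  if (object@traitType == "binary" &&
      (any(object@mu <= 0) || any(object@mu >= 1)))
    msg <- c(msg, "binary fitted means must lie in (0, 1)")
  if (object@traitType == "quantitative" &&
      (is.na(object@sigma2) || object@sigma2 <= 0))
    msg <- c(msg, "quantitative dispersion must be positive")
  if (length(object@y) != nrow(object@X))
    msg <- c(msg, "phenotype and design matrix disagree on sample count")
  if (length(msg)) msg else TRUE
})

#' A planted association effect for the cohort simulator
#'
#' Describes one effect the simulator injects: qualifying alleles of a given
#' functional class and frequency tier within one gene set either multiply
#' the per-sample accumulation rate in cases (`rate_fold`), act on the odds
#' of case status per allele (`odds_ratio`), or shift a quantitative trait
#' per allele (`beta`).
#'
#' @slot targetSet gene-set name the effect acts through.
#' @slot targetClass functional class tier: `"Disruptive"`, `"NS_strict"` or
#'   `"NS_broad"` (cumulative qualifying sets).
#' @slot targetTier `"singleton"` or `"rare"`.
#' @slot mode `"rate_fold"`, `"odds_ratio"` or `"beta"`.
#' @slot magnitude positive fold / OR per allele / trait units per allele
#'   (for `beta` the signed effect is `magnitude * sign`, see constructor).
#' @slot targetTrait trait name the effect acts on.
#' @aliases PlantedEffect-class
#' @exportClass PlantedEffect
setClass("PlantedEffect", representation(
  targetSet = "character", targetClass = "character", targetTier = "character",
  mode = "character", magnitude = "numeric", targetTrait = "character"))

setValidity("PlantedEffect", function(object) {
  msg <- character()
  if (!object@targetClass %in% CLASS_TIERS)
    msg <- c(msg, sprintf("targetClass must be one of %s",
                          paste(CLASS_TIERS, collapse = ", ")))
  if (!object@targetTier %in% FREQ_TIERS)
    msg <- c(msg, "targetTier must be 'singleton' or 'rare'")
  if (!object@mode %in% c("rate_fold", "odds_ratio", "beta"))
    msg <- c(msg, "mode must be rate_fold, odds_ratio or beta")
  if (object@mode == "beta") {
    if (object@magnitude == 0) msg <- c(msg, "beta magnitude must be nonzero")
  } else if (object@magnitude <= 0)
    msg <- c(msg, "magnitude must be positive")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the study design the package targets: case groups of
#' 211 (SCZ), 195 (BD) and 169 (rMDD) with 871 controls; 213 genes split
#' into two gene sets of 59 and 154; roughly 21 coding variants per gene
#' with consequence proportions matching a deeply sequenced candidate-gene
#' panel; and a 1/k site-frequency spectrum truncated so that about 78% of
#' variants have MAF < 1%.
#'
#' @slot nCasesByTrait named integer, cases per binary trait.
#' @slot nControls integer, shared control count.
#' @slot nGenes integer, number of genes.
#' @slot genesPerSet named integer, genes per gene set (sums to `nGenes`).
#' @slot variantsPerGene mean coding variants per gene (Poisson).
#' @slot sfsMax truncation point of the 1/k minor-allele-count spectrum;
#'   `NA` selects it so that ~78% of variants are rare (MAF < 1%).
#' @slot classProportions named probabilities over silent/missense/nonsense/
#'   splice.
#' @slot predictorDamageProb probability each of the 5 predictors calls a
#'   missense variant damaging (length 1 or 5).
#' @slot quantTraits names of quantitative traits to generate.
#' @slot quantControlsOnly if `TRUE` (default) quantitative traits are
#'   measured in controls only, mirroring a control-cohort design.
#' @slot missingRate genotype missingness rate.
#' @slot plantedEffects list of [PlantedEffect-class] objects.
#' @slot seed integer random seed.
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
  nCasesByTrait = "integer", nControls = "integer", nGenes = "integer",
  genesPerSet = "integer", variantsPerGene = "numeric", sfsMax = "integer",
  classProportions = "numeric", predictorDamageProb = "numeric",
  quantTraits = "character", quantControlsOnly = "logical",
  missingRate = "numeric", plantedEffects = "list", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (any(object@nCasesByTrait <= 0L) || is.null(names(object@nCasesByTrait)))
    msg <- c(msg, "nCasesByTrait must be a named vector of positive counts")
  if (object@nControls <= 0L) msg <- c(msg, "nControls must be positive")
  if (object@nGenes <= 0L) msg <- c(msg, "nGenes must be positive")
  if (sum(object@genesPerSet) > object@nGenes)
    msg <- c(msg, "genesPerSet must not exceed nGenes")
  if (object@variantsPerGene <= 0) msg <- c(msg, "variantsPerGene must be > 0")
  cp <- object@classProportions
  if (!setequal(names(cp), c("silent", "missense", "nonsense", "splice")))
    msg <- c(msg, "classProportions must cover silent/missense/nonsense/splice")
  if (abs(sum(cp) - 1) > 1e-12)
    msg <- c(msg, "classProportions must sum to 1 within 1e-12")
  if (any(cp < 0) || any(cp > 1)) msg <- c(msg, "proportions must be in [0,1]")
  pd <- object@predictorDamageProb
  if (!length(pd) %in% c(1L, 5L) || any(pd < 0) || any(pd > 1))
    msg <- c(msg, "predictorDamageProb must be 1 or 5 probabilities in [0,1]")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0, 1)")
  traits <- c(names(object@nCasesByTrait), "combined", object@quantTraits)
  for (pe in object@plantedEffects) {
    if (!is(pe, "PlantedEffect"))
      msg <- c(msg, "plantedEffects must contain PlantedEffect objects")
    else {
      if (!pe@targetTrait %in% traits)
        msg <- c(msg, sprintf("planted target_trait '%s' not in config",
                              pe@targetTrait))
      if (!pe@targetSet %in% names(object@genesPerSet))
        msg <- c(msg, sprintf("planted target_set '%s' not in config",
                              pe@targetSet))
      if (pe@mode == "beta" && !pe@targetTrait %in% object@quantTraits)
        msg <- c(msg, "beta effects must target a quantitative trait")
      if (pe@mode != "beta" && pe@targetTrait %in% object@quantTraits)
        msg <- c(msg, "rate_fold/odds_ratio effects must target a binary trait")
    }
  }
  if (length(msg)) msg else TRUE
})
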