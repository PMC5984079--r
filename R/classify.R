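#' Classify coding variants into functional tiers
#'
#' Assigns each variant one label: nonsense and splice-site variants are
#' `DISRUPTIVE`; missense variants called damaging by all five predictors
#' are `NS_STRICT`; missense variants called damaging by at least one (but
#' not all five) are `NS_BROAD`; missense variants damaging by none are
#' `NEUTRAL_MISSENSE`; synonymous variants are `SILENT`. Unknown consequence
#' labels map to `OTHER` with a warning, never silently dropped. Missing
#' (`NA`) verdicts count as not damaging.
#'
#' For burden testing the three analysis classes are cumulative qualifying
#' sets: Disruptive contains the `DISRUPTIVE` labels; NS_strict adds the
#' strictly damaging missense; NS_broad adds the broadly damaging missense,
#' so Disruptive is a subset of NS_strict which is a subset of NS_broad
#' (see [qualifyingClass()]).
#'
#' @param consequence character vector over
#'   `c("silent","missense","nonsense","splice","other")`.
#' @param verdicts character matrix (variants x 5) of predictor verdicts in
#'   `c("damaging","tolerated",NA)`, columns SIFT, PolyPhen2-HumDiv,
#'   PolyPhen2-HumVar, LRT, MutationTaster. May be `NULL` if no variant is
#'   missense.
#' @return factor with levels `DISRUPTIVE`, `NS_STRICT`, `NS_BROAD`,
#'   `NEUTRAL_MISSENSE`, `SILENT`, `OTHER`.
#' @examples
#' classifyVariants("nonsense", matrix(NA_character_, 1, 5))
#' classifyVariants("missense", matrix("damaging", 1, 5))
#' @export
classifyVariants <- function(consequence, verdicts = NULL) {
  consequence <- as.character(consequence)
  n <- length(consequence)
  if (is.null(verdicts)) verdicts <- matrix(NA_character_, n, 5)
  verdicts <- as.matrix(verdicts)
  if (ncol(verdicts) != 5L)
    stop("verdicts must have 5 columns (one per predictor)")
  if (nrow(verdicts) != n)
    stop("verdicts and consequence lengths differ")
  unknown <- !consequence %in% CONSEQUENCES
  if (any(unknown)) {
    warning(sprintf("%d variant(s) with unknown consequence label mapped to OTHER: %s",
                    sum(unknown),
                    paste(unique(consequence[unknown]), collapse = ", ")))
    consequence[unknown] <- "other"
  }
  nDamaging <- rowSums(verdicts == "damaging", na.rm = TRUE)
  out <- rep("OTHER", n)
  out[consequence == "silent"] <- "SILENT"
  out[consequence %in% c("nonsense", "splice")] <- "DISRUPTIVE"
  mis <- consequence == "missense"
  out[mis & nDamaging == 0] <- "NEUTRAL_MISSENSE"
  out[mis & nDamaging >= 1] <- "NS_BROAD"
  out[mis & nDamaging == 5] <- "NS_STRICT"
  factor(out, levels = FUNCTIONAL_CLASSES)
}

#' Membership in the cumulative qualifying class sets
#'
#' @param functionalClass factor/character of per-variant labels as produced
#'   by [classifyVariants()].
#' @param classTier one of `"Disruptive"`, `"NS_strict"`, `"NS_broad"`.
#' @return logical vector: does the variant qualify for the tier?
#' @export
qualifyingClass <- function(functionalClass, classTier) {
  classTier <- match.arg(classTier, CLASS_TIERS)
  members <- switch(classTier,
    Disruptive = "DISRUPTIVE",
    NS_strict  = c("DISRUPTIVE", "NS_STRICT"),
    NS_broad   = c("DISRUPTIVE", "NS_STRICT", "NS_BROAD"))
  as.character(functionalClass) %in% members
}

#' Per-variant allele-frequency summaries
#'
#' Computes, per variant (row), the minor-allele frequency over non-missing
#' genotypes, the minor-allele count, and singleton / rare flags. Dosages
#' are oriented to the minor allele first (columns with alternate-allele
#' frequency above 0.5 are flipped `d -> 2 - d`), so `maf <= 0.5` always. A
#' singleton carries its minor allele exactly once in the whole cohort;
#' rare means MAF strictly below 1%. Variants with all genotypes missing get
#' `NA` frequencies and are flagged in `all_missing`.
#'
#' @param dosage variants x samples matrix with values in \{0,1,2,NA\}.
#' @return `DataFrame` with columns `maf`, `mac`, `n_called`,
#'   `is_singleton`, `is_rare`, `flipped`, `all_missing`.
#' @export
computeFrequencies <- function(dosage) {
  dosage <- as.matrix(dosage)
  nCalled <- rowSums(!is.na(dosage))
  altCount <- rowSums(dosage, na.rm = TRUE)
  altFreq <- ifelse(nCalled > 0, altCount / (2 * nCalled), NA_real_)
  flipped <- !is.na(altFreq) & altFreq > 0.5
  mac <- ifelse(flipped, 2 * nCalled - altCount, altCount)
  maf <- ifelse(flipped, 1 - altFreq, altFreq)
  DataFrame(
    maf = maf,
    mac = as.integer(round(mac)),
    n_called = as.integer(nCalled),
    is_singleton = !is.na(maf) & mac == 1,
    is_rare = !is.na(maf) & maf < 0.01,
    flipped = flipped,
    all_missing = nCalled == 0,
    row.names = rownames(dosage))
}

#' Minor-allele-oriented dosage matrix
#'
#' Returns the dosage matrix with flipped columns re-oriented so every row
#' counts the cohort minor allele, as used by all tests.
#' @param cohort a [BurdenCohort-class].
#' @return numeric matrix, variants x samples.
#' @export
minorDosage <- function(cohort) {
  d <- dosage(cohort)
  fl <- rowData(cohort)$flipped
  if (!is.null(fl) && any(fl)) d[fl, ] <- 2 - d[fl, , drop = FALSE]
  d
}

#' Qualifying variant ids for a unit/class/tier cell
#'
#' A variant qualifies when it lies in the unit's gene(s), its functional
#' class belongs to the cumulative class tier, its frequency tier matches
#' (`singleton`: minor-allele count exactly 1; `rare`: MAF < 1%), and it is
#' polymorphic (minor-allele count >= 1) with at least one called genotype.
#'
#' @param cohort a [BurdenCohort-class] with classification and frequencies.
#' @param genes character vector of gene symbols defining the unit.
#' @param classTier `"Disruptive"`, `"NS_strict"` or `"NS_broad"`.
#' @param freqTier `"singleton"` or `"rare"`.
#' @return character vector of qualifying variant ids (possibly empty).
#' @export
qualifyingVariants <- function(cohort, genes, classTier, freqTier) {
  freqTier <- match.arg(freqTier, FREQ_TIERS)
  rd <- rowData(cohort)
  ok <- rd$gene %in% genes &
    qualifyingClass(rd$functional_class, classTier) &
    !rd$all_missing & rd$mac >= 1L
  ok <- ok & if (freqTier == "singleton") rd$is_singleton else rd$is_rare
  rownames(cohort)[which(ok)]
}

#' Classification summary table
#'
#' Counts qualifying variants per gene x class tier x frequency tier, the
#' bookkeeping view written by the pipeline.
#' @param cohort a classified [BurdenCohort-class].
#' @return data.frame with columns gene, class, tier, n_variants.
#' @export
classificationSummary <- function(cohort) {
  rd <- rowData(cohort)
  genes <- sort(unique(as.character(rd$gene)))
  grid <- expand.grid(gene = genes, class = CLASS_TIERS, tier = FREQ_TIERS,
                      stringsAsFactors = FALSE)
  grid$n_variants <- vapply(seq_len(nrow(grid)), function(i)
    length(qualifyingVariants(cohort, grid$gene[i], grid$class[i],
                              grid$tier[i])), integer(1))
  grid[order(grid$gene, match(grid$class, CLASS_TIERS),
             match(grid$tier, FREQ_TIERS)), , drop = FALSE]
}
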