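#' Gene-set and gene-wide burden scan
#'
#' Runs the kernel score test and the collapsing burden regression for
#' every combination of trait, unit (gene sets and/or single genes),
#' functional class tier and frequency tier. Gene-set cells are tested
#' whenever at least one variant qualifies; gene-wide cells require at
#' least two qualifying variants (the "more than one rare variant"
#' inclusion rule — singleton- and rare-tier qualifying variants are by
#' construction rare). Output order is deterministic: traits in the given
#' order, then sets before genes, then unit name, class and tier in
#' canonical order.
#'
#' @param cohort a classified, QC-passed [BurdenCohort-class].
#' @param traits trait names to analyse (default: all traits with at least
#'   10 non-missing values).
#' @param units `"sets"`, `"genes"` or both (default both).
#' @param classes class tiers (default all three).
#' @param tiers frequency tiers (default singleton and rare).
#' @param covariates phenotype columns to adjust for.
#' @param weights kernel weight scheme, see [variantWeights()].
#' @return data.frame with columns unit, unit_type, trait, class, tier,
#'   n_variants, kernel_p, burden_p, effect, se, backend; attribute
#'   `"variantIds"` carries the qualifying variant list per row.
#' @export
runBurdenScan <- function(cohort, traits = NULL, units = c("sets", "genes"),
                          classes = CLASS_TIERS, tiers = FREQ_TIERS,
                          covariates = character(), weights = "beta") {
  units <- match.arg(units, several.ok = TRUE)
  if (is.null(traits)) traits <- names(traitTypes(cohort))
  gs <- geneSets(cohort)
  if ("sets" %in% units && !length(gs)) stop("cohort has no gene sets")
  unitTab <- data.frame(unit = character(), unit_type = character(),
                        stringsAsFactors = FALSE)
  if ("sets" %in% units)
    unitTab <- rbind(unitTab, data.frame(unit = names(gs),
                                         unit_type = "set"))
  if ("genes" %in% units) {
    genes <- sort(unique(as.character(rowData(cohort)$gene)))
    unitTab <- rbind(unitTab, data.frame(unit = genes, unit_type = "gene"))
  }
  rows <- list(); vlists <- list(); k <- 0L
  for (trait in traits) {
    null <- fitNullModel(cohort, trait, covariates)
    for (u in seq_len(nrow(unitTab))) {
      genesU <- if (unitTab$unit_type[u] == "set") gs[[unitTab$unit[u]]]
                else unitTab$unit[u]
      for (cl in classes) for (ti in tiers) {
        vids <- qualifyingVariants(cohort, genesU, cl, ti)
        minV <- if (unitTab$unit_type[u] == "gene") 2L else 1L
        if (length(vids) < minV) next
        kt <- kernelSetTest(cohort, null, vids, weights)
        br <- burdenRegressionCore(
          burdenScore(cohort, vids, null@sampleIds),
          null@y, null@traitType, null@X)
        k <- k + 1L
        rows[[k]] <- data.frame(
          unit = unitTab$unit[u], unit_type = unitTab$unit_type[u],
          trait = trait, class = cl, tier = ti,
          n_variants = length(vids), kernel_p = kt$p, burden_p = br$p,
          effect = br$effect, se = br$se, backend = kt$backend,
          stringsAsFactors = FALSE)
        vlists[[k]] <- vids
      }
    }
  }
  if (!k) {
    out <- data.frame(unit = character(), unit_type = character(),
                      trait = character(), class = character(),
                      tier = character(), n_variants = integer(),
                      kernel_p = numeric(), burden_p = numeric(),
                      effect = numeric(), se = numeric(),
                      backend = character(), stringsAsFactors = FALSE)
    attr(out, "variantIds") <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(match(out$trait, traits),
               match(out$unit_type, c("set", "gene")), out$unit,
               match(out$class, CLASS_TIERS), match(out$tier, FREQ_TIERS))
  vlists <- vlists[ord]
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  names(vlists) <- testIds(out)
  attr(out, "variantIds") <- vlists
  out
}

testIds <- function(results)
  paste(results$unit, results$trait, results$class, results$tier, sep = "|")

#' Leave-one-out variant contributions to a set test
#'
#' Recomputes a unit's test excluding each qualifying variant in turn. The
#' contribution of variant `j` is the signed change in `-log10(p)` caused
#' by keeping it: `log10(p without j) - log10(p with all variants)`, so the
#' variant whose removal weakens the signal most ranks first. Ties are
#' broken by lexicographic variant id. No-test sentinels from the
#' underlying test (e.g. a set collapsing to zero variance) propagate as
#' `NA` contributions.
#'
#' @inheritParams kernelSetTest
#' @param statistic `"kernel"` (default) or `"burden"`: which of the two
#'   set tests to recompute.
#' @param covariates phenotype columns to adjust for (burden statistic
#'   refits use the null model's design).
#' @return data.frame with columns variant_id, p_excluded, contribution,
#'   rank, sorted by rank; attribute `"p_base"` holds the all-variant p.
#' @export
leaveOneOut <- function(cohort, null, variantIds, weights = "beta",
                        statistic = c("kernel", "burden")) {
  statistic <- match.arg(statistic)
  if (length(variantIds) < 2L)
    stop("leave-one-out requires at least 2 qualifying variants")
  pOf <- function(vids) {
    if (statistic == "kernel")
      kernelSetTest(cohort, null, vids, weights)$p
    else
      burdenRegressionCore(burdenScore(cohort, vids, null@sampleIds),
                           null@y, null@traitType, null@X)$p
  }
  pBase <- pOf(variantIds)
  pMinus <- vapply(variantIds,
                   function(v) pOf(setdiff(variantIds, v)), numeric(1))
  contrib <- log10(pMinus) - log10(pBase)
  out <- data.frame(variant_id = variantIds, p_excluded = pMinus,
                    contribution = contrib, stringsAsFactors = FALSE)
  out <- out[order(-out$contribution, out$variant_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "p_base") <- pBase
  out
}
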