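#' Exact two-sample Poisson rate test
#'
#' Compares per-sample accumulation rates of qualifying alleles between two
#' groups. Conditional on the total `T = c1 + c2`, the case count is
#' Binomial(T, n1/(n1+n2)) under equal per-sample rates; the two-sided
#' p-value doubles the smaller exact tail, capped at 1. The fold enrichment
#' is the ratio of per-sample rates, reported as `Inf` when the control
#' count is zero (and 0 when only the control count is positive).
#'
#' @param c1,c2 qualifying minor-allele totals in the two groups.
#' @param n1,n2 group sample counts (exposures).
#' @return list with `fold`, `p`, and the inputs. When `c1 = c2 = 0` a
#'   no-test sentinel (`p = NA`, `fold = NA`) is returned.
#' @examples
#' exactPoissonTest(10, 200, 10, 800)  # fold 4, doubled binomial tail
#' @export
exactPoissonTest <- function(c1, n1, c2, n2) {
  stopifnot(n1 > 0, n2 > 0, c1 >= 0, c2 >= 0)
  if (c1 + c2 == 0)
    return(list(c1 = c1, n1 = n1, c2 = c2, n2 = n2,
                fold = NA_real_, p = NA_real_, note = "no_test"))
  tot <- c1 + c2
  prob <- n1 / (n1 + n2)
  pLow <- stats::pbinom(c1, tot, prob)
  pHigh <- stats::pbinom(c1 - 1, tot, prob, lower.tail = FALSE)
  p <- min(1, 2 * min(pLow, pHigh))
  fold <- if (c2 == 0) Inf else (c1 / n1) / (c2 / n2)
  list(c1 = c1, n1 = n1, c2 = c2, n2 = n2, fold = fold, p = p, note = "ok")
}

#' Accumulate qualifying allele counts for a case/control split
#'
#' Sums minor-allele dosages over the qualifying variants separately in
#' cases (trait value 1) and controls (trait value 0); missing genotypes
#' contribute nothing. Exposures are the post-QC group sizes.
#'
#' @inheritParams kernelSetTest
#' @param trait binary trait defining the split.
#' @return list with `c1`, `n1` (cases), `c2`, `n2` (controls).
#' @export
accumulateCounts <- function(cohort, variantIds, trait) {
  ph <- colData(cohort)
  if (!trait %in% colnames(ph)) stop(sprintf("unknown trait '%s'", trait))
  if (traitTypes(cohort)[[trait]] != "binary")
    stop(sprintf("trait '%s' is not binary", trait))
  y <- ph[[trait]]
  cases <- which(!is.na(y) & y == 1)
  ctrls <- which(!is.na(y) & y == 0)
  countIn <- function(idx) {
    if (!length(variantIds) || !length(idx)) return(0)
    d <- minorDosage(cohort)[variantIds, idx, drop = FALSE]
    sum(d, na.rm = TRUE)
  }
  list(c1 = countIn(cases), n1 = length(cases),
       c2 = countIn(ctrls), n2 = length(ctrls))
}

#' Accumulation-rate scan
#'
#' Exact Poisson rate comparison for every binary trait x unit x class tier
#' x frequency tier cell.
#'
#' @inheritParams runBurdenScan
#' @return data.frame with columns unit, unit_type, trait, class, tier,
#'   c1, n1, c2, n2, fold, p; attribute `"variantIds"` as in
#'   [runBurdenScan()].
#' @export
runRateTests <- function(cohort, traits = NULL, units = "sets",
                         classes = CLASS_TIERS, tiers = FREQ_TIERS) {
  units <- match.arg(units, c("sets", "genes"), several.ok = TRUE)
  tt <- traitTypes(cohort)
  if (is.null(traits)) traits <- names(tt)[tt == "binary"]
  if (any(tt[traits] != "binary")) stop("rate tests need binary traits")
  gs <- geneSets(cohort)
  unitTab <- data.frame(unit = character(), unit_type = character())
  if ("sets" %in% units)
    unitTab <- rbind(unitTab, data.frame(unit = names(gs), unit_type = "set"))
  if ("genes" %in% units)
    unitTab <- rbind(unitTab, data.frame(
      unit = sort(unique(as.character(rowData(cohort)$gene))),
      unit_type = "gene"))
  rows <- list(); vlists <- list(); k <- 0L
  for (trait in traits) for (u in seq_len(nrow(unitTab)))
    for (cl in classes) for (ti in tiers) {
      genesU <- if (unitTab$unit_type[u] == "set") gs[[unitTab$unit[u]]]
                else unitTab$unit[u]
      vids <- qualifyingVariants(cohort, genesU, cl, ti)
      ac <- accumulateCounts(cohort, vids, trait)
      et <- exactPoissonTest(ac$c1, ac$n1, ac$c2, ac$n2)
      k <- k + 1L
      rows[[k]] <- data.frame(
        unit = unitTab$unit[u], unit_type = unitTab$unit_type[u],
        trait = trait, class = cl, tier = ti, c1 = ac$c1, n1 = ac$n1,
        c2 = ac$c2, n2 = ac$n2, fold = et$fold, p = et$p,
        stringsAsFactors = FALSE)
      vlists[[k]] <- vids
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(vlists) <- testIds(out)
  attr(out, "variantIds") <- vlists
  out
}
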