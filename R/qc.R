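#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test for a biallelic site: conditional on the minor
#' allele count, the probability of each possible heterozygote count is
#' computed from the standard exact distribution and the p-value sums the
#' probabilities of all configurations no more probable than the observed
#' one.
#'
#' @param nAA,nAa,naa genotype counts (major homozygote, heterozygote,
#'   minor homozygote).
#' @return exact p-value in (0, 1].
#' @export
hweExactP <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (n == 0L) return(NA_real_)
  nA <- 2L * nAA + nAa
  na <- 2L * naa + nAa
  m <- min(nA, na)                    # minor allele count
  if (m == 0L) return(1)
  # heterozygote counts share the parity of the minor allele count;
  # P(het | n, m) = n! / (homMajor! het! homMinor!) 2^het maj! m! / (2n)!
  het <- seq(m %% 2L, m, by = 2L)
  hom_minor <- (m - het) / 2L
  hom_major <- n - het - hom_minor
  logp <- lgamma(n + 1) - lgamma(hom_major + 1) - lgamma(het + 1) -
    lgamma(hom_minor + 1) + het * log(2) +
    lgamma(max(nA, na) + 1) + lgamma(m + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obsHet <- nAa
  sum(p[p <= p[match(obsHet, het)] * (1 + 1e-12)])
}

#' Quality-control filtering of a cohort
#'
#' Deterministic filter sequence, iterated to a fixed point so the result
#' is idempotent: within each pass (1) samples failing the genotype
#' call-rate threshold are removed; (2) on the remaining samples, variants
#' failing the variant call-rate threshold or with all genotypes missing
#' are removed; passes repeat until nothing changes (removing a variant
#' alters sample call rates and vice versa). Finally (3) variants whose
#' control-group genotype counts fail the exact Hardy-Weinberg test below
#' the threshold are removed. Allele frequencies and singleton/rare flags
#' are recomputed on the filtered cohort. Every exclusion is listed with
#' its reason and offending value in the report.
#'
#' @param cohort a [BurdenCohort-class].
#' @param sampleCallRate minimum per-sample genotype call rate (default 0.9).
#' @param variantCallRate minimum per-variant call rate (default 0.9).
#' @param hwePThreshold minimum control-group exact HWE p (default 1e-6).
#' @param controlTrait binary trait whose `0` level defines the control
#'   group for the HWE filter; defaults to the first binary trait. When no
#'   binary trait exists the HWE filter uses all samples.
#' @return list with `cohort` (filtered) and `report` (data.frame with
#'   columns entity, id, reason, value).
#' @export
applyQC <- function(cohort, sampleCallRate = 0.9, variantCallRate = 0.9,
                    hwePThreshold = 1e-6, controlTrait = NULL) {
  d <- dosage(cohort)
  report <- data.frame(entity = character(), id = character(),
                       reason = character(), value = numeric(),
                       stringsAsFactors = FALSE)
  keepS <- rep(TRUE, ncol(d)); keepV <- rep(TRUE, nrow(d))
  if (is.null(controlTrait)) {
    tt <- traitTypes(cohort)
    bin <- names(tt)[tt == "binary"]
    if (length(bin)) controlTrait <- bin[[1]]
  }
  repeat {
    if (!any(keepV)) break   # nothing left to filter on
    # call-rate fixed point
    repeat {
      if (!any(keepV)) break
      changed <- FALSE
      scr <- colMeans(!is.na(d[keepV, keepS, drop = FALSE]))
      badS <- scr < sampleCallRate
      if (all(badS)) stop("QC would exclude all samples (sample call rate)")
      if (any(badS)) {
        report <- rbind(report, data.frame(
          entity = "sample", id = colnames(d)[keepS][badS],
          reason = "sample_call_rate", value = scr[badS]))
        keepS[keepS] <- !badS
        changed <- TRUE
      }
      sub <- d[keepV, keepS, drop = FALSE]
      vcr <- rowMeans(!is.na(sub))
      badV <- vcr < variantCallRate
      allMiss <- rowSums(!is.na(sub)) == 0 & !badV
      if (any(badV))
        report <- rbind(report, data.frame(
          entity = "variant", id = rownames(sub)[badV],
          reason = "variant_call_rate", value = vcr[badV]))
      if (any(allMiss))
        report <- rbind(report, data.frame(
          entity = "variant", id = rownames(sub)[allMiss],
          reason = "all_missing", value = 0))
      if (any(badV | allMiss)) {
        keepV[keepV] <- !(badV | allMiss)
        changed <- TRUE
      }
      if (!changed) break
    }
    # Hardy-Weinberg in controls; removals can shift call rates, so loop
    ctrl <- rep(TRUE, sum(keepS))
    if (!is.null(controlTrait) &&
        controlTrait %in% colnames(colData(cohort))) {
      ph <- colData(cohort)[[controlTrait]][keepS]
      if (any(ph == 0, na.rm = TRUE)) ctrl <- !is.na(ph) & ph == 0
    }
    dctrl <- d[keepV, keepS, drop = FALSE][, ctrl, drop = FALSE]
    hwe <- vapply(seq_len(nrow(dctrl)), function(i) {
      g <- dctrl[i, ]
      g <- g[!is.na(g)]
      if (!length(g)) return(NA_real_)
      hweExactP(sum(g == 0), sum(g == 1), sum(g == 2))
    }, numeric(1))
    badH <- !is.na(hwe) & hwe < hwePThreshold
    if (!any(badH)) break
    report <- rbind(report, data.frame(
      entity = "variant", id = rownames(dctrl)[badH],
      reason = "hwe_controls", value = hwe[badH]))
    keepV[keepV] <- !badH
  }

  out <- updateFrequencies(cohort[keepV, keepS])
  rownames(report) <- NULL
  list(cohort = out, report = report)
}
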