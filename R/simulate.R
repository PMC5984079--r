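#' Planted effect constructor
#'
#' @param targetSet gene-set name.
#' @param targetClass `"Disruptive"`, `"NS_strict"` or `"NS_broad"`.
#' @param targetTier `"singleton"` or `"rare"`.
#' @param mode `"rate_fold"`, `"odds_ratio"` or `"beta"`.
#' @param magnitude fold / OR per allele (positive), or signed trait units
#'   per allele for `beta`.
#' @param targetTrait trait the effect acts on.
#' @return a [PlantedEffect-class].
#' @export
plantedEffect <- function(targetSet, targetClass, targetTier, mode,
                          magnitude, targetTrait) {
  new("PlantedEffect", targetSet = targetSet, targetClass = targetClass,
      targetTier = targetTier, mode = mode,
      magnitude = as.numeric(magnitude), targetTrait = targetTrait)
}

#' Simulation configuration constructor
#'
#' See [SimulationConfig-class] for slot meanings; defaults emulate the
#' targeted-sequencing study design the package is built around (three
#' diagnostic case groups plus a shared control cohort, 213 genes in two
#' sets, ~21 coding variants per gene, a rare-skewed 1/k site frequency
#' spectrum with ~78% of variants below 1% MAF).
#'
#' @param nCasesByTrait named integer vector of case counts per binary trait.
#' @param nControls shared control count.
#' @param nGenes number of genes.
#' @param genesPerSet named integer vector of gene-set sizes.
#' @param variantsPerGene mean coding variants per gene.
#' @param sfsMax truncation of the 1/k spectrum; `NA` = auto-calibrated so
#'   the expected rare fraction is ~0.78.
#' @param classProportions consequence probabilities (silent, missense,
#'   nonsense, splice).
#' @param predictorDamageProb per-predictor damaging probability for
#'   missense variants (length 1 or 5).
#' @param quantTraits names of quantitative traits.
#' @param quantControlsOnly measure quantitative traits in controls only.
#' @param missingRate genotype missingness rate.
#' @param plantedEffects list of [PlantedEffect-class].
#' @param seed integer seed; all outputs are bit-reproducible given it.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(
    nCasesByTrait = c(SCZ = 211L, BD = 195L, rMDD = 169L),
    nControls = 871L, nGenes = 213L,
    genesPerSet = c(Interactome = 59L, Regulome = 154L),
    variantsPerGene = 21,
    sfsMax = NA_integer_,
    classProportions = c(silent = 1893, missense = 2569, nonsense = 41,
                         splice = 24) / 4527,
    predictorDamageProb = 0.4,
    quantTraits = c("cognition_age11", "cognition_age70"),
    quantControlsOnly = TRUE,
    missingRate = 0,
    plantedEffects = list(),
    seed = 1L) {
  cp <- classProportions / sum(classProportions)
  new("SimulationConfig",
      nCasesByTrait = stats::setNames(as.integer(nCasesByTrait),
                                      names(nCasesByTrait)),
      nControls = as.integer(nControls), nGenes = as.integer(nGenes),
      genesPerSet = stats::setNames(as.integer(genesPerSet),
                                    names(genesPerSet)),
      variantsPerGene = variantsPerGene, sfsMax = as.integer(sfsMax),
      classProportions = cp, predictorDamageProb = predictorDamageProb,
      quantTraits = quantTraits, quantControlsOnly = quantControlsOnly,
      missingRate = missingRate, plantedEffects = plantedEffects,
      seed = as.integer(seed))
}

#' @describeIn simulationConfig display method.
#' @param object a `SimulationConfig`.
#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %s cases + %d controls; %d genes (%s); ~%.0f variants/gene; %d planted effect(s); seed %d\n",
    paste(sprintf("%s=%d", names(object@nCasesByTrait),
                  object@nCasesByTrait), collapse = "/"),
    object@nControls, object@nGenes,
    paste(sprintf("%s=%d", names(object@genesPerSet), object@genesPerSet),
          collapse = "/"),
    object@variantsPerGene, length(object@plantedEffects), object@seed))
  invisible(NULL)
})

# Truncation point of the 1/k spectrum chosen so the expected fraction of
# variants with MAF < 1% is as close as possible to `target` (default the
# 78% rare fraction of deeply sequenced candidate-gene panels). Closed-form
# search over harmonic sums; independent of any random draw.
calibrateSfsMax <- function(nSamples, target = 0.78) {
  kRare <- ceiling(0.02 * nSamples) - 1L   # largest k with k/(2N) < 0.01
  kRare <- max(kRare, 1L)
  H <- cumsum(1 / seq_len(nSamples))       # k capped at N so MAF <= 0.5
  frac <- H[kRare] / H
  kmax <- which.min(abs(frac - target))
  max(kmax, kRare + 1L, 2L)
}

sfsProbabilities <- function(kmax) {
  p <- 1 / seq_len(kmax)
  p / sum(p)
}

# Exact fixed-size sampling with probability of a selected set proportional
# to the product of per-sample weights (conditional Poisson sampling): the
# distribution of case labels under a prospective logistic model given the
# attained case total. Burden weights take few distinct values, so the
# per-weight-class selection counts follow a multivariate Fisher
# noncentral hypergeometric law sampled exactly by log-space convolution
# and backward sampling; members within a class are exchangeable.
sampleFixedSizeWeighted <- function(logw, n1) {
  N <- length(logw)
  stopifnot(n1 <= N)
  if (length(unique(logw)) == 1L) return(sample.int(N, n1))
  lw <- sort(unique(logw))
  grp <- match(logw, lw)
  C <- length(lw)
  Ns <- tabulate(grp, C)
  logsumexp <- function(x) {
    mx <- max(x)
    if (!is.finite(mx)) return(-Inf)
    mx + log(sum(exp(x - mx)))
  }
  f <- lapply(seq_len(C), function(cc) {
    k <- 0:min(Ns[cc], n1)
    lchoose(Ns[cc], k) + k * lw[cc]
  })
  G <- vector("list", C)
  G[[1]] <- rep(-Inf, n1 + 1L)
  G[[1]][seq_along(f[[1]])] <- f[[1]]
  for (cc in seq_len(C)[-1]) {
    g <- rep(-Inf, n1 + 1L)
    for (t in 0:n1) {
      k <- 0:min(length(f[[cc]]) - 1L, t)
      g[t + 1L] <- logsumexp(f[[cc]][k + 1L] + G[[cc - 1L]][t - k + 1L])
    }
    G[[cc]] <- g
  }
  ks <- integer(C)
  t <- n1
  for (cc in rev(seq_len(C)[-1])) {
    k <- 0:min(length(f[[cc]]) - 1L, t)
    lp <- f[[cc]][k + 1L] + G[[cc - 1L]][t - k + 1L]
    pr <- exp(lp - logsumexp(lp))
    ks[cc] <- k[sample.int(length(k), 1L, prob = pr)]
    t <- t - ks[cc]
  }
  ks[1L] <- t
  sel <- integer(0)
  for (cc in seq_len(C)) {
    members <- which(grp == cc)
    if (ks[cc] > 0L)
      sel <- c(sel, members[sample.int(length(members), ks[cc])])
  }
  sel
}

#' Simulate a synthetic case-control cohort
#'
#' Generates a cohort with the statistical structure the burden analysis
#' assumes: minor-allele counts drawn from a truncated 1/k site frequency
#' spectrum and scattered over chromosomes at random; consequences and
#' predictor verdicts drawn from the configured proportions; binary traits
#' realised by selecting each case group from the sample pool (uniformly
#' under the null; under planted `odds_ratio`/`rate_fold` effects by
#' weighted sampling without replacement with weight
#' `magnitude^(qualifying allele count)`, the case-control sampling
#' equivalent of a prospective logistic model conditioned on the attained
#' case total); quantitative traits as the planted per-allele effects plus
#' unit-variance Gaussian noise. A `combined` binary trait (all cases vs
#' controls) is added automatically.
#'
#' @param config a [SimulationConfig-class].
#' @return a [BurdenCohort-class] with annotation, frequencies, phenotypes
#'   and gene sets filled in.
#' @export
simulateCohort <- function(config) {
  validObject(config)
  withSeed(config@seed, simulateCohortImpl(config))
}

simulateCohortImpl <- function(config) {
  nCase <- config@nCasesByTrait
  nTot <- sum(nCase) + config@nControls
  sampleIds <- sprintf("S%05d", seq_len(nTot))

  # genes and gene sets
  geneIds <- sprintf("GENE%04d", seq_len(config@nGenes))
  setAssign <- rep(NA_character_, config@nGenes)
  off <- 0L
  gs <- list()
  for (nm in names(config@genesPerSet)) {
    idx <- off + seq_len(config@genesPerSet[[nm]])
    gs[[nm]] <- geneIds[idx]
    setAssign[idx] <- nm
    off <- off + config@genesPerSet[[nm]]
  }

  # variants: positions, consequences, verdicts
  nPerGene <- stats::rpois(config@nGenes, config@variantsPerGene)
  if (sum(nPerGene) == 0L) nPerGene[1L] <- 1L
  gene <- rep(geneIds, nPerGene)
  M <- length(gene)
  chrom <- rep(sprintf("chr%d", (seq_len(config@nGenes) - 1L) %% 22L + 1L),
               nPerGene)
  offset <- unlist(lapply(nPerGene[nPerGene > 0], function(m)
    sort(sample.int(50000L, m))), use.names = FALSE)
  pos <- rep((seq_len(config@nGenes) - 1L) %/% 22L * 100000L + 1000L,
             nPerGene) + offset
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, M, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  consequence <- sample(names(config@classProportions), M, replace = TRUE,
                        prob = config@classProportions)
  pd <- rep(config@predictorDamageProb, length.out = 5L)
  verdicts <- matrix(NA_character_, M, 5L,
                     dimnames = list(NULL, PREDICTORS))
  mis <- consequence == "missense"
  for (j in 1:5)
    verdicts[mis, j] <- ifelse(stats::runif(sum(mis)) < pd[j],
                               "damaging", "tolerated")
  functionalClass <- classifyVariants(consequence, verdicts)

  # genotypes: k minor alleles per variant dropped on 2N chromosomes
  kmax <- if (is.na(config@sfsMax)) calibrateSfsMax(nTot) else config@sfsMax
  kv <- sample.int(kmax, M, replace = TRUE, prob = sfsProbabilities(kmax))
  dos <- matrix(0L, M, nTot, dimnames = list(NULL, sampleIds))
  for (i in seq_len(M)) {
    owner <- (sample.int(2L * nTot, kv[i]) + 1L) %/% 2L
    dup <- duplicated(owner)          # both chromosomes hit: homozygote
    dos[i, owner[!dup]] <- 1L
    if (any(dup)) dos[i, owner[dup]] <- 2L
  }
  variantIds <- sprintf("%s:%d_%s/%s", chrom, pos, ref, alt)
  dup <- duplicated(variantIds)
  if (any(dup))
    variantIds[dup] <- sprintf("%s.%d", variantIds[dup], seq_len(sum(dup)))
  rownames(dos) <- variantIds

  # frequency tiers before missingness (true allele counts drive planting)
  singleton <- kv == 1L
  rare <- kv / (2 * nTot) < 0.01

  qualifyingFor <- function(pe) {
    ok <- gene %in% gs[[pe@targetSet]] &
      qualifyingClass(functionalClass, pe@targetClass) &
      (if (pe@targetTier == "singleton") singleton else rare)
    which(ok)
  }
  for (pe in config@plantedEffects)
    if (!length(qualifyingFor(pe)))
      stop(sprintf(
        "planted effect selects zero variants (%s / %s / %s)",
        pe@targetSet, pe@targetClass, pe@targetTier))

  # case-group assignment (weighted under planted binary effects)
  logW <- matrix(0, nTot, length(nCase),
                 dimnames = list(NULL, names(nCase)))
  for (pe in config@plantedEffects) {
    if (pe@mode == "beta") next
    s <- colSums(dos[qualifyingFor(pe), , drop = FALSE])
    logW[, pe@targetTrait] <- logW[, pe@targetTrait] +
      log(pe@magnitude) * s
  }
  pool <- seq_len(nTot)
  groups <- rep("control", nTot)
  for (tr in names(nCase)) {
    sel <- pool[sampleFixedSizeWeighted(logW[pool, tr], nCase[[tr]])]
    groups[sel] <- tr
    pool <- setdiff(pool, sel)
  }

  # phenotype table
  ph <- DataFrame(row.names = sampleIds)
  for (tr in names(nCase)) {
    v <- rep(NA_real_, nTot)
    v[groups == tr] <- 1
    v[groups == "control"] <- 0
    ph[[tr]] <- v
  }
  ph$combined <- ifelse(groups == "control", 0, 1)
  for (qt in config@quantTraits) {
    mu <- rep(0, nTot)
    for (pe in config@plantedEffects) {
      if (pe@mode != "beta" || pe@targetTrait != qt) next
      s <- colSums(dos[qualifyingFor(pe), , drop = FALSE])
      mu <- mu + pe@magnitude * s
    }
    v <- mu + stats::rnorm(nTot)
    if (config@quantControlsOnly) v[groups != "control"] <- NA_real_
    ph[[qt]] <- v
  }

  # genotype missingness
  dosNum <- dos * 1
  if (config@missingRate > 0) {
    miss <- stats::runif(length(dosNum)) < config@missingRate
    dosNum[miss] <- NA_real_
  }

  vi <- DataFrame(
    variant_id = variantIds, chrom = chrom, pos = as.integer(pos),
    ref = ref, alt = alt, gene = gene, consequence = consequence,
    sift = verdicts[, 1], pph2_div = verdicts[, 2],
    pph2_var = verdicts[, 3], lrt = verdicts[, 4],
    mutation_taster = verdicts[, 5],
    functional_class = functionalClass, row.names = variantIds)
  tt <- c(stats::setNames(rep("binary", length(nCase) + 1L),
                          c(names(nCase), "combined")),
          stats::setNames(rep("quantitative", length(config@quantTraits)),
                          config@quantTraits))
  BurdenCohort(dosNum, vi, ph, geneSets = gs, traitTypes = tt)
}
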