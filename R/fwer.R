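#' @importFrom stats setNames
NULL

# Permutation of a sample subset induced by a global permutation: the
# elements of A reordered as the global permutation arranges them. Keeps
# families on overlapping sample subsets correlated across resamples.
induceSubPermutation <- function(perm, A) {
  q <- perm[perm %in% A]
  match(q, A)
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Permutation for one resample
#'
#' Deterministically derives the permutation used for resample `b` from the
#' master seed, so families can be evaluated in any order (or in parallel)
#' with identical results.
#'
#' @param n number of samples.
#' @param seed master seed (integer).
#' @param b resample index in `1..B`.
#' @return integer permutation of `1..n`.
#' @export
permutationForResample <- function(n, seed, b) {
  s <- (as.numeric(seed) %% 1000003) * 2011 + as.numeric(b)
  withSeed(as.integer(s %% 2147483647), sample.int(n))
}

#' With-replacement bootstrap indices for one resample
#'
#' Companion to [permutationForResample()] drawing `n` sample indices with
#' replacement; provided for comparing the label-permutation null with a
#' true bootstrap.
#' @inheritParams permutationForResample
#' @return integer vector of length `n`.
#' @export
bootstrapForResample <- function(n, seed, b) {
  s <- (as.numeric(seed) %% 1000003) * 2011 + as.numeric(b)
  withSeed(as.integer(s %% 2147483647),
           sample.int(n, n, replace = TRUE))
}

#' Resample phenotypes under the joint null
#'
#' Applies a single random permutation of sample indices simultaneously to
#' every phenotype column, preserving cross-trait phenotype correlation and
#' each sample's missing-phenotype pattern while breaking the
#' genotype-phenotype link. Sample ids keep their original order (the
#' phenotype rows move beneath them).
#'
#' @param cohort a [BurdenCohort-class] (or anything with `colData`).
#' @param seed master seed.
#' @param b resample index.
#' @return `DataFrame` of permuted phenotypes, rownames the original ids.
#' @export
resampleNull <- function(cohort, seed, b) {
  ph <- colData(cohort)
  perm <- permutationForResample(nrow(ph), seed, b)
  out <- ph[perm, , drop = FALSE]
  rownames(out) <- rownames(ph)
  out
}

#' Single-step min-p family-wise error adjustment
#'
#' Westfall-Young single-step procedure: for each of `B` phenotype
#' permutations all member p-values are recomputed; within each scope
#' (each trait family, and the across-traits family of all members) the
#' minimum resampled p is recorded, and the adjusted p of an observed value
#' `p0` is `(1 + #\{b : min_b <= p0\}) / (B + 1)`, floored at the member's
#' raw p so the adjustment can never undercut the unadjusted value.
#'
#' @param pfun function taking an integer sample permutation and returning
#'   the vector of member p-values (aligned with `observed`; `NA` entries
#'   are ignored in the minima).
#' @param observed named numeric vector of observed member p-values.
#' @param groups character/factor of the same length assigning each member
#'   to its within-trait family.
#' @param nSamples number of samples the permutations act on.
#' @param B number of resamples (default 10000; below 100 a warning).
#' @param seed master seed.
#' @param resampler function `(n, seed, b)` producing the index vector for
#'   resample `b`; default label permutation
#'   ([permutationForResample()]), the Westfall-Young construction. A
#'   with-replacement bootstrap resampler ([bootstrapForResample()]) is
#'   available for fidelity comparisons.
#' @return list with `table` (data.frame: id, group, raw_p, fwer_within_p,
#'   fwer_across_p, B), `minpWithin` (per-group vector of resampled minima)
#'   and `minpAcross`.
#' @export
fwerAdjust <- function(pfun, observed, groups, nSamples, B = 10000L,
                       seed = 1L, resampler = permutationForResample) {
  stopifnot(length(observed) == length(groups))
  if (B < 100) warning("B < 100 resamples: adjusted p-values are coarse")
  ids <- names(observed)
  if (is.null(ids)) ids <- as.character(seq_along(observed))
  groups <- as.character(groups)
  ok <- !is.na(observed)
  P <- matrix(NA_real_, B, length(observed))
  for (b in seq_len(B)) {
    pb <- pfun(resampler(nSamples, seed, b))
    if (length(pb) != length(observed))
      stop("pfun returned a vector of the wrong length")
    P[b, ] <- pb
  }
  P[is.na(P)] <- Inf
  minAcross <- apply(P[, ok, drop = FALSE], 1, min)
  adjA <- vapply(seq_along(observed), function(i) {
    if (!ok[i]) return(NA_real_)
    (1 + sum(minAcross <= observed[i])) / (B + 1)
  }, numeric(1))
  minWithin <- list()
  adjW <- rep(NA_real_, length(observed))
  for (g in unique(groups)) {
    sel <- groups == g & ok
    if (!any(sel)) next
    mg <- apply(P[, sel, drop = FALSE], 1, min)
    minWithin[[g]] <- mg
    adjW[sel] <- vapply(which(sel), function(i)
      (1 + sum(mg <= observed[i])) / (B + 1), numeric(1))
  }
  tab <- data.frame(
    id = ids, group = groups, raw_p = as.numeric(observed),
    fwer_within_p = pmin(1, pmax(adjW, observed)),
    fwer_across_p = pmin(1, pmax(adjA, adjW, observed)),
    B = B, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab, minpWithin = minWithin, minpAcross = minAcross)
}

#' Bootstrap/permutation FWER adjustment of scan and rate results
#'
#' Builds the test families from burden-scan and rate-test results (each
#' result row contributes its kernel, burden and/or rate p-value as a
#' family member), recomputes every member under joint phenotype
#' resampling, and returns the results annotated with `fwer_within_p`
#' (family: all members of the same trait) and `fwer_across_p` (family:
#' all members). By default the null is resampled by label permutation,
#' which preserves the phenotype marginals exactly; `replace = TRUE`
#' switches to a with-replacement bootstrap of sample indices.
#'
#' @param cohort the [BurdenCohort-class] the results were computed on.
#' @param burdenResults result of [runBurdenScan()] (or `NULL`).
#' @param rateResults result of [runRateTests()] (or `NULL`).
#' @param B number of resamples.
#' @param seed master seed.
#' @param weights kernel weight scheme used in the scan.
#' @param covariates covariates used in the scan.
#' @param replace resample with replacement (bootstrap) instead of
#'   permuting labels.
#' @return data.frame with columns id, stat, unit, unit_type, trait, class,
#'   tier, raw_p, fwer_within_p, fwer_across_p, B.
#' @export
adjustResults <- function(cohort, burdenResults = NULL, rateResults = NULL,
                          B = 10000L, seed = 1L, weights = "beta",
                          covariates = character(), replace = FALSE) {
  members <- list(); k <- 0L
  addMembers <- function(res, stats_) {
    vl <- attr(res, "variantIds")
    for (i in seq_len(nrow(res))) for (st in stats_) {
      p0 <- res[[if (st == "kernel") "kernel_p" else
                 if (st == "burden") "burden_p" else "p"]][i]
      k <<- k + 1L
      members[[k]] <<- list(
        id = paste(testIds(res[i, ]), st, sep = "|"), stat = st,
        unit = res$unit[i], unit_type = res$unit_type[i],
        trait = res$trait[i], class = res$class[i], tier = res$tier[i],
        vids = vl[[i]], raw = p0)
    }
  }
  if (!is.null(burdenResults) && nrow(burdenResults))
    addMembers(burdenResults, c("kernel", "burden"))
  if (!is.null(rateResults) && nrow(rateResults)) addMembers(rateResults, "rate")
  if (!k) stop("no tests to adjust")

  ph <- colData(cohort)
  n <- nrow(ph)
  traits <- unique(vapply(members, `[[`, "", "trait"))
  tt <- traitTypes(cohort)

  # The null is resampled by jointly permuting each trait family's
  # (phenotype, covariate) rows within the set of samples that family's
  # tests actually use (traits measured on disjoint subsets keep their
  # sample base and case counts). The within-family permutation is induced
  # from one global permutation per resample, so families sharing samples
  # stay correlated. Because the permuted null-model residuals are then a
  # permutation of the observed ones, every kernel null preparation
  # (eigen-spectra, exact permutation moments, skewness df) is computed
  # once per cell and reused across all resamples.
  traitPrep <- list()
  for (trait in traits) {
    null <- fitNullModel(cohort, trait, covariates)
    A <- match(null@sampleIds, colnames(cohort))
    idx <- which(vapply(members, function(m) m$trait == trait, TRUE))
    cellPrep <- list()
    for (i in idx) {
      m <- members[[i]]
      key <- paste(m$unit, m$class, m$tier, sep = "|")
      if (!is.null(cellPrep[[key]])) next
      vids <- m$vids
      if (!length(vids)) { cellPrep[[key]] <- list(empty = TRUE); next }
      wg <- weightedGenotypes(cohort, vids, null@sampleIds, weights)
      s <- burdenScore(cohort, vids, null@sampleIds)
      r <- null@y - null@mu
      kPrep <- if (!ncol(wg$Gw)) NULL
        else if (null@traitType == "quantitative")
          kernelQuantPrep(wg$Gw, null@X, sum(r^2))
        else kernelBinaryPrep(wg$Gw, null@X, null@varFun, r)
      cellPrep[[key]] <- list(empty = FALSE, Gw = wg$Gw, s = s,
                              kPrep = kPrep)
    }
    traitPrep[[trait]] <- list(null = null, A = A, idx = idx,
                               r = null@y - null@mu, cells = cellPrep)
  }
  pfun <- function(perm) {
    out <- numeric(k)
    for (trait in traits) {
      tp <- traitPrep[[trait]]
      sigma <- induceSubPermutation(perm, tp$A)
      rB <- tp$r[sigma]
      yB <- tp$null@y[sigma]
      XB <- tp$null@X[sigma, , drop = FALSE]
      for (i in tp$idx) {
        m <- members[[i]]
        pc <- tp$cells[[paste(m$unit, m$class, m$tier, sep = "|")]]
        out[i] <- if (pc$empty) NA_real_
        else if (m$stat == "rate") {
          cs <- sum(pc$s[yB == 1]); cc <- sum(pc$s[yB == 0])
          exactPoissonTest(cs, sum(yB == 1), cc, sum(yB == 0))$p
        } else if (m$stat == "burden") {
          burdenPFast(pc$s, yB, tt[[trait]], XB)
        } else {
          if (is.null(pc$kPrep)) NA_real_
          else pc$kPrep$pOf(sum(crossprod(pc$Gw, rB)^2))$p
        }
      }
    }
    out
  }
  observed <- setNames(vapply(members, function(m) as.numeric(m$raw),
                              numeric(1)),
                       vapply(members, `[[`, "", "id"))
  groups <- vapply(members, `[[`, "", "trait")
  base <- fwerAdjust(pfun, observed, groups, n, B = B, seed = seed,
                     resampler = if (replace) bootstrapForResample
                                 else permutationForResample)
  tab <- base$table
  meta <- data.frame(
    stat = vapply(members, `[[`, "", "stat"),
    unit = vapply(members, `[[`, "", "unit"),
    unit_type = vapply(members, `[[`, "", "unit_type"),
    trait = vapply(members, `[[`, "", "trait"),
    class = vapply(members, `[[`, "", "class"),
    tier = vapply(members, `[[`, "", "tier"), stringsAsFactors = FALSE)
  cbind(id = tab$id, meta,
        data.frame(raw_p = tab$raw_p, fwer_within_p = tab$fwer_within_p,
                   fwer_across_p = tab$fwer_across_p, B = tab$B))
}
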