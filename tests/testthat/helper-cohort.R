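# Build a small cohort directly from a dosage matrix and minimal
# annotation. Variants default to damaging missense so they qualify for
# every class tier; consequences/verdicts can be overridden per variant.
makeCohort <- function(dosage, genes, consequence = NULL, verdicts = NULL,
                       phenotypes, geneSets = NULL) {
  m <- nrow(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("chr1:%d_A/G", seq_len(m) * 10L)
  if (is.null(consequence)) consequence <- rep("missense", m)
  if (is.null(verdicts))
    verdicts <- matrix("damaging", m, 5,
                       dimnames = list(NULL, c("sift", "pph2_div",
                                               "pph2_var", "lrt",
                                               "mutation_taster")))
  vi <- data.frame(
    variant_id = rownames(dosage), chrom = "chr1",
    pos = seq_len(m) * 10L, ref = "A", alt = "G", gene = genes,
    consequence = consequence,
    sift = verdicts[, 1], pph2_div = verdicts[, 2],
    pph2_var = verdicts[, 3], lrt = verdicts[, 4],
    mutation_taster = verdicts[, 5], stringsAsFactors = FALSE)
  if (is.null(geneSets))
    geneSets <- list(SetA = unique(as.character(genes)))
  BurdenCohort(dosage, vi, phenotypes, geneSets = geneSets)
}

# Dosage matrix with prescribed minor-allele counts, one carrier per
# allele by default (no homozygotes unless mac > n).
dosageWithMac <- function(mac, n, seed = 1) {
  withr::with_seed(seed, {
    d <- matrix(0, length(mac), n)
    for (j in seq_along(mac)) {
      idx <- sample.int(n, mac[j])
      d[j, idx] <- 1
    }
    rownames(d) <- sprintf("chr1:%d_A/G", seq_along(mac) * 10L)
    d
  })
}

namedDosage <- function(d) {
  rownames(d) <- sprintf("chr1:%d_A/G", seq_len(nrow(d)) * 10L)
  d
}

# All permutations of 1..n (for exhaustive permutation oracles, tiny n).
allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in allPermutations(n - 1L))
    for (pos in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}
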