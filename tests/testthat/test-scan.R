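# A cohort where every gene has two disruptive singletons and two
# disruptive mac-2 variants, so every unit x class x tier cell is eligible.
fullyEligibleCohort <- function(nGenes = 5, n = 150, seed = 30) {
  m <- nGenes * 4
  mac <- rep(c(1, 1, 2, 2), nGenes)
  d <- dosageWithMac(mac, n, seed = seed)
  genes <- rep(sprintf("G%d", seq_len(nGenes)), each = 4)
  withr::with_seed(seed + 1, {
    ph <- data.frame(cc1 = rbinom(n, 1, 0.4), cc2 = rbinom(n, 1, 0.5),
                     qt1 = rnorm(n), qt2 = rnorm(n))
  })
  makeCohort(d, genes, consequence = rep("nonsense", m),
             phenotypes = ph,
             geneSets = list(SetA = sprintf("G%d", 1:3),
                             SetB = sprintf("G%d", 4:5)))
}

test_that("the scan grid produces one row per eligible cell", {
  co <- fullyEligibleCohort()
  res <- runBurdenScan(co)
  # (2 sets + 5 genes) x 4 traits x 3 classes x 2 tiers
  expect_equal(nrow(res), 7 * 4 * 3 * 2)
  expect_equal(colnames(res),
               c("unit", "unit_type", "trait", "class", "tier",
                 "n_variants", "kernel_p", "burden_p", "effect", "se",
                 "backend"))
  expect_true(all(res$n_variants[res$unit_type == "gene"] >= 2))
})

test_that("genes with at most one rare variant are excluded gene-wide", {
  n <- 150
  # G1 has two rare variants, G2 exactly one
  d <- dosageWithMac(c(1, 2, 1), n, seed = 9)
  co <- makeCohort(d, c("G1", "G1", "G2"),
                   consequence = rep("nonsense", 3),
                   phenotypes = data.frame(
                     cc = rep(0:1, n / 2)),
                   geneSets = list(SetA = c("G1", "G2")))
  res <- runBurdenScan(co, tiers = "rare")
  expect_false("G2" %in% res$unit[res$unit_type == "gene"])
  expect_true("G1" %in% res$unit[res$unit_type == "gene"])
  # the singleton in G2 still contributes to the pooled set test
  vl <- attr(res, "variantIds")
  setRow <- which(res$unit == "SetA" & res$class == "Disruptive" &
                  res$tier == "rare")
  expect_true(rownames(co)[3] %in% vl[[setRow]])
})

test_that("rescanning identical input reproduces identical results", {
  co <- fullyEligibleCohort()
  r1 <- runBurdenScan(co)
  r2 <- runBurdenScan(co)
  expect_identical(r1, r2)
})

test_that("leave-one-out ranks the signal-carrying variant first", {
  withr::with_seed(14, {
    n <- 400; m <- 6
    d <- dosageWithMac(c(12, rep(6, m - 1)), n)
    y <- 2.5 * d[1, ] + rnorm(n)
    co <- makeCohort(d, rep("G1", m), phenotypes = data.frame(qt = y))
    nl <- fitNullModel(co, "qt")
    lo <- leaveOneOut(co, nl, rownames(d))
    expect_equal(lo$variant_id[1], rownames(d)[1])
    expect_equal(lo$rank, 1:m)
    expect_gt(lo$contribution[1], 0)
  })
})

test_that("variants carried by no phenotyped sample contribute nothing", {
  withr::with_seed(15, {
    n <- 100
    d <- dosageWithMac(c(8, 5, 3), n)
    ph <- data.frame(qt = rnorm(n))
    ph$qt[d[3, ] > 0] <- NA           # variant 3 carriers unphenotyped
    co <- makeCohort(d, rep("G1", 3), phenotypes = ph)
    nl <- fitNullModel(co, "qt")
    lo <- leaveOneOut(co, nl, rownames(d))
    expect_equal(lo$contribution[lo$variant_id == rownames(d)[3]], 0,
                 tolerance = 1e-12)
  })
})

test_that("duplicated variants tie and break deterministically", {
  withr::with_seed(16, {
    n <- 120
    base <- dosageWithMac(c(6, 4), n)
    d <- rbind(base, base[1, , drop = FALSE])   # variant 3 == variant 1
    rownames(d) <- c("chr1:10_A/G", "chr1:20_A/G", "chr1:30_A/G")
    y <- rnorm(n) + d[1, ]
    co <- makeCohort(d, rep("G1", 3), phenotypes = data.frame(qt = y))
    nl <- fitNullModel(co, "qt")
    lo <- leaveOneOut(co, nl, rownames(d))
    c1 <- lo$contribution[lo$variant_id == "chr1:10_A/G"]
    c3 <- lo$contribution[lo$variant_id == "chr1:30_A/G"]
    expect_equal(c1, c3, tolerance = 1e-9)
    expect_true(which(lo$variant_id == "chr1:10_A/G") <
                which(lo$variant_id == "chr1:30_A/G"))
    expect_error(leaveOneOut(co, nl, rownames(d)[1]), "at least 2")
  })
})
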