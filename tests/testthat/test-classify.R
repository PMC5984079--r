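dmg <- function(k) c(rep("damaging", k), rep("tolerated", 5 - k))

test_that("functional classes follow the tiered damaging rules", {
  v <- rbind(dmg(0), dmg(5), dmg(1), dmg(0), dmg(3), dmg(0))
  cls <- classifyVariants(
    c("nonsense", "missense", "missense", "missense", "missense", "silent"),
    v)
  expect_equal(as.character(cls),
               c("DISRUPTIVE", "NS_STRICT", "NS_BROAD", "NEUTRAL_MISSENSE",
                 "NS_BROAD", "SILENT"))
  # splice behaves like nonsense regardless of verdicts
  expect_equal(as.character(classifyVariants("splice", rbind(dmg(5)))),
               "DISRUPTIVE")
  # NA verdicts count as not damaging: 1 damaging + 4 NA is broad not strict
  vNA <- matrix(c("damaging", rep(NA_character_, 4)), 1)
  expect_equal(as.character(classifyVariants("missense", vNA)), "NS_BROAD")
})

test_that("unknown consequence labels map to OTHER with a warning", {
  expect_warning(cls <- classifyVariants(c("frameshift", "silent"),
                                         rbind(dmg(0), dmg(0))),
                 "OTHER")
  expect_equal(as.character(cls), c("OTHER", "SILENT"))
})

test_that("qualifying class sets are nested for random annotations", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      m <- 50
      cons <- sample(c("silent", "missense", "nonsense", "splice"), m,
                     replace = TRUE, prob = c(.4, .55, .03, .02))
      v <- matrix(sample(c("damaging", "tolerated", NA), m * 5,
                         replace = TRUE), m, 5)
      cls <- classifyVariants(cons, v)
      dis <- which(qualifyingClass(cls, "Disruptive"))
      str <- which(qualifyingClass(cls, "NS_strict"))
      brd <- which(qualifyingClass(cls, "NS_broad"))
      expect_true(all(dis %in% str))
      expect_true(all(str %in% brd))
    }
  })
})

test_that("allele frequencies, singletons and rare flags are exact", {
  # one het among 3 samples: MAF 1/6, a singleton; in a cohort this tiny
  # the strict MAF < 1% rule does not label it rare (1/6 > 0.01)
  fr <- computeFrequencies(matrix(c(0, 0, 1), 1, 3))
  expect_equal(fr$maf, 1 / 6)
  expect_true(fr$is_singleton)
  expect_false(fr$is_rare)
  # the same singleton in a cohort of 60 is rare
  fr60 <- computeFrequencies(matrix(c(1, rep(0, 59)), 1, 60))
  expect_true(fr60$is_singleton && fr60$is_rare)
  # monomorphic: MAF 0, not singleton
  fr0 <- computeFrequencies(matrix(0, 1, 4))
  expect_equal(fr0$maf, 0)
  expect_false(fr0$is_singleton)
  # minor count 3 in 100 samples: MAF 0.015, not rare (strict < 1%)
  d <- matrix(0, 1, 100); d[1, 1:3] <- 1
  fr3 <- computeFrequencies(d)
  expect_equal(fr3$maf, 0.015)
  expect_false(fr3$is_rare)
  # missing genotypes leave the denominator
  dm <- matrix(c(1, 0, NA, NA), 1, 4)
  expect_equal(computeFrequencies(dm)$maf, 1 / 4)
  # all-missing flagged
  expect_true(computeFrequencies(matrix(NA_real_, 1, 3))$all_missing)
})

test_that("frequencies are invariant to allele relabeling", {
  withr::with_seed(7, {
    d <- matrix(rbinom(300, 2, 0.3), 10, 30)
    flip <- sample(10, 4)
    d2 <- d; d2[flip, ] <- 2 - d2[flip, ]
    a <- computeFrequencies(d); b <- computeFrequencies(d2)
    expect_equal(a$maf, b$maf)
    expect_equal(a$mac, b$mac)
    expect_equal(a$is_singleton, b$is_singleton)
    expect_equal(a$is_rare, b$is_rare)
  })
})

test_that("singletons are a subset of rare variants in cohorts above 50", {
  withr::with_seed(3, {
    d <- dosageWithMac(sample(1:20, 30, replace = TRUE), 60)
    fr <- computeFrequencies(d)
    expect_true(all(fr$is_rare[fr$is_singleton]))
  })
})
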