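smallConfig <- function(seed = 1, ...) {
  simulationConfig(nCasesByTrait = c(CASE = 60L), nControls = 140L,
                   nGenes = 20L, genesPerSet = c(SetA = 10L, SetB = 10L),
                   quantTraits = "qt", quantControlsOnly = FALSE,
                   seed = seed, ...)
}

test_that("simulation is bit-reproducible given a seed", {
  c1 <- simulateCohort(smallConfig(7))
  c2 <- simulateCohort(smallConfig(7))
  expect_identical(dosage(c1), dosage(c2))
  expect_identical(as.data.frame(variantInfo(c1)),
                   as.data.frame(variantInfo(c2)))
  expect_identical(as.data.frame(phenotypes(c1)),
                   as.data.frame(phenotypes(c2)))
  c3 <- simulateCohort(smallConfig(8))
  expect_false(identical(dosage(c1), dosage(c3)))
})

test_that("the default frequency spectrum is rare-skewed (~78% rare)", {
  co <- simulateCohort(simulationConfig(
    nCasesByTrait = c(CASE = 250L), nControls = 750L, nGenes = 120L,
    genesPerSet = c(SetA = 60L, SetB = 60L), quantTraits = character(),
    seed = 19))
  expect_equal(mean(rowData(co)$is_rare), 0.78, tolerance = 0.05)
  expect_lte(max(rowData(co)$maf), 0.5)
})

test_that("group sizes, traits and annotations are structured correctly", {
  co <- simulateCohort(simulationConfig(
    nCasesByTrait = c(SCZ = 30L, BD = 25L), nControls = 100L,
    nGenes = 10L, genesPerSet = c(SetA = 4L, SetB = 6L),
    quantTraits = "cog", seed = 3))
  ph <- phenotypes(co)
  expect_equal(sum(ph$SCZ == 1, na.rm = TRUE), 30)
  expect_equal(sum(ph$BD == 1, na.rm = TRUE), 25)
  expect_equal(sum(ph$combined == 1), 55)
  expect_equal(sum(ph$SCZ == 0, na.rm = TRUE), 100)
  # cognition measured in controls only by default
  expect_equal(sum(!is.na(ph$cog)), 100)
  rd <- variantInfo(co)
  # verdicts exist only for missense variants
  mis <- rd$consequence == "missense"
  expect_true(all(!is.na(rd$sift[mis])))
  expect_true(all(is.na(rd$sift[!mis])))
  expect_equal(lengths(geneSets(co)), c(SetA = 4L, SetB = 6L))
})

test_that("planted effects that select no variants are rejected", {
  cfg <- smallConfig(5, variantsPerGene = 2,
                     classProportions = c(silent = 1, missense = 0,
                                          nonsense = 0, splice = 0),
                     plantedEffects = list(plantedEffect(
                       "SetA", "Disruptive", "singleton", "rate_fold",
                       3, "CASE")))
  expect_error(simulateCohort(cfg), "zero variants")
})

test_that("null cohorts have equal case and control accumulation rates", {
  withr::with_seed(31, {
    folds <- c(0, 0)
    for (s in 1:30) {
      co <- simulateCohort(smallConfig(400 + s))
      vids <- qualifyingVariants(co, unlist(geneSets(co)), "NS_broad",
                                 "rare")
      ac <- accumulateCounts(co, vids, "CASE")
      folds <- folds + c(ac$c1 / ac$n1, ac$c2 / ac$n2)
    }
    expect_equal(folds[1] / folds[2], 1, tolerance = 0.15)
  })
})

test_that("fixed-size weighted sampling follows the product-weight law", {
  withr::with_seed(33, {
    logw <- log(c(3, 1, 1, 1, 1))
    draws <- replicate(4000, {
      sel <- rvburden:::sampleFixedSizeWeighted(logw, 2L)
      1L %in% sel
    })
    # P(heavy item selected): sets containing item 1: 4 of 10, each with
    # relative weight 3: p = 4*3 / (4*3 + 6)
    expect_equal(mean(draws), 12 / 18, tolerance = 0.025)
  })
})

test_that("planted quantitative effects shift carriers by beta per allele", {
  co <- simulateCohort(smallConfig(
    11, variantsPerGene = 30,
    plantedEffects = list(plantedEffect("SetA", "NS_broad", "rare",
                                        "beta", -5, "qt"))))
  vids <- qualifyingVariants(co, geneSets(co)$SetA, "NS_broad", "rare")
  br <- burdenRegression(co, "qt", vids)
  expect_lt(br$coef, -3)     # strong planted signal is visible
})
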