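test_that("resampled phenotypes are joint row permutations", {
  withr::with_seed(20, {
    n <- 60
    d <- dosageWithMac(c(5, 3), n)
    ph <- data.frame(cc = rbinom(n, 1, 0.4), qt = rnorm(n))
    ph$qt[1:10] <- NA
    co <- makeCohort(d, c("G1", "G1"), phenotypes = ph)
    r1 <- resampleNull(co, seed = 5, b = 3)
    # multisets preserved, missingness pattern travels with its sample
    expect_equal(sort(r1$cc), sort(ph$cc))
    expect_equal(sort(r1$qt, na.last = TRUE), sort(ph$qt, na.last = TRUE))
    expect_equal(sum(is.na(r1$qt)), 10)
    # same (seed, b) reproduces; different b differs
    expect_equal(as.data.frame(r1), as.data.frame(resampleNull(co, 5, 3)))
    expect_false(identical(as.data.frame(r1),
                           as.data.frame(resampleNull(co, 5, 4))))
  })
})

test_that("each sample lands uniformly across resampled positions", {
  n <- 25
  pos <- vapply(1:1000, function(b)
    which(permutationForResample(n, seed = 11, b = b) == 1L), integer(1))
  expect_gt(chisq.test(tabulate(pos, n))$p.value, 0.01)
})

test_that("a singleton family is adjusted to its own raw p", {
  withr::with_seed(22, {
    n <- 200
    s <- rbinom(n, 2, 0.15)
    y <- rnorm(n)
    X <- matrix(1, n, 1)
    p0 <- rvburden:::burdenPFast(s, y, "quantitative", X)
    pfun <- function(perm)
      rvburden:::burdenPFast(s, y[perm], "quantitative", X)
    B <- 2000
    res <- fwerAdjust(pfun, c(t1 = p0), groups = "tA", nSamples = n,
                      B = B, seed = 3)
    se <- sqrt(p0 * (1 - p0) / B)
    expect_lt(abs(res$table$fwer_within_p - p0), 3 * se + 1 / (B + 1))
  })
})

test_that("adjusted p-values are monotone and properly nested", {
  withr::with_seed(23, {
    n <- 150; K <- 6
    S <- matrix(rbinom(n * K, 2, 0.2), n, K)
    y <- rnorm(n); y2 <- rnorm(n)
    X <- matrix(1, n, 1)
    pvec <- function(yy) vapply(1:K, function(j)
      rvburden:::burdenPFast(S[, j], yy, "quantitative", X), numeric(1))
    obs <- c(pvec(y), pvec(y2))
    names(obs) <- paste0("t", 1:(2 * K))
    groups <- rep(c("A", "B"), each = K)
    pfun <- function(perm) c(pvec(y[perm]), pvec(y2[perm]))
    res <- fwerAdjust(pfun, obs, groups, nSamples = n, B = 500, seed = 9)
    tab <- res$table
    # across >= within >= raw for every member
    expect_true(all(tab$fwer_across_p >= tab$fwer_within_p - 1e-12))
    expect_true(all(tab$fwer_within_p >= tab$raw_p - 1e-12))
    # monotone in raw p within each family
    for (g in c("A", "B")) {
      sub <- tab[tab$group == g, ]
      ord <- order(sub$raw_p)
      expect_true(all(diff(sub$fwer_within_p[ord]) >= -1e-12))
    }
    # growing a family never helps any member
    resBig <- fwerAdjust(function(perm) c(pvec(y[perm]), pvec(y2[perm])),
                         obs, rep("A", 2 * K), nSamples = n, B = 500,
                         seed = 9)
    expect_true(all(resBig$table$fwer_within_p >=
                    tab$fwer_within_p[match(tab$id, resBig$table$id)] -
                    1e-12))
  })
})

test_that("small resample counts trigger a warning", {
  pfun <- function(perm) c(a = runif(1))
  expect_warning(fwerAdjust(pfun, c(a = 0.5), "g", nSamples = 10, B = 50,
                            seed = 1),
                 "coarse")
})

test_that("induced sub-permutations restrict the global permutation", {
  perm <- c(4L, 1L, 5L, 3L, 2L)
  A <- c(2L, 3L, 5L)
  sig <- rvburden:::induceSubPermutation(perm, A)
  expect_setequal(sig, 1:3)
  # order of A's members within the permutation: 5, 3, 2 -> indices 3, 2, 1
  expect_equal(sig, c(3L, 2L, 1L))
})

test_that("adjustResults annotates scan members with both FWER scopes", {
  withr::with_seed(25, {
    n <- 160
    mac <- rep(c(1, 2, 3), 4)
    d <- dosageWithMac(mac, n)
    genes <- rep(c("G1", "G2"), each = 6)
    ph <- data.frame(cc = rep(0:1, n / 2), qt = rnorm(n))
    co <- makeCohort(d, genes,
                     consequence = rep("nonsense", 12), phenotypes = ph,
                     geneSets = list(SetA = "G1", SetB = "G2"))
    burden <- runBurdenScan(co, classes = "Disruptive")
    rates <- runRateTests(co, classes = "Disruptive")
    adj <- adjustResults(co, burden, rates, B = 200, seed = 4)
    expect_true(all(c("kernel", "burden", "rate") %in% adj$stat))
    ok <- !is.na(adj$raw_p)
    expect_true(all(adj$fwer_across_p[ok] >= adj$fwer_within_p[ok] - 1e-12))
    expect_true(all(adj$fwer_within_p[ok] >= adj$raw_p[ok] - 1e-12))
    # deterministic under the same seed
    adj2 <- adjustResults(co, burden, rates, B = 200, seed = 4)
    expect_identical(adj, adj2)
  })
})
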