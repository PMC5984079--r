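test_that("a single-variant set reduces to the standard 1-df test", {
  withr::with_seed(4, {
    n <- 80
    g <- rbinom(n, 2, 0.2)
    qt <- rnorm(n) + 0.3 * g
    cc <- rbinom(n, 1, 0.5)
    d <- rbind(g, dosageWithMac(5, n))
    rownames(d) <- c("chr1:10_A/G", "chr1:20_A/G")
    co <- makeCohort(d, c("G1", "G1"),
                     phenotypes = data.frame(cc = cc, qt = qt))
    # quantitative: exact two-sided t-test of the variant (stats::lm oracle)
    nq <- fitNullModel(co, "qt")
    kq <- kernelSetTest(co, nq, "chr1:10_A/G", weights = "uniform")
    pLm <- summary(lm(qt ~ g))$coefficients[2, 4]
    expect_equal(kq$p, pLm, tolerance = 1e-9)
    # binary: 1-df chi-square score test (closed form oracle), evaluated
    # through the unadjusted mixture path
    nb <- fitNullModel(co, "cc")
    wg <- rvburden:::weightedGenotypes(co, "chr1:10_A/G", nb@sampleIds,
                                       "uniform")
    r <- nb@y - nb@mu
    Q <- sum(crossprod(wg$Gw, r)^2)
    lam <- rvburden:::projectedKernelEigen(wg$Gw, nb@varFun, nb@X)
    mu <- mean(cc)
    zsq <- sum(g * r)^2 / (mu * (1 - mu) * sum((g - mean(g))^2))
    expect_equal(pMixtureChisq(Q, lam)$p,
                 pchisq(zsq, 1, lower.tail = FALSE), tolerance = 1e-9)
  })
})

test_that("analytic kernel p matches residual permutation at small n", {
  withr::with_seed(21, {
    for (rep in 1:3) {
      n <- 50; m <- sample(2:5, 1)
      G <- namedDosage(matrix(rbinom(n * m, 2, runif(1, 0.1, 0.35)), m, n))
      y <- rnorm(n)
      co <- makeCohort(G, rep("G1", m),
                       phenotypes = data.frame(qt = y))
      nl <- fitNullModel(co, "qt")
      kt <- kernelSetTest(co, nl, rownames(G), weights = "uniform")
      r <- y - mean(y)
      B <- 20000
      Qs <- replicate(B, sum(crossprod(t(G), sample(r))^2))
      pp <- (1 + sum(Qs >= kt$Q)) / (B + 1)
      expect_lt(abs(kt$p - pp), 4 * sqrt(pp * (1 - pp) / B))
    }
  })
})

test_that("the kernel statistic is invariant to joint sample reordering", {
  withr::with_seed(6, {
    n <- 60; m <- 6
    d <- namedDosage(matrix(rbinom(n * m, 2, 0.2), m, n))
    ph <- data.frame(cc = rbinom(n, 1, 0.4), qt = rnorm(n))
    co <- makeCohort(d, rep("G1", m), phenotypes = ph)
    perm <- sample(n)
    co2 <- makeCohort(d[, perm], rep("G1", m),
                      phenotypes = ph[perm, , drop = FALSE])
    for (tr in c("cc", "qt")) {
      k1 <- kernelSetTest(co, fitNullModel(co, tr), rownames(d))
      k2 <- kernelSetTest(co2, fitNullModel(co2, tr), rownames(d))
      expect_equal(k1$Q, k2$Q, tolerance = 1e-9)
      expect_equal(k1$p, k2$p, tolerance = 1e-9)
    }
  })
})

test_that("degenerate genotype sets yield a no-test sentinel, not p = 1", {
  withr::with_seed(8, {
    n <- 30
    d <- namedDosage(matrix(0, 2, n))
    co <- makeCohort(d, c("G1", "G1"),
                     phenotypes = data.frame(qt = rnorm(n)))
    kt <- kernelSetTest(co, fitNullModel(co, "qt"), rownames(d))
    expect_true(is.na(kt$p))
    expect_equal(kt$backend, "no_test")
  })
})

test_that("permutation moments of the score quadratic form are exact", {
  withr::with_seed(9, {
    n <- 7; m <- 3
    Z <- matrix(rnorm(n * m), n, m)
    perms <- allPermutations(n)
    for (r in list(rbinom(n, 1, 0.5) - 0.4, rnorm(n))) {
      r <- r - mean(r)
      Qs <- vapply(perms, function(p) sum(crossprod(Z, r[p])^2),
                   numeric(1))
      pm <- rvburden:::permQuadformMoments(Z, r)
      expect_equal(pm$mean, mean(Qs), tolerance = 1e-10)
      expect_equal(pm$var, mean(Qs^2) - mean(Qs)^2, tolerance = 1e-10)
    }
  })
})

test_that("variant weights follow the Beta(1,25) default", {
  maf <- c(0.001, 0.01, 0.1)
  expect_equal(variantWeights(maf), dbeta(maf, 1, 25))
  expect_equal(variantWeights(maf, "uniform"), rep(1, 3))
  expect_equal(variantWeights(maf, c(1, 2, 3)), c(1, 2, 3))
  expect_error(variantWeights(maf, c(1, 2)), "one entry per variant")
})
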