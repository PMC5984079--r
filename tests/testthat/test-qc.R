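# independent enumeration oracle for the exact HWE test
hweOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  m <- min(nA, 2 * n - nA)
  het <- seq(m %% 2, m, by = 2)
  pr <- vapply(het, function(h) {
    homMin <- (m - h) / 2
    homMaj <- n - h - homMin
    exp(lfactorial(n) - lfactorial(homMaj) - lfactorial(h) -
          lfactorial(homMin) + h * log(2) +
          lfactorial(max(nA, 2 * n - nA)) + lfactorial(m) -
          lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[het == nAa] * (1 + 1e-12)])
}

test_that("exact HWE test matches the enumeration oracle", {
  cases <- list(c(20, 0, 5), c(5, 10, 5), c(50, 21, 2), c(0, 1, 0),
                c(3, 0, 3), c(88, 10, 2), c(10, 5, 0))
  for (g in cases)
    expect_equal(hweExactP(g[1], g[2], g[3]), hweOracle(g[1], g[2], g[3]),
                 tolerance = 1e-12)
  expect_equal(hweExactP(10, 0, 0), 1)   # monomorphic
})

test_that("a heterozygote deficit is rejected by the exact HWE filter", {
  # (20, 0, 5): exact p is ~5.2e-6, below 1e-4 but above the default 1e-6
  p <- hweExactP(20, 0, 5)
  expect_lt(p, 1e-4)
  expect_gt(p, 1e-6)
  d <- matrix(rep(c(0, 2), c(20, 5)), 1, 25)
  ph <- data.frame(cc = rep(0, 25))
  co <- makeCohort(d, "G1", phenotypes = ph)
  kept <- applyQC(co, hwePThreshold = 1e-4)
  expect_equal(nrow(kept$cohort), 0L)
  expect_equal(kept$report$reason, "hwe_controls")
  keptDefault <- applyQC(co)
  expect_equal(nrow(keptDefault$cohort), 1L)
})

test_that("clean cohorts pass QC untouched", {
  withr::with_seed(1, {
    d <- matrix(rbinom(200, 2, 0.3), 10, 20)
    co <- makeCohort(d, rep(c("G1", "G2"), each = 5),
                     phenotypes = data.frame(cc = rep(0:1, 10)))
    qc <- applyQC(co)
    expect_equal(dim(qc$cohort), dim(co))
    expect_equal(nrow(qc$report), 0L)
  })
})

test_that("samples failing the call-rate threshold are removed first", {
  withr::with_seed(2, {
    d <- matrix(rbinom(400, 2, 0.3), 20, 20)
    d[1:10, 1] <- NA          # sample 1: 50% missing
    co <- makeCohort(d, rep("G1", 20),
                     phenotypes = data.frame(cc = rep(0:1, 10)))
    qc <- applyQC(co, sampleCallRate = 0.9)
    expect_equal(ncol(qc$cohort), 19L)
    expect_true(any(qc$report$entity == "sample" &
                    qc$report$reason == "sample_call_rate"))
  })
})

test_that("QC is idempotent and errors when nothing survives", {
  withr::with_seed(5, {
    d <- matrix(rbinom(1500, 2, 0.2), 30, 50)
    d[runif(length(d)) < 0.05] <- NA
    d[3, 1:40] <- NA
    co <- makeCohort(d, rep(sprintf("G%d", 1:6), each = 5),
                     phenotypes = data.frame(cc = rep(0:1, 25)))
    q1 <- applyQC(co)
    q2 <- applyQC(q1$cohort)
    expect_equal(dim(q2$cohort), dim(q1$cohort))
    expect_equal(nrow(q2$report), 0L)
    dAllMiss <- matrix(NA_real_, 2, 10)
    co2 <- makeCohort(dAllMiss, c("G1", "G2"),
                      phenotypes = data.frame(cc = rep(0:1, 5)))
    expect_error(applyQC(co2), "all samples")
  })
})
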