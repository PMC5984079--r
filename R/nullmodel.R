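#' Fit a covariates-only null model for one trait
#'
#' Binary traits (coded 0/1) get a maximum-likelihood logistic fit of the
#' phenotype on covariates alone; quantitative traits an ordinary
#' least-squares fit. Samples with missing phenotype or covariates are
#' dropped and recorded. The fitted means, variance-function values and
#' design matrix feed the kernel score test and the resampling machinery.
#'
#' @param cohort a [BurdenCohort-class].
#' @param trait trait name (column of `phenotypes(cohort)`).
#' @param covariates character vector of phenotype-table columns to adjust
#'   for; the intercept is always included. Default: intercept only.
#' @return a [NullModel-class].
#' @export
fitNullModel <- function(cohort, trait, covariates = character()) {
  ph <- colData(cohort)
  if (!trait %in% colnames(ph)) stop(sprintf("unknown trait '%s'", trait))
  type <- traitTypes(cohort)[[trait]]
  y <- as.numeric(ph[[trait]])
  X <- cbind(`(Intercept)` = rep(1, length(y)))
  for (cv in covariates) {
    if (!cv %in% colnames(ph))
      stop(sprintf("unknown covariate '%s' for trait '%s'", cv, trait))
    X <- cbind(X, as.numeric(ph[[cv]]))
    colnames(X)[ncol(X)] <- cv
  }
  keep <- !is.na(y) & stats::complete.cases(X)
  if (sum(keep) < 10)
    stop(sprintf("trait '%s': fewer than 10 non-missing phenotype values",
                 trait))
  yk <- y[keep]; Xk <- X[keep, , drop = FALSE]
  if (qr(Xk)$rank < ncol(Xk))
    stop(sprintf("trait '%s': covariate matrix is rank deficient", trait))
  if (type == "binary") {
    if (!all(yk %in% c(0, 1)))
      stop(sprintf("binary trait '%s' must be coded 0/1", trait))
    fit <- stats::glm.fit(Xk, yk, family = stats::binomial())
    mu <- fit$fitted.values
    if (!fit$converged || any(mu < 1e-8) || any(mu > 1 - 1e-8))
      stop(sprintf("trait '%s': logistic null model did not converge (separation?)",
                   trait))
    varFun <- mu * (1 - mu)
    sigma2 <- NA_real_
  } else {
    fit <- stats::lm.fit(Xk, yk)
    mu <- fit$fitted.values
    sigma2 <- sum(fit$residuals^2) / (length(yk) - ncol(Xk))
    if (!is.finite(sigma2) || sigma2 <= 0)
      stop(sprintf("trait '%s': degenerate residual variance", trait))
    varFun <- rep(sigma2, length(yk))
  }
  new("NullModel", trait = trait, traitType = type,
      sampleIds = colnames(cohort)[keep], y = yk, mu = as.numeric(mu),
      varFun = as.numeric(varFun), X = Xk, sigma2 = sigma2,
      dropped = colnames(cohort)[!keep])
}

#' @describeIn fitNullModel display method.
#' @param object a `NullModel`.
#' @export
setMethod("show", "NullModel", function(object) {
  cat(sprintf("NullModel for '%s' (%s): %d samples, %d covariate column(s)%s\n",
              object@trait, object@traitType, length(object@y),
              ncol(object@X) - 1L,
              if (length(object@dropped))
                sprintf(", %d dropped", length(object@dropped)) else ""))
  invisible(NULL)
})

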