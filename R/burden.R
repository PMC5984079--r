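#' Collapsing burden regression of a variant set
#'
#' Collapses the qualifying variants into a per-sample burden score (count
#' of qualifying minor alleles; missing dosages count 0) and regresses the
#' phenotype on the score plus covariates: logistic regression for binary
#' traits, reporting the per-allele odds ratio with its standard error on
#' the log scale and a two-sided Wald p; ordinary least squares for
#' quantitative traits, reporting the per-allele effect `beta` with its
#' standard error and the two-sided t-referenced Wald p.
#'
#' @inheritParams kernelSetTest
#' @param trait trait name.
#' @param covariates phenotype-table columns to adjust for.
#' @return list with `effect` (OR or beta), `coef` (always on the linear
#'   scale: log-OR or beta), `se`, `p`, `df` (residual df, quantitative
#'   only), `n`, and `note` (`"ok"` or `"no_test"` when the burden score
#'   has zero variance).
#' @export
burdenRegression <- function(cohort, trait, variantIds,
                             covariates = character()) {
  null <- fitNullModel(cohort, trait, covariates)
  burdenRegressionCore(burdenScore(cohort, variantIds, null@sampleIds),
                       null@y, null@traitType, null@X)
}

#' Per-sample burden score
#'
#' Count of qualifying minor alleles carried by each sample; missing
#' genotypes contribute 0.
#' @inheritParams kernelSetTest
#' @param sampleIds samples to score (default all).
#' @return named numeric vector.
#' @export
burdenScore <- function(cohort, variantIds, sampleIds = colnames(cohort)) {
  if (!length(variantIds))
    return(stats::setNames(numeric(length(sampleIds)), sampleIds))
  d <- minorDosage(cohort)[variantIds, sampleIds, drop = FALSE]
  d[is.na(d)] <- 0
  colSums(d)
}

burdenRegressionCore <- function(s, y, traitType, X) {
  if (stats::var(s) == 0)
    return(list(effect = NA_real_, coef = NA_real_, se = NA_real_,
                p = NA_real_, df = NA_real_, n = length(y),
                note = "no_test"))
  D <- cbind(X, burden = s)
  if (traitType == "binary") {
    # separation in sparse resampled fits is expected and handled via the
    # convergence check; the fitter's warning would only add noise
    fit <- suppressWarnings(stats::glm.fit(D, y, family = stats::binomial()))
    if (!fit$converged)
      return(list(effect = NA_real_, coef = NA_real_, se = NA_real_,
                  p = NA_real_, df = NA_real_, n = length(y),
                  note = "no_test"))
    co <- fit$coefficients[["burden"]]
    vc <- solve(crossprod(D, D * fit$weights))
    se <- sqrt(vc["burden", "burden"])
    p <- 2 * stats::pnorm(-abs(co / se))
    list(effect = exp(co), coef = co, se = se, p = p, df = NA_real_,
         n = length(y), note = "ok")
  } else {
    fit <- stats::lm.fit(D, y)
    df <- length(y) - ncol(D)
    sigma2 <- sum(fit$residuals^2) / df
    co <- fit$coefficients[["burden"]]
    vc <- solve(crossprod(D)) * sigma2
    idx <- match("burden", colnames(D))
    se <- sqrt(vc[idx, idx])
    p <- 2 * stats::pt(-abs(co / se), df = df)
    list(effect = co, coef = co, se = se, p = p, df = df,
         n = length(y), note = "ok")
  }
}

# Fast burden p-value for resampling: identical statistic to
# burdenRegressionCore, specialised for an intercept-only design where the
# quantitative case has a correlation closed form. Returns NA for a
# zero-variance score.
burdenPFast <- function(s, y, traitType, X) {
  if (ncol(X) == 1L && traitType == "quantitative") {
    n <- length(y)
    sy <- s - mean(s); yy <- y - mean(y)
    den <- sqrt(sum(sy^2) * sum(yy^2))
    if (den == 0) return(NA_real_)
    r <- sum(sy * yy) / den
    r2 <- min(r^2, 1 - 1e-15)
    tt <- r * sqrt((n - 2) / (1 - r2))
    return(2 * stats::pt(-abs(tt), df = n - 2))
  }
  burdenRegressionCore(s, y, traitType, X)$p
}
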