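---
title: "Rare-variant burden analysis with rvburden: models, assumptions and design choices"
author: "rvburden authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant burden analysis with rvburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvburden)
```

# The scientific problem

Targeted-sequencing case-control studies of candidate gene panels ask
whether rare coding variants — individually too infrequent to test — are
collectively enriched in affected individuals, or associated with
quantitative traits such as cognitive test scores. `rvburden` implements
the complete analysis chain for this design: tiered functional
classification of coding variants, gene-set and gene-wide burden testing
with both a variance-component kernel score test and a collapsing
regression, exact Poisson comparison of allele accumulation rates, and
resampling-based family-wise error control within and across traits. A
synthetic-cohort generator with the same statistical structure makes every
stage testable end to end, which matters because real psychiatric
genotype data of this kind are typically not redistributable.

The default configuration emulates a study of three diagnostic groups
(211 schizophrenia, 195 bipolar disorder and 169 recurrent major
depression cases) sharing 871 controls, with 213 genes split into two
candidate gene sets of 59 and 154 genes.

# Functional classification

Coding variants are grouped into three nested analysis classes:

* **Disruptive** — nonsense and splice-site variants;
* **NS_strict** — disruptive variants plus missense variants called
  damaging by *all five* damage predictors (SIFT, PolyPhen2-HumDiv,
  PolyPhen2-HumVar, LRT, MutationTaster);
* **NS_broad** — disruptive variants plus missense variants called
  damaging by *at least one* predictor.

The sets are cumulative by construction, so Disruptive ⊆ NS_strict ⊆
NS_broad always holds; `qualifyingClass()` encodes the membership rule
and the test suite asserts the nesting on random annotations. Missing
predictor verdicts count as "not damaging", which makes the strict class
conservative in the presence of incomplete annotation. Unrecognised
consequence labels are never dropped silently: they map to an `OTHER`
class with a warning and take part in no analysis tier.

Frequency tiers are computed on the combined cohort (cases plus
controls): a **singleton** carries its minor allele exactly once, and a
**rare** variant has minor-allele frequency strictly below 1%, with
missing genotypes excluded from the denominator. The reference population
for these frequencies is a genuine modelling choice — the burden
literature this package follows computes them on the combined cohort, and
that convention is what `computeFrequencies()` implements. In cohorts
larger than 50 samples every singleton is automatically rare; in toy
examples smaller than that, a singleton can exceed the 1% bound, and the
strict rule wins.

# The burden tests

## Kernel (variance-component) score test

For a trait $y$ with covariates-only null fit $\hat\mu$ (logistic for
binary, least squares for quantitative), residuals $r = y - \hat\mu$, a
dosage matrix $G$ over the qualifying variants and weights
$W = \mathrm{diag}(w_j)$, the score statistic is

$$Q = r^\top G W^2 G^\top r .$$

Under the null, $Q$ is distributed as $\sum_k \lambda_k \chi^2_{1,k}$
where $\lambda_k$ are the eigenvalues of the covariate-projected weighted
kernel $W G^\top P_0 G W$, with
$P_0 = V - VX(X^\top V X)^{-1}X^\top V$ the variance of the score
residuals. Weights default to the Beta(1, 25) density at each variant's
MAF — the standard choice that up-weights the rarest variants — with a
uniform option (`weights = "uniform"`).

The mixture tail is evaluated by exact numerical inversion of its
characteristic function (the Davies/Imhof integral). Because the
integrand oscillates with slowly decaying amplitude when few eigenvalues
are present, `pMixtureChisq()` integrates half-period segments between
consecutive zeros of the oscillation and accelerates the alternating
series by repeated averaging; this reaches absolute accuracy near 1e-9
even for two eigenvalues, where naive quadrature stalls. On any numerical
fault the evaluation falls back to modified Liu moment matching, and the
backend actually used is recorded in every result row.

Two finite-sample refinements depart from the textbook plug-in recipe,
and both exist because the package checks itself against resampling
references:

* **Quantitative traits are studentized.** The plug-in approach treats
  the estimated residual variance as known; at a few dozen samples this
  visibly disagrees with the permutation distribution of $Q$. Under
  Gaussian errors the residual direction is uniform on the sphere of the
  covariate-orthogonal space, so the scale-free statistic
  $F = Q / (r^\top r)$ has an exactly computable tail:
  $P(F > f) = P\!\left(\sum_j (\lambda^*_j - f)\chi^2_1 -
  f\,\chi^2_{n-p-m} > 0\right)$, an indefinite quadratic form evaluated
  with the same inversion machinery. With a single variant this collapses
  to the exact two-sided t-test.
* **Binary traits get a small-sample moment adjustment.** With sparse
  rare variants the label-permutation law of $Q$ is much narrower and
  less skewed than the asymptotic mixture (a singleton's score
  contribution is nearly constant under permutation), making the plug-in
  p-value severely conservative. The package computes the *exact*
  permutation mean and variance of $Q$ in closed form from power sums of
  the residuals and contraction sums of the kernel (the formulas are
  validated against exhaustive permutation enumeration in the tests), and
  matches a chi-square's degrees of freedom to the permutation skewness
  estimated from a fixed-seed internal batch of 2,000 vectorised label
  permutations. The estimate depends on the residuals only through their
  power sums, so it is identical across resamples of the same phenotype
  and the resulting p-value is deterministic and invariant to sample
  reordering. Results using this path are flagged `perm_moment`.

On 2,000 null synthetic cohorts of 200 samples, both kernel paths, the
burden regression and the exact Poisson test hold their size at the 5%
and 1% levels (the acceptance suite recomputes this).

## Collapsing burden regression

The per-sample burden score is the count of qualifying minor alleles
(missing genotypes count zero). Binary traits are analysed by logistic
regression of case status on the score plus covariates, reported as an
odds ratio per allele with the standard error on the log scale;
quantitative traits by ordinary least squares, reported as β per allele.
P-values are two-sided Wald tests (t-referenced for least squares).
Effect sizes always come from this collapsing fit — the kernel test has
no natural signed effect — and both p-values are reported side by side,
since a set can be significant under one and not the other (the kernel
test is sensitive to mixed effect directions, the collapsing test to
consistent ones).

## Eligibility rules

Gene-set cells are tested whenever at least one qualifying variant is
polymorphic. Gene-wide cells require more than one qualifying rare
variant — single-variant genes carry no aggregation information and are
left to their set-level test. Monomorphic and all-missing variants never
qualify.

# Accumulation-rate tests

For each cell the total count of qualifying minor alleles in cases
($c_1$, $n_1$ samples) and controls ($c_2$, $n_2$) is compared by the
exact conditional construction: given $T = c_1 + c_2$, under equal
per-sample rates $c_1 \sim \mathrm{Binomial}(T,\, n_1/(n_1+n_2))$. The
two-sided p doubles the smaller exact tail, capped at 1 — the convention
of `poisson.test`-style exact comparisons — and the fold enrichment is
the ratio of per-sample rates $(c_1/n_1)/(c_2/n_2)$, reported as
infinite when controls carry nothing. Exposure is the post-QC sample
count per group; a per-chromosome exposure would simply halve both rates
and change nothing.

In recovery experiments across replicate cohorts the package aggregates
counts before forming the fold (the ratio of summed rates) rather than
averaging per-replicate ratios: with small control counts
$E[1/c_2] > 1/E[c_2]$ and the mean of ratios is biased upward.

# Family-wise error control

All tests for one trait form the `FWER_within` family; all tests across
all traits form the `FWER_across` family. Significance is adjusted by the
single-step min-p (Westfall–Young) procedure: for each resample $b$ every
member p-value is recomputed on resampled phenotypes, the family minimum
$m_b$ is recorded, and

$$p_{\mathrm{adj}}(p_0) = \frac{1 + \#\{b : m_b \le p_0\}}{B + 1},$$

floored at the member's raw p so Monte-Carlo noise can never make the
adjusted value undercut the unadjusted one. The default is $B =$ 10,000
resamples; adjusted p-values have granularity $1/(B+1)$, so small studies
can use fewer resamples at a corresponding loss of resolution (below 100
a warning is emitted). Nesting is automatic: the across-traits minimum is
never larger than a within-trait minimum, so
`fwer_across_p >= fwer_within_p >= raw_p` holds row by row.

The null is resampled by label permutation, not a with-replacement
bootstrap: permutation preserves the phenotype marginals exactly and is
the standard Westfall–Young construction (a bootstrap mode is available
behind `replace = TRUE` for comparison). Traits measured on disjoint
sample subsets — diagnoses versus control-only cognition — are handled by
permuting each family's (phenotype, covariate) rows jointly *within the
samples that family's tests use*, with the within-family permutation
induced from one shared global permutation per resample so that families
sharing samples remain correlated. This keeps each trait's case count
fixed, mirrors the fixed-n sampling design, and has a useful computational
consequence: the permuted null-model residuals are a permutation of the
observed ones, so eigen-spectra, exact permutation moments and skewness
preparations are computed once per cell and reused across all resamples.
A single master seed spawns one stream per resample index, so families
can be evaluated in any order — or restricted to subsets — with identical
results.

# The synthetic cohort generator

`simulateCohort()` produces cohorts with the statistical structure the
analysis assumes, not a population-genetics simulation:

* **Site frequency spectrum.** Minor-allele counts are drawn from
  $P(k) \propto 1/k$, the neutral-spectrum shape, truncated at a maximum
  $k_{\max}$. By default $k_{\max}$ is chosen by a deterministic
  closed-form search so that the expected fraction of variants with
  MAF < 1% is about 0.78, the rare-skew typical of deeply sequenced
  candidate-gene panels; alleles are then scattered uniformly over the
  $2N$ chromosomes.
* **Annotation.** Consequences are drawn from proportions matching a
  coding-variant panel (about 42% silent, 57% missense, 1.4% nonsense or
  splice, roughly 21 coding variants per gene over 213 genes); each of
  the five predictors independently calls a missense variant damaging
  with probability 0.4. Real predictors are strongly correlated, so real
  NS_strict sets are relatively larger than simulated ones — a known
  infidelity that affects class sizes, not test calibration.
* **Binary traits.** Under the null, case groups are uniform draws
  without replacement from the sample pool. A planted `odds_ratio` or
  `rate_fold` effect selects the fixed number of cases by *conditional
  Poisson sampling*: the probability of a case set is proportional to the
  product of per-sample weights $\mathrm{magnitude}^{s_i}$, where $s_i$
  is the sample's qualifying allele count. This is exactly the
  prospective logistic model conditioned on the attained case total, and
  it is sampled exactly via the multivariate Fisher noncentral
  hypergeometric distribution (log-space convolution over the handful of
  distinct weight classes). Naive sequential weighted sampling does *not*
  have odds-proportional inclusion probabilities and over-enriches
  carriers — a planted 3.5-fold came out 4.7-fold under it — which is why
  the exact sampler matters.
* **Quantitative traits.** Per-sample means are the planted β times the
  qualifying allele count, plus unit-variance Gaussian noise; by default
  they are measured in controls only, mirroring designs where cognitive
  phenotyping exists for the control cohort, and the restriction is
  configurable.
* A `combined` case group (all diagnoses versus controls) is added
  automatically, genotype missingness can be injected at a configurable
  rate, and every output is bit-reproducible given the seed.

What passing tests on these cohorts do **not** show: robustness to
linkage disequilibrium, population stratification, relatedness,
genotyping error, or correlated predictor panels — none of which the
generator models. Calibration statements transfer to real data only to
the extent that those features are absent or corrected upstream.

# Quality control

`applyQC()` removes samples below a 90% genotype call rate and variants
below a 90% call rate or failing the exact Hardy–Weinberg test in
controls at p < 1e-6, iterating the call-rate filters to a fixed point so
the operation is idempotent (removing a variant shifts sample call rates
and vice versa). The HWE test is the exact conditional test on the
heterozygote count. These thresholds are conventions of the QC
literature, not reproductions of any particular study's supplementary
pipeline, and are configurable and fully logged: every exclusion appears
in the report with its reason and offending value.

# Numerical choices and degenerate inputs

* Characteristic-function inversion: absolute tolerance 1e-9, fault →
  Liu moment matching, backend recorded. Eigenvalues and the evaluation
  point are rescaled by the spectral maximum first, since the infinite-
  interval quadrature otherwise misses features far from $u \approx 1$.
* Eigenvalues below $10^{-10}$ of the spectral maximum are treated as
  null directions.
* $Q \le 0$ (possible after moment rescaling) gives p = 1 exactly.
* Missing dosages are imputed to the variant mean for the kernel test
  and to zero for burden scores and allele counts, the two conventions
  documented separately because they answer different questions (expected
  genotype versus observed allele).
* All-zero genotype submatrices, zero-variance burden scores and empty
  count pairs give a no-test sentinel (`NA` with a reason), never p = 1.
* Leave-one-out contributions are the signed change in $-\log_{10} p$
  from removing each variant, ranked descending with lexicographic
  variant-id tie-breaking; removing a variant carried by no phenotyped
  sample changes nothing and scores exactly zero.

# Problem sizes used in validation

The shipped validation suite simulates at reduced-but-faithful scale
chosen to keep the full run in minutes: calibration uses 2,000 null
cohorts of 200 samples and 20 genes; fold recovery 200 replicates of a
200/800 cohort over 150 genes; β recovery 500 replicates of a 400-sample
cohort over 100 genes; FWER closed-form checks 10 independent tests at
B = 10,000 and FWER control 500 cohorts at B = 250; the end-to-end
pipeline checks run a 200-sample, 12-gene study twice and compare bytes.

# A minimal worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(
  nCasesByTrait = c(SCZ = 211L, BD = 195L, rMDD = 169L),
  nControls = 871L,
  plantedEffects = list(
    plantedEffect("Regulome", "Disruptive", "singleton",
                  "rate_fold", 4.13, "SCZ")),
  seed = 1L)
paths <- simulateFixture(cfg, "fixture")
res <- runPipeline(list(
  vcf = paths[["vcf"]], annotations = paths[["annotations"]],
  phenotypes = paths[["phenotypes"]],
  gene_sets = paths[c("geneset_Interactome", "geneset_Regulome")],
  out_dir = "results", resamples = 10000L, seed = 2L))
subset(res$adjusted, fwer_across_p < 0.05)
```

# Known limitations

* No SKAT-O style combination of the kernel and collapsing statistics;
  both p-values are reported, not combined.
* No mixed-model or relatedness correction; covariates enter as fixed
  effects only.
* The binary kernel p relies on a skewness-matched chi-square rather
  than the full permutation distribution; extreme tails (p well below
  1e-4) are approximations, while the FWER layer — which is what
  significance statements rest on — is fully resampling-based.
* Indels, multiallelic sites and CNVs are out of scope; inputs are
  biallelic SNVs with diploid genotypes.
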