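---
title: "Genomic selection with regularized-regression feature selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection with regularized-regression feature selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsfs)
```

## The problem

Genomic selection predicts the breeding value of a candidate animal from
genome-wide markers, using a reference population with both genotypes and
phenotypic information. When the markers come from whole-genome sequence
rather than a SNP chip, millions of variants are available but most are
irrelevant or redundant, and mixed-model solvers cannot fit them all at
once. The strategy implemented here reduces the sequence data in two
stages — a single-marker mixed-model association scan pre-selects nominally
associated SNPs, then a cross-validated LASSO or elastic net keeps the
jointly informative subset — and feeds the selected markers, alone or
combined with a chip panel, into GBLUP with reliability-weighted residuals.
Accuracy and dispersion bias on a year-of-birth validation split evaluate
each marker-panel scenario.

The response throughout is a de-regressed proof (DRP): a progeny-test
breeding value transformed so records are approximately independent, with a
per-individual reliability $r^2 \in (0,1]$ quantifying how much information
it carries.

## Models

### Single-marker mixed-model scan

For each SNP the model is
$$\mathbf{y} = \mathbf{1}\mu + \mathbf{x}b + \mathbf{g} + \mathbf{e},
\qquad \mathbf{g}\sim N(0, \mathbf{G}\sigma_g^2),\quad
\mathbf{e}\sim N(0, \mathbf{I}\sigma_e^2),$$
where $\mathbf{x}$ holds additive codes 0/1/2 and $\mathbf{G}$ is a
per-marker standardized genomic relationship matrix built from all
chromosomes *except* the one carrying the tested SNP (leave one chromosome
out, LOCO), so the polygenic term cannot absorb the tested signal. The Wald
statistic $(\hat b/\mathrm{se})^2$ is referred to $\chi^2_1$.

Two numerical choices matter. First, variance components are estimated once
per LOCO null model (by REML profiled on the GRM eigenbasis, a 1-D Brent
search over $h = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$) and then held fixed
for every SNP on that chromosome. Re-estimating per SNP would change
p-values only marginally at these sample sizes while multiplying cost by
the marker count; the package therefore ships only the fixed-components
scan, and its calibration is verified directly (null simulations give a
4–6% rejection rate at the nominal 5% threshold, and forcing
$\sigma_g^2 = 0$ reproduces fixed-variance OLS Wald tests exactly). Second,
the standardized GRM with its distinct unbiased diagonal is very slightly
indefinite by construction (see *Numerical behavior of the relationship
matrices* below), so eigenvalues marginally below zero are clipped before
the REML profile is formed; a matrix whose negative part exceeds 5% of the
largest eigenvalue is rejected as genuinely non-PSD.

SNPs with $p < 0.05$ (strict) are retained for the regression stage — a
deliberately permissive gate whose purpose is dimension reduction, not
discovery.

### Feature selection

On the pre-selected design $\mathbf{X}$ the package minimizes
$$\frac{1}{2n}\lVert \mathbf{y}-\mu\mathbf{1}-\mathbf{X}\mathbf{b}\rVert^2
+ \lambda\Big[\tfrac{1-\alpha}{2}\lVert\mathbf{b}\rVert_2^2
+ \alpha\lVert\mathbf{b}\rVert_1\Big],$$
by cyclic coordinate descent with soft-thresholding; $\alpha = 1$ is the
LASSO. The conventional $1/(2n)$ scaling and $(1-\alpha)/2$ ridge factor
keep the penalty path stable across sample sizes; an unnormalized
residual-sum-of-squares objective selects the same models under a
reparameterization of $\lambda$, so printed penalty values are comparable
only within one parameterization. Columns are standardized to unit variance
before fitting (penalty fairness across allele frequencies) and
coefficients are reported back on the genotype scale.

Tuning uses ten-fold cross-validation with the one-standard-error rule:
within each $\alpha$, take the largest $\lambda$ whose mean validation MSE
is within one standard error of the minimum; across the $\alpha$ grid
(0.05 to 0.95 in steps of 0.1 for the elastic net) keep the pair with the
smallest 1SE-rule error; refit on all data and keep the nonzero
coefficients. Fold assignment is a seeded permutation into equal folds, so
a fixed fold seed makes the entire selection deterministic.

Numerical controls: the $\lambda$ path has 100 log-spaced values from
$\lambda_{\max}$ (the smallest all-zero penalty, given $10^{-9}$ relative
headroom so the top of the path is exactly the empty model in floating
point) down to $10^{-3}\lambda_{\max}$; coordinate descent converges when
the largest coefficient change in a sweep falls below $10^{-7}$, with
active-set cycling between full sweeps. Cross-validation fold fits use a
relaxed $10^{-5}$ tolerance — validation errors are insensitive to the last
decimals of the coefficients — while the final refit always uses
$10^{-7}$. Zero-variance columns keep coefficient zero by construction.

The comparator strategies select the $N$ SNPs with the smallest scan
p-values, with $N$ matched to the LASSO or elastic-net selection size; ties
are broken by larger absolute effect and then map order so results are
reproducible.

### GBLUP with one or two relationship matrices

Prediction uses
$$\mathbf{y} = \mathbf{1}\mu + \sum_k \mathbf{a}_k + \mathbf{e},\qquad
\mathbf{a}_k \sim N(0, \mathbf{G}_k\sigma_k^2),\quad
\mathbf{e} \sim N(0, \mathbf{D}\sigma_e^2),$$
with one additive term (a single SNP panel) or two (selected SNPs and chip
SNPs, overlap removed from the chip side so no marker is counted twice).
$\mathbf{G}_k$ is VanRaden's first matrix,
$\mathbf{Z}\mathbf{Z}^\top / 2\sum_i p_i(1-p_i)$ on centered codes. The
residual weight $d_{jj} = (1-r^2_j)/r^2_j$ encodes the DRP reliability;
a single $\sigma_e^2$ scales the fixed weight matrix $\mathbf{D}$. Weights
are floored at $10^{-6}$ so a perfectly reliable proof does not degenerate
the system, and floored individuals are flagged.

Variance components are estimated by average-information REML. When an AI
step would leave the parameter space the step is halved until feasible
(damped AI); if even a tiny step is infeasible the iteration falls back to
an expectation-maximization update, which cannot decrease the restricted
likelihood. Convergence requires a relative parameter-change norm below
$10^{-8}$; the iteration cap defaults to 1000, and hitting it reports
`converged = FALSE` rather than raising — two-matrix models on strongly
overlapping panels can be genuinely confounded, and an unconverged fit is a
result, not an error. Scenario reports carry the convergence flag and
refuse accuracy metrics for unconverged fits unless forced.

GEBVs come from the conditional mean
$\hat{\mathbf{a}}_k = \sigma_k^2\mathbf{G}_k\mathbf{V}^{-1}(\mathbf{y}-\mathbf{1}\hat\mu)$,
and validation animals are predicted by the cross-covariance projection
$\sigma_k^2\mathbf{G}_k[\text{val},\text{ref}]\,\mathbf{V}_{\text{ref}}^{-1}(\mathbf{y}_{\text{ref}}-\mathbf{1}\hat\mu)$;
with a single matrix and matched penalty
$\lambda = c\,\sigma_e^2/\sigma_a^2$ (where $c$ is the GRM scale constant)
this is identical to ridge SNP-BLUP, an identity the tests verify to
$10^{-6}$.

### Evaluation

Reference animals are those born strictly before the cutoff year (default
2013); validation animals are born in or after it, after removing
candidates with DRP reliability below 0.40 — the filter applies to
validation only, because an unreliable proof is still information on the
training side but a poor benchmark. Accuracy is
$\mathrm{cor}(\text{DRP}, \text{GEBV}) / \sqrt{\bar r^2}$, the Pearson
correlation corrected by the root mean reliability *of the validation set*
(the averaging population is ambiguous in common usage; this choice is
fixed here and configurable). Bias is the OLS slope of DRP on GEBV: 1 is
ideal, below 1 over-dispersed predictions.

## The synthetic population

Real dairy-cattle proofs and sequence genotypes are proprietary, so the
package carries a generator that emulates the statistical structure the
analysis relies on, making every stage testable:

* **Genotypes.** Per chromosome, each gamete is a latent first-order
  autoregressive Gaussian chain thresholded at the allele frequency, and
  two independent gametes sum to codes 0/1/2. Marginal frequencies are
  exact; adjacent-marker LD is governed by one parameter (`ld_rho`,
  default 0.6) and decays geometrically with distance. Chromosomes are
  independent.
* **Trait.** `n_qtl` markers drawn without replacement get iid normal
  effects, rescaled so the realized variance of true breeding values is
  exactly `h2`; total phenotypic variance is normalized to 1, so
  `sigma2_a = h2` and one free scale disappears.
* **Proofs.** DRP = true breeding value + noise with variance
  $\sigma_a^2(1-r^2)/r^2$, the de-regression noise model, so
  $\mathrm{cor}(\text{DRP}, \text{TBV}) \approx r$ by construction.
  Reliabilities are uniform on (0.5, 0.95) by default — a plausible range
  for progeny-tested and genotyped-cow proofs — and birth years uniform on
  2008–2015 so the default 2013 cutoff yields roughly a 5:3
  reference:validation split.
* **Chip nesting.** The "50K chip" of a synthetic run is a fixed seeded
  subsample of the simulated markers (a fifth of them by default), which
  reproduces the chip-within-sequence nesting without an array manifest.
* **Missingness** is off by default (sequence data are analyzed
  post-imputation) but can be injected to exercise quality control.

What the generator does *not* emulate: pedigree and family structure,
selection over generations, a realistic cattle LD spectrum or
minor-allele-frequency distribution, dominance and epistasis, and the
internal de-regression computation (DRPs are generated directly from their
noise model). Passing tests therefore demonstrate that the machinery is
correct under its stated assumptions — unbiased component recovery,
calibrated scans, exact model identities — not that any particular accuracy
level will be attained on real Holstein data, where LD between panels and
QTL, population structure and reliability heterogeneity differ.

## Quality control

Filters run in a fixed order: non-autosomal markers are dropped
unconditionally; individuals with call rate $\le 0.95$ are removed; then
markers failing call rate ($\le 0.95$), minor allele frequency
($\le 0.01$) or the Hardy–Weinberg exact test ($p \le 10^{-6}$) are
removed, each computed after individual removal. Retention is strictly
greater-than throughout. The HWE test is the conditional exact test
(two-sided, summing configurations no more likely than the observed one),
computed by the stable mid-to-tails recurrence — the chi-square
approximation misbehaves exactly where the filter matters, at low minor
allele frequency. Filtering is idempotent and the removal report partitions
the removed items by reason.

## Numerical behavior of the relationship matrices

VanRaden's first matrix is a scaled Gram matrix: symmetric and positive
semi-definite to machine precision, with one exactly-zero eigenvalue along
the ones vector because the codes are centered at realized frequencies.
The per-marker standardized matrix used for the scan replaces the Gram
diagonal with the unbiased estimator
$1 + \tfrac{1}{N}\sum_i (x_i^2 - (1+2p_i)x_i + 2p_i^2)/(2p_i(1-p_i))$.
That replacement perturbs the diagonal by zero-mean sampling noise of
order $1/\sqrt{N}$ per individual, so the matrix is generically *slightly
indefinite* — its smallest eigenvalue sits near
$-\mathcal{O}(1/\sqrt{Nn})$, not at zero, shrinking as markers accumulate.
This is a property of the estimator (widely observed for this GRM flavor in
the wild), not an implementation artifact; the package implements the
formula exactly, documents the indefiniteness scale in its tests, and
handles it where it matters (eigenvalue clipping in the null-model REML).
Both constructions are invariant to recoding any marker by the opposite
allele, which also resolves the ambiguity of which allele the 0/1/2 codes
count: the matrices — and everything downstream — do not depend on it.
Monomorphic markers are excluded from numerator and scale (they carry no
information and break the per-marker standardization), and missing codes
are mean-imputed at $2p_i$ before centering.

## Scenario grid

`run_scenario_grid()` executes the five marker-panel scenarios — selected
SNPs only, chip only, all sequence SNPs, chip plus selected with one
relationship matrix, and chip plus selected with two matrices — sharing the
expensive stages (QC, the LOCO scan, each feature selection) across
scenarios through a cache. Problem sizes used by the package's own
validation runs: the end-to-end test simulates 1,500 individuals with 5,000
markers on 5 chromosomes and 100 QTL at $h^2 = 0.3$ and completes the grid
in well under a minute per population; the acceptance script uses 1,200
individuals with 4,000 markers. These sizes were chosen so that the
reference population, marker density and signal sparsity are in realistic
proportion while a full grid remains a desk-scale computation.

```{r example, eval = FALSE}
cfg <- sim_config(n_individuals = 1200, n_chromosomes = 4,
                  snps_per_chromosome = 1000, n_qtl = 100, h2 = 0.3, seed = 1)
pop <- simulate_population(cfg)
grid <- run_scenario_grid(pop, strategy = "EN", chip_size = 800)
grid$report
```

## Design choices and limitations

* **Interface.** The package is function-first: tabular results (scan
  results, feature sets, evaluation reports) are tibbles, fitted objects
  have `tidy()`/`glance()`/`autoplot()` methods, and matrix-native objects
  (genotypes, relationship matrices) stay matrix-backed. Orchestration is
  exposed as `run_scenario()`/`run_scenario_grid()` rather than a shell
  tool; writing a wrapper script around these is trivial where a
  command-line entry point is wanted.
* **Solver authorship.** The elastic-net coordinate descent, the exact HWE
  test, the eigenbasis REML and the AI-REML are implemented in the package;
  established implementations (glmnet, dense linear algebra oracles,
  closed forms) serve as independent cross-checks in the test suite, which
  keeps every dual-route comparison genuinely two-route.
* **The GWAS residual is homoscedastic** ($\mathbf{I}\sigma_e^2$) even
  though GBLUP weights residuals by reliability — the scan model is
  implemented as specified, and the pre-selection gate at $p<0.05$ is
  robust to this approximation.
* **Boundary components.** A variance component whose truth is zero
  converges to the floor ($10^{-10}$) rather than exactly zero; reported
  near-zero components should be read as boundary estimates.
* **Known limitations.** No pedigree relationships, single-step methods,
  Bayesian mixture priors, multi-trait models or genomic-control
  correction; the scan offers no per-SNP variance re-estimation; the
  generator's LD and QTL architecture are stylized. These are scope
  boundaries, not roadmap items.
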