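---
title: "Adaptive gene-based methylation association tests for related samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive gene-based methylation association tests for related samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aspuwscan)
```

## The problem

Epigenome-wide association studies usually test each CpG site separately
against the phenotype. That strategy pays a heavy multiple-testing price and
ignores that several nearby CpGs in a gene may be associated — possibly in
different directions and with very different magnitudes. aspuwscan instead
tests all CpGs in a gene *jointly*, with a family of statistics whose
behavior ranges continuously from "sum everything" (powerful for dense,
same-direction signals) to "take the strongest site" (powerful for sparse
signals), and an adaptive combination that does not require knowing the
signal architecture in advance. Because cohorts with methylation data are
often family studies, the test is built on a linear mixed model that absorbs
both genetic relatedness and shared-household effects.

## Model

For $n$ individuals in $F$ families, with phenotype $y$, fixed covariates
$X$ ($n \times q$, intercept included) and a gene's beta-values $G$
($n \times p$), the generating model is

$$ y = X\alpha + G\beta + b + \varepsilon, \qquad
   b \sim N\!\Big(0,\ \sum_{k=1}^{K} T_k \Psi_k\Big), \qquad
   \varepsilon \sim N(0, \sigma^2 I), $$

where each $\Psi_k$ is a prespecified $n \times n$ PSD structure and $T_k
\ge 0$ its variance component. The default structures are $\Psi_1$, an
empirical genetic relationship matrix (GRM) estimated from genome-wide SNPs
by the standardized cross-product
$\Psi_1[i,i'] = \tfrac1{m'}\sum_s z_{is} z_{i's}$ with
$z_{is} = (g_{is} - 2\hat p_s)/\sqrt{2\hat p_s(1-\hat p_s)}$, and $\Psi_2$,
a within-family block matrix of ones capturing shared environment. A
residual term $\sigma^2 I$ is always present in addition to the listed
structures; without it the model would be degenerate whenever no $\Psi_k$
has full rank.

The null hypothesis is $\beta = 0$. The null model (no CpG terms) is fitted
by REML, and the gene is summarized by the score vector and its covariance
with fixed effects profiled out:

$$ U = G'\hat\Sigma^{-1}(y - X\hat\alpha), \qquad
   V = G'\hat P G, \qquad
   \hat P = \hat\Sigma^{-1} - \hat\Sigma^{-1}X(X'\hat\Sigma^{-1}X)^{-1}
            X'\hat\Sigma^{-1}, $$

with $\hat\Sigma = \hat\sigma^2 I + \sum_k \hat T_k \Psi_k$. $V$ uses the
plugged-in REML estimates with no correction for their estimation error, the
standard practice for variance-component score tests. Only the Gaussian
(identity-link) case is implemented; binary traits are out of scope.

## The SPUw family and the adaptive combination

With weights $\omega_j$ the sum-of-powered-score statistics are

$$ T_{SPUw(\gamma)} = \sum_{j=1}^p (\omega_j U_j)^\gamma,
   \qquad \gamma = 1, 2, 3, \ldots $$

Small $\gamma$ aggregates many moderate signals; large $\gamma$ concentrates
on the strongest ones; in the limit we define
$T_{SPUw(\infty)} = \max_j |\omega_j U_j|$, the standard limiting form (the
$\gamma$-th root of the finite-$\gamma$ statistic converges to it, and for
even $\gamma$ the induced test is identical). The default weights are
$\omega_j = 1/\widehat{\mathrm{sd}}(G_{\cdot j})$ (denominator $n-1$), which
stop high-variance CpGs from drowning out associations at stable sites;
$\omega_j = 1$ recovers the unweighted SPU family, and $\gamma = 2$ with
unit weights is exactly the linear-kernel SKAT quadratic form $U'U$.

p-values come from a single layer of Monte Carlo simulation. Null scores
$U^{(b)} \sim N(0, V)$, $b = 1,\dots,B$, are drawn once through a symmetric
eigenfactorization of $V$ (negative eigenvalues clipped at zero — $V$ is
rank-deficient whenever CpGs are collinear) and shared by all powers:

$$ P_{SPUw(\gamma)} = \frac{1 + \sum_b I\big(|T^{(b)}_{SPUw(\gamma)}| \ge
   |T_{SPUw(\gamma)}|\big)}{B + 1}. $$

The adaptive statistic is $T_{aSPUw} = \min_{\gamma \in \Gamma}
P_{SPUw(\gamma)}$. Because a minimum of p-values is not a p-value, each null
replicate $b_1$ receives leave-one-out p-values
$p^{(b_1)}_\gamma = \sum_{b \ne b_1} I(|T^{(b)}| \ge |T^{(b_1)}|)/B$,
minimized over $\Gamma$, and

$$ P_{aSPUw} = \frac{1 + \sum_b I\big(T^{(b)}_{aSPUw} \le T_{aSPUw}\big)}
   {B + 1}. $$

All indicators use non-strict comparisons, so ties count toward the null and
the test errs conservative; every reported p-value lies in
$[1/(B+1),\, 1]$ and a Monte Carlo p-value of exactly zero is impossible by
construction. Two exactness properties are worth noting because the test
suite leans on them: for a single CpG all powers give the *same* p-value on
shared draws (the indicator events coincide), and rescaling all weights by a
positive constant leaves every p-value bit-identical.

### Defaults

- $\Gamma = \{1, \dots, 6, \infty\}$: small powers for dense signals,
  medium powers for intermediate sparsity, $\infty$ for highly sparse ones.
- $B = 1000$ by default. A staged scheme (`B_max`) re-runs a gene with
  $10\times$ the replicates whenever its smallest p-value falls below
  $5/B$, so genome-wide scans resolve small p-values without paying the
  maximal $B$ for every gene. Genome-wide significance near $10^{-6}$
  requires $B \ge 10^6$ for the top genes.
- Per-gene seeds are derived by hashing (master seed, gene ID), making scan
  results invariant to gene order and reproducible gene by gene.

## REML fitting

The restricted likelihood is profiled over $\alpha$ and $\sigma^2$, leaving
only the variance ratios $\delta_k = T_k/\sigma^2$; these are optimized on
the log scale, each evaluation costing one Cholesky factorization of
$H(\delta) = I + \sum_k \delta_k \Psi_k$. The optimizer is BOBYQA (bounded
derivative-free quadratic modeling, the same choice lme4 makes for linear
mixed models) with bounds $\log\delta \in [-18, 8]$; the lower bound is
treated as $T_k = 0$. A bounded quasi-Newton (L-BFGS-B with central-diff
gradients) and Nelder-Mead are available through `control$method`; BOBYQA
reaches the same optimum in roughly half the objective evaluations, which
matters when simulation studies refit thousands of phenotypes. By default
three dispersed starts guard against plateaus (an identity-like $\Psi_k$
makes the profile flat along an aliased direction — the fit is still valid,
only the split between $T_k$ and $\sigma^2$ is arbitrary); repeated
simulation fits use one warm start instead. Convergence is assessed by the
optimizer's trust-region/objective criterion plus a post-hoc
central-difference gradient norm on interior coordinates, reported in the
fit. The null model is fitted once per phenotype: variance components do not
depend on the gene, so per-gene work is only score extraction against
cached factors.

## What the synthetic generator emulates

`simulate_dataset()` and its components generate:

- **Pedigrees** — nuclear families (two unrelated founders plus children),
  the simplest structure with a nontrivial kinship and family blocks.
  Kinship is the additive relationship matrix (parent-offspring and full
  sibs 0.5).
- **Genotypes** — founder alleles at MAFs uniform on an interval, offspring
  by gene dropping, so the realized GRM matches the pedigree in expectation.
- **Methylation** — latent exchangeable-correlation Gaussians pushed
  through the inverse logit. The latent scale for CpG $j$ is
  $s_j = v_j / (\bar p_j(1-\bar p_j))$ (delta method), so empirical
  beta-value SDs track the requested profile $v_j$; heterogeneous $v_j$ is
  deliberate, since it is what separates inverse-SD from constant weights.
  The construction is exactly invertible through `qlogis`, which the tests
  use to verify the correlation. It does *not* emulate array probe biology,
  bimodal methylation, batch effects, or cell-type composition — passing
  tests validate the statistical machinery, not robustness to those
  artifacts.
- **Phenotypes** — drawn exactly from the mixed model above; $\beta = 0$
  gives an exact null generator. The covariance factorization is computed
  once, so thousands of replicates are cheap.
- **Covariates** — one standardized continuous (age-like) and one binary
  (sex-like) variable, mirroring a typical adjustment set.

Simulated studies generate the random intercept on the *empirical* GRM
(plus family blocks), i.e. the same matrices the analyst fits, which
isolates test calibration from GRM estimation error; GRM estimation quality
is validated separately against pedigree expectations.

## Validation study design

The test suite fixes these design choices (chosen for statistical
resolution within a practical runtime, and fixed before the studies were
run):

- *Size*: 200 families of 4 ($n = 800$), one 10-CpG gene with latent
  correlation 0.5 and SD profile 0.02-0.12, $T = (0.3, 0.2)$,
  $\sigma^2 = 1$, 1000 phenotype replicates, $B = 500$. Every power and the
  adaptive test must reject at a rate inside the 99% binomial band
  [0.032, 0.068] at $\alpha = 0.05$, and the null aSPUw p-values must pass
  a Kolmogorov-Smirnov uniformity check.
- *Adaptivity*: $n = 600$, 20 CpGs. Sparse: one mid-variance CpG with
  $\beta = 2.5$; dense: all CpGs with $\beta = 0.15$. Effect sizes were
  chosen once, from a small pilot, to put power in an intermediate range
  where orderings are informative. Expected orderings:
  $SPUw(\infty) \ge SPUw(1)$ under sparsity, the reverse under density,
  with aSPUw within 10 points of the best single power. A third scenario
  plants the signal on the lowest-variance CpG ($\beta = 7$), where
  inverse-SD weighting must beat constant weighting (paired comparison on
  shared scores and draws).
- *Mixed-model correctness*: REML recovery of $(0.5, 0.3, 1.0)$ within
  $\pm 0.15$ averaged over 50 replicates at $n = 1000$; the empirical
  covariance of 8000 simulated null scores against the analytic $V$ within
  10% entrywise (5 CpGs of one gene, so no near-zero entries enter the
  relative comparison).
- *Scan*: ten replicate 200-gene scans with one strongly associated gene
  ($\beta = 2$ on its 5 CpGs). The planted gene must attain the minimum
  aSPUw p-value in each scan (ties at the $1/(B+1)$ floor count as
  attained). Genomic-control lambda is computed on the null genes pooled
  across scans: the median of 199 p-values is far too noisy to certify a
  [0.9, 1.1] band, so the band is asserted on the pooled 1990.

## Numerical choices

- PSD repairs (GRM, $V$, phenotype covariance) clip negative eigenvalues at
  zero after symmetrization; eigenvalues below $10^{-12}$ of the largest are
  treated as zero when factorizing $V$ so that rank-deficient draws are
  exactly degenerate.
- Zero-variance CpGs are dropped (with a warning) before weighting; a gene
  whose CpGs are all constant is reported untestable rather than $p = 1$.
- Monomorphic SNPs are dropped and missing genotypes mean-imputed per SNP
  before GRM standardization; missing methylation is rejected outright
  (no imputation rule is defensible without a data model).
- `B < |\Gamma|` triggers a resolution warning; scans record per-gene
  failures in their result row rather than aborting.

## Known limitations

- Gaussian traits only; no logit link, no penalized quasi-likelihood.
- The weights as defined ($1/\mathrm{sd}(G_j)$) make $SPUw(\infty)$ the
  maximum of *variance-weighted* scores; this coincides with the classical
  minimum-p (UminP) test only when $\omega_j$ is the reciprocal of the
  score's standard deviation, not the CpG's. The weights are implemented as
  defined, and the discrepancy is intentional.
- Asymptotic (simulation-free) p-values are not provided; the Monte Carlo
  floor $1/(B+1)$ bounds the smallest reportable p-value.
- "Gene region" means whatever interval the supplied BED file declares —
  gene-model semantics are the annotation's responsibility.
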