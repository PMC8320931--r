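---
title: "Spectral estimation of F_ST: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral estimation of F_ST: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popspectral)
```

## The model and the central identity

`popspectral` works with a haploid genotype matrix $X = (x_{i\ell})$ of $n$
samples by $L$ biallelic loci, entries counting copies of the alternate
allele, and an assignment of each sample to one of $K$ discrete populations
with haploid counts $n_k$ and weights $c_k = n_k/n$. Diploid data are
represented as $2n$ haploid rows with a random phase for heterozygotes
(`haploidize()`); this loses no information for any statistic computed
here, all of which depend on the data only through allele counts.

Per locus, with within-population frequencies $p_{k\ell}$ and total
frequency $P_\ell = \sum_k c_k p_{k\ell}$, the Nei diversities are

$$H_S = 2\sum_k c_k p_k(1-p_k),\qquad H_T = 2P(1-P),\qquad
  D_{ST} = H_T - H_S,\qquad F_{ST} = D_{ST}/H_T,$$

and the package's headline quantity is the **mean of the per-locus ratios**
$F_{ST,\ell}$ over loci polymorphic in the total sample — an average of
ratios, not a ratio of averages.

The centered matrix decomposes as $Z = Z_{ST} + Z_S$, where the
between-population matrix $Z_{ST}$ repeats $p_{k\ell} - P_\ell$ across each
population's rows (rank $\le K-1$) and the residual matrix $Z_S$ holds
$x_{i\ell} - p_{k\ell}$. Dividing columns by $\sqrt{P_\ell(1-P_\ell)}$ gives
the scaled variants. These satisfy $\|Z\|^2 = \|Z_{ST}\|^2 + \|Z_S\|^2$
exactly, and the identities on which everything rests:

$$\overline{F_{ST}} = \sum_{k=1}^{K-1}\rho_k^2(Z^{sc}_{ST})/L, \qquad
  \overline{D_{ST}}/2 = \sum_{k=1}^{K-1}\sigma_k^2(Z_{ST})/L,$$

with eigenvalues defined as squared singular values divided by $n$. By the
Pythagorean identity the same quantities can be computed from the residual
spectrum (`complement_fst()`, `complement_dst()`). These are algebraic
identities for 0/1 data, not approximations: the test suite asserts them to
$10^{-10}$ on hundreds of random matrices with random unequal partitions.

The label-free approximation replaces the between-matrix spectrum by the
leading eigenvalues of the scaled PCA of $Z^{sc}$ itself
(`pca_fst_approx()`). It is accurate to $O(K/L)$ **only under the
separation condition** $\sigma^2_{K-1}(Z_{ST}) > \sigma^2_1(Z_S)$
(`separation_condition()`); the packaged simulations show the error
halving as $L$ doubles (log-log slope $\approx -1$) when it holds, and the
approximation failing (gap of several percentage points) under a merged,
misspecified grouping.

## Divisor conventions

All identities are exact with eigenvalues divided by $n$; the unbiased
convention divides by $n-1$ and perturbs every quantity by a factor
$n/(n-1)$, i.e. $O(1/n)$. `fst_fit(..., divisor = "n-1")` reports the
unbiased ladders, but the spectral estimators themselves always use $n$ so
that they equal the per-locus means exactly. The separation verdict is
divisor-free (both sides share the divisor). The residual-bulk dimension is
$n-1$ for a single population (column centering removes one dimension) and
$n-K$ for a $K$-population decomposition (within-population centering
removes $K$).

## Random-matrix diagnostics

For a structureless scaled matrix the bulk of the spectrum follows the
Marchenko–Pastur law; on the proportion-of-variance scale used in scree
plots its support is $[(1 \mp \sqrt{\gamma})^2/L]$ with
$\gamma = L/n_{\mathrm{eff}}$. The density shape is
$\sqrt{(x_M - x)(x - x_m)}/x$; the package normalizes it numerically (the
closed-form constant buys nothing at this problem size, and the numeric
normalization is exact to quadrature accuracy, which the tests bound at
$10^{-6}$).

Three derived diagnostics:

* the **structure threshold** $\theta = (1/\sqrt{L} + 1/\sqrt{n-1})^2$ — a
  mean $F_{ST}$ below it carries no evidence of population structure. Note
  $\theta > 1/\sqrt{nL}$ always, so this is a more conservative rule than
  the familiar eigenvalue-testing threshold;
* the predicted leading residual eigenvalue
  $(1-\overline{F_{ST}})\,(1/\sqrt{L}+1/\sqrt{n-K})^2$ (scaled) and
  $\overline{H_S}\,(1/\sqrt{L}+1/\sqrt{n-K})^2/2$ (unscaled). The scaled
  residual columns have variance $\approx 1-F_{ST,\ell}$, which motivates
  the $(1-\overline{F_{ST}})$ shrinkage of the MP edge;
* the **KS distance** of the residual bulk to the MP law (`mp_fit()`) —
  an informal test for the number of populations: a correctly specified
  grouping leaves an MP-distributed residual (observed KS $\approx 0.08$
  with $n=200$), a misspecified one leaves structure in it.

The per-locus variance heterogeneity of an F-model (the $1-F_{ST,\ell}$
mixture) widens the bulk slightly relative to a homogeneous MP law; at the
simulated designs this effect is within the KS tolerance used by the tests
(0.1) but it is a known approximation, not an identity.

## The F-model generator

The simulator is first-class, tested code and defines the package's study
conditions. Per locus: $p_{anc} \sim \mathrm{Beta}(a, b)$; per population
$p_k \sim \mathrm{Beta}(p_{anc}(1-F_k)/F_k,\ (1-p_{anc})(1-F_k)/F_k)$, so
that $\mathrm{E}[p_k] = p_{anc}$ and
$\mathrm{Var}(p_k) = F_k\,p_{anc}(1-p_{anc})$; genotypes are Bernoulli per
haploid sample. Closed forms: $\mathrm{E}[H_A] = 2ab/((a+b)(a+b+1))$,
$\mathrm{E}[D_{ST}] = \mathrm{E}[H_A]\sum_k c_k(1-c_k)F_k$, and for three
equally sampled populations with uniform ancestral frequencies the two
non-null eigenvalues of the between-population covariance
$\Lambda_{jk} = \sqrt{c_jc_k}\,\mathrm{E}[(p_j-P)(p_k-P)]$ are
$(F_1+F_2+F_3 \pm \sqrt{F_1^2+F_2^2+F_3^2-F_1F_2-F_2F_3-F_3F_1})/54$, with
$\mathrm{E}[D_{ST}] = 2(\lambda_1+\lambda_2)$. $\mathrm{E}[F_{ST}]$ has no
useful closed form and is computed by Monte Carlo over locus draws
(`expected_fst_mc()`).

Numerical guards and choices:

* $p_{anc}$ is clamped to $[10^{-12}, 1-10^{-12}]$ so Beta shapes are
  strictly positive;
* monomorphic loci (total-sample frequency 0 or 1) are removed by default,
  matching the scaled analyses; the pre-filter count is recorded;
* a single seeded R stream drives each simulation — the package runs
  serially, so one generator is the simplest fully reproducible choice;
* reference designs: the three-population benchmark uses
  $F = (5, 10, 30)\%$, $\mathrm{Beta}(1,4)$, $n_k = 100$, $L = 10{,}000$
  simulated; the two-population designs use $F = 7\%$, $\mathrm{Beta}(1,9)$
  with $n = 200$, $L = 100{,}000$ and $n = 40$, $L = 15{,}000$; the
  single-population null uses $F = 15\%$, $\mathrm{Beta}(1,9)$ with
  pre-filter locus counts (15,400 at $n = 100$; 2,500 at $n = 10$) chosen
  once so that about 10,000 (resp. 1,000) polymorphic loci survive; the
  separation-power design uses $F = 10\%$, $\mathrm{Beta}(1,4)$, $L = 100$
  simulated loci at $n = 10$. Replicated studies use 200 replicates; the
  error-decay study uses 8 locus counts log-spaced in $[10^3, 10^5]$ with
  3 replicates each at $n = 150$, $F = 2\%$.

What the generator does **not** emulate: linkage disequilibrium (loci are
independent), admixture and migration (populations are draws around a
single ancestral pool), ascertainment of SNP panels, genotyping error and
missingness. Passing tests therefore demonstrate the algebraic identities
(which hold for any 0/1 matrix, real or simulated) and the finite-sample
behavior of the method under the F-model — not robustness to admixed or
spatially structured real data, where the discrete-$K$ assumption itself is
the binding approximation.

### Finite-sample bias of the plug-in estimates

The per-locus statistics computed from sample frequencies are plug-in
estimates: $\hat H_S$ is biased down by a factor $\approx 1 - 1/n_k$,
giving mean $F_{ST}$ an upward bias of order $H_S/n$. At $n = 100$ and
drift 10% this is about $+1.3$ percentage points relative to the
infinite-sample value, far larger than Monte-Carlo error. The theory-closure
tests therefore compare expectations against statistics computed from the
simulated population frequencies (the level at which the expectations are
defined) and separately bound the plug-in bias. The artificial-split null
illustrates the same phenomenon from another angle: splitting one
homogeneous population on the sign of PC1 manufactures a mean $F_{ST}$ of
about 1.1% at $n = 100$, $L = 10{,}000$ — close to the structure threshold
$\theta$, and correctly rejected by the separation condition.

## Adjusted F_ST for surrogate genotypes

Covariate effects are removed with the latent factor regression
$Z = YB^T + W + \epsilon$, fitted by alternating a ridge update of $B$ with
a truncated-SVD update of the rank-$k$ matrix $W$. Design choices:

* **Initialization.** The first half-step regresses the full $Z$ on the
  covariates ($W$ starts at zero). Initializing $W$ as the rank-$k$
  approximation of $Z$ instead lets the factors swallow covariate effects
  that align with the leading principal directions, and the alternation
  then converges to a local optimum with badly shrunken $\hat B$ (planted
  covariates with known effects are recovered with median correlation
  $\approx 0.7$ instead of $> 0.95$). Covariates-first is the standard
  identification convention: attribute contested variance to the measured
  variables.
* **Defaults.** `ridge = 1e-6 * trace(Y^T Y)/d` (numerical regularization
  only), `tol = 1e-8` on the relative objective change, `max_iter = 500`.
  The latent rank `k` has no default: it is a modelling choice, bounded by
  $n - d$. Setting `k` near that bound keeps $W + \epsilon$ as close as
  possible to $Z$ and is the right regime when the goal is to subtract
  covariate effects rather than to denoise.
* **Scaling.** The adjusted matrix $Z^{adj} = Z - Y\hat B^T$ is re-centered
  column-wise and divided by the column standard deviation with divisor
  $n$. This is the unique scaling under which the spectral definition of
  adjusted $F_{ST}$ (squared norm of the between-population matrix over
  $nL$) coincides **exactly** with the mean over loci of the $R^2$ of
  regressing each column on the population indicators; the equivalence is
  asserted to $10^{-10}$ on arbitrary matrices. Under label permutation the
  null expectation of that $R^2$ is $(K-1)/(n-1)$, a useful baseline when
  reading adjusted values.

Adjusted genotypes are continuous; the complement identities (which require
unit-variance 0/1 columns) are not guaranteed for them, and the package
warns accordingly.

## Degenerate inputs and tie-breaking

Monomorphic loci have $H_T = 0$: $F_{ST}$ is masked there rather than
defined by convention, and such loci are excluded from scaled matrices
(they contribute zero columns to the unscaled ones). Populations are
ordered by first appearance in the label source, making all outputs
deterministic. `K = 1` yields a zero between-matrix and errors from the
between-population estimators; `K = n` makes the residual matrix zero and
the spectral $F_{ST}$ equal to 1. The separation inequality is evaluated
strictly with zero tolerance, and the signed margin is always reported so
borderline verdicts are visible.

## Problem sizes used by the packaged studies

The replicated studies run at the design sizes above (200 replicates; up to
$n = 200$, $L = 10^5$ for single datasets), which keeps the full test suite
around two minutes on one core; single-dataset analyses at $n$ a few
hundred and $L \sim 10^5$ take seconds, dominated by the $O(n^2 L)$ Gram
products. Known limitations: no Tracy–Widom fluctuation theory for the
largest eigenvalue (point predictions and a KS fit only), no
Weir–Cockerham or Hudson estimators (the plug-in Nei/Wright definition is
what the spectral identities hold for), no LD pruning, and no special
handling of admixed individuals, for which the discrete-population model is
misspecified and the PCA approximation is expected to drift from the mean
per-locus $F_{ST}$.
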