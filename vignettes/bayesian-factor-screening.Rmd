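---
title: "Bayesian factor screening: model, sampler, and design notes"
author: "bfscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian factor screening: model, sampler, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bfscreen)
```

## The screening problem

With tens of thousands of candidate variants and a few hundred samples,
per-variant testing has little power against rare variants and pays a
heavy multiplicity price. Factor screening takes a different stance: fix
a small model size $m$, treat every size-$m$ linear model as a candidate,
and ask for each factor how much posterior mass falls on models that
contain it. The output is a ranking by marginal inclusion probability,
meant to feed a follow-up stage, not a calibrated per-factor test.

## Model and conjugate evidence

For a model $\gamma$ with $k$ design columns $X$ (centered minor-allele
counts of the active factors) and centered response $y$ of length $n$:

$$y = X\beta + \varepsilon, \quad \varepsilon \sim N(0, \sigma^2 I),
\qquad \beta \mid \sigma^2 \sim N(0, \sigma^2 \lambda^2 \Sigma), \qquad
p(\sigma^2) \propto 1/\sigma^2.$$

Integrating $\beta$ and $\sigma^2$ out analytically,

$$p(y \mid \gamma) \propto |\lambda^2\Sigma|^{-1/2}
\,|X'X + (\lambda^2\Sigma)^{-1}|^{-1/2}\, Q(\gamma)^{-n/2},$$

with $Q(\gamma) = y'y - y'X\,(X'X + (\lambda^2\Sigma)^{-1})^{-1}X'y$. The
normalizing constant depends only on $n$, so it never needs to be
evaluated: the sampler and the exhaustive enumerator only use posterior
*ratios*.

Both $Q(\gamma)$ and the determinant come from one QR decomposition of
the augmented regression of $(y; 0_k)$ on $\bigl(X;\ \lambda^{-1}C\bigr)$
where $C'C = \Sigma^{-1}$: $Q$ is the augmented residual sum of squares,
and $|X'X + (\lambda^2\Sigma)^{-1}|$ is the squared product of the R
diagonal. `tests/` verify this route against an explicit normal-equations
evaluation (relative error below $10^{-8}$ on random instances up to
$k = 10$) and, including all constants, against direct numerical
integration over $(\beta, \sigma^2)$ on small instances.

Numerical choices:

* **Log space throughout.** At $n = 697$, $Q^{-n/2}$ under- or overflows
  doubles; only log differences are ever exponentiated.
* **Prior square root by Cholesky.** $C = R^{-T}$ with $R$ the upper
  Cholesky factor of $\Sigma$; any square root gives identical $Q$ and
  determinant.
* **Degenerate columns are allowed.** A monomorphic variant contributes
  an all-zero centered column; the proper prior keeps the augmented
  design full rank, so the evidence stays well defined (a warning is
  emitted once per run).

## Tunable parameters

* `lambda` (default 1) — prior scale of effect sizes relative to the
  residual standard deviation. With trait noise of order 1 and plausible
  effects of order 0.1–1.4, $\lambda = 1$ is a flat-but-proper choice;
  results are insensitive to moderate changes because only evidence
  ratios matter.
* `m` — model size, i.e. how many factors a model may hold. Screening
  results are fairly stable in $m$ at the SNP level; at the gene level
  larger $m$ admits more false positives.
* `sigma_structure` — `"identity"` (default: no prior correlation among
  effects) or `"exchangeable"` with `rho` (default 0.1), which in gene
  mode places a slight correlation among the effects of variants within
  the same gene, block-diagonal over active genes.
* `model_prior` — `"uniform"` for SNP mode, where every model has
  exactly $m$ parameters; `"size_penalized"` for gene mode, prior
  $\propto e^{-k/2}$ with $k$ the number of regression coefficients.

Two deliberately exposed interpretation choices: $k$ in the penalty
counts design columns (the dimension of $\beta$), not $\sigma^2$ — only
differences in $k$ enter any ratio, so the constant choice is
immaterial; and a `size_penalty = "bic_log_n"` variant
($\propto e^{-(k/2)\log n}$) is available for comparison but off by
default, since the plain $e^{-k/2}$ form is the primary definition. The
$e^{-k/2}$ penalty demonstrably over-corrects — between equal-evidence
genes it favors the smaller by odds $e^{(k_2-k_1)/2}$ — and this bias is
reproduced faithfully rather than patched, since any correction is a
research question of its own (high within-gene correlation makes the
effective parameter count smaller than $k$).

## The sampler

States are sets of exactly $m$ active factors. One iteration proposes
swapping a uniformly chosen active factor for a uniformly chosen
inactive one — a symmetric proposal ($q = 1/(m(p-m))$ both ways) — and
accepts with probability $\min\{e^{\Delta \log \text{posterior}}, 1\}$.
Marginal inclusion probabilities are visit fractions, counting every
post-burn-in iteration including repeats; they sum to $m$ by
construction.

* **Initialization** is a uniformly random $m$-subset from the chain's
  seed; defaults are 100,000 iterations after 1,000 burn-in at the SNP
  level and 10,000 after 1,000 at the gene level.
* **Determinism.** One integer seed governs initialization, proposals
  and acceptance draws, so a chain is bit-reproducible; the caller's RNG
  state is restored afterwards.
* **Evidence cache.** Log posteriors are cached per model (keyed by the
  sorted active set) in a bounded hash that is flushed when full —
  flushing is as effective as LRU eviction here because chains revisit a
  small neighbourhood, and it keeps the bookkeeping trivial.
* **Convergence diagnostic.** Two chains with different seeds are
  compared by the Pearson correlation of their inclusion vectors
  (Spearman available); the check is reported, not gated, with a CLI
  warning below 0.9. On default-length runs of the default synthetic
  replicate the correlation exceeds 0.99.
* A proposal whose log posterior evaluates non-finite is auto-rejected.

Correctness is tested against exhaustive enumeration: on a $p = 10$,
$m = 2$ instance (45 models), visit frequencies come within total
variation distance 0.05 of the exact posterior at 50,000 iterations, and
with every gene holding exactly one variant under a uniform prior, gene
mode reproduces the SNP-mode chain bit for bit.

## Gene mode

A gene model's design stacks the centered columns of every variant of
its $m$ active genes (blocks ordered by gene), so $k$ varies between
models and the size-penalized prior applies. Gene-level statements can
also be derived from a SNP-level run: the mean marginal posterior over a
gene's variants divided by the per-variant prior $m/p$ — the prior
inclusion probability under the uniform model prior, since each factor
appears in $\binom{p-1}{m-1}$ of the $\binom{p}{m}$ models.

## The synthetic generator

No suitable public data set with this study's structure is
redistributable, so the package generates replicates with known truth.
The generator reproduces the *stated* features of the emulated study —
697 unrelated individuals; genes with highly variable variant counts;
a rare-skewed frequency spectrum; a handful of causal variants clustered
in few genes with effects in $[0.13, 1.35]$ against unit noise; Smoke,
Age and Sex covariates; an optional smoking-by-gene-burden interaction —
and fills every unstated detail with one fixed, documented convention:

* **Gene sizes**: log-series($\theta = 0.93$), mean ≈ 5 variants per
  gene, so the 200-gene default yields ≈ 1,000 variants. The log-series
  right tail gives a few large genes and many singletons, the
  characteristic exome shape.
* **Frequencies**: MAF $= \tfrac12 B$, $B \sim$ Beta(0.3, 2.5) truncated
  below at one copy per sample — median MAF ≈ 0.02, long common tail.
* **Causal plan**: 10 variants in 3 genes (5 + 3 + 2), effects
  $\{0.13, 0.25, 0.40, 0.55, 0.70, 0.85, 1.00, 1.15, 1.25, 1.35\}$
  paired with frequencies spanning 0.001–0.30 so that the plan contains
  rare-weak, rare-strong, common-moderate and common-strong variants —
  the mix that makes the method's characteristic behaviour visible
  (common, moderately strong variants are found; rare ones are not).
* **Covariates**: Smoke ~ Bernoulli(0.3) with coefficient 0.5, Age ~
  uniform on 30–70 with coefficient 0.02, Sex ~ Bernoulli(0.5) with
  coefficient 0.2 — a covariate $R^2$ of a few percent.
* **Ascertainment**: sites drawn monomorphic are redrawn, as a variant
  list is by definition ascertained from observed polymorphism.

What the generator does **not** emulate: linkage disequilibrium between
sites (independent binomial sampling by default; a within-gene Gaussian
copula LD option exists for robustness checks and is clearly beyond the
emulated study's stated structure), population structure or relatedness,
genotyping error, and any specific real gene. Passing recovery tests on
these replicates therefore demonstrates the machinery — evidence,
sampler, ranking — under clean conditions, not performance on real
exomes, where LD spreads posterior mass across correlated neighbours.

The trait decomposition (genetic + covariate + interaction + noise) is
stored exactly, so tests can assert against ground truth to machine
precision.

## Covariate adjustment

Covariates are removed once, up front: the trait is regressed on an
intercept plus the covariates and the residuals are the response
everywhere downstream. Both response and design columns are then
mean-centered, so variant models need no intercept. The cost of the
two-stage scheme is power against factors acting purely through a
covariate interaction (a smoking-by-gene effect is attenuated when only
the main effect is modeled); this trade-off is inherent to the design
and is left visible rather than patched.

## Problem sizes used by the test suite

Unit tests run on instances small enough to enumerate exhaustively
($p \le 10$). The end-to-end recovery checks use the default replicate
(697 × ≈1,000) with 50,000-iteration SNP chains over 10 replicates and
10,000-iteration gene chains — enough for two independently seeded
chains to correlate above 0.99 on this problem size, which is the
package's own convergence evidence for these settings. A
`"gaw17_scale"` preset (3,205 genes, 39 causal variants in 9 genes) is
provided for manual full-scale runs.

## Known limitations

* Factor–factor interaction terms are not included in model designs.
* Missing genotypes are a hard error by design; impute upstream if
  needed.
* The $e^{-k/2}$ gene prior over-penalizes large genes (see above).
* Marginal inclusion probabilities are ranking devices; they are not
  calibrated error rates. The reported "false-positive discovery rate"
  is the realized false fraction among flagged factors given known
  truth, not an expected FDR.
* `count_model_space` is exact only up to $2^{53}$ and refuses beyond;
  prior inclusion probabilities use the reduced form $m/p$ instead of a
  ratio of astronomically large counts.
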