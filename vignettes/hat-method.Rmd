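---
title: "Predictability of GBLUP without refitting: the leverage (HAT) correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictability of GBLUP without refitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hatpress)
```

## The model and what "predictability" means

GBLUP fits

$$ y = X\beta + \xi + e, \qquad \xi \sim N(0, A\sigma_\xi^2), \qquad
   e \sim N(0, I\sigma^2), $$

with $A$ an $n \times n$ marker-inferred kinship matrix. Two quantities
are routinely confused:

* **Fit** — how well the BLUP $\hat\xi$ tracks the centered phenotypes
  $\xi = y - X\hat\beta$ on the data the model was trained on. We report
  it both as $\mathrm{cor}(\xi,\hat\xi)^2$ and as
  $1 - \mathrm{ERESS}/SS$ with $\mathrm{ERESS}=\sum(\xi_j-\hat\xi_j)^2$;
  the two are close but not identical, so both are stored.
* **Predictability** — $R^2 = 1 - \mathrm{PRESS}/SS$, where PRESS sums
  squared residuals of individuals predicted *without their own
  contribution*. This is what cross-validation estimates and what a
  breeding program or risk model actually cares about.

Fit always exceeds predictability, often dramatically: an observation
participates in its own prediction, deflating its apparent residual.

## The leverage correction

The BLUP is linear in the centered phenotypes, $\hat\xi = H_R\,\xi$, with

$$ H_R = \sigma_\xi^2 A V^{-1}
       = U\,\mathrm{diag}\!\left(\frac{\delta_j}{\delta_j+\lambda}\right)U',
   \qquad \lambda = \sigma^2/\sigma_\xi^2, $$

where $A = U D U'$ and $\delta_j \ge 0$ are the eigenvalues. The ratio
form $\delta/(\delta+\lambda)$ is used throughout because it remains
defined when eigenvalues are exactly zero (a rank-deficient kinship is
the rule, not the exception, whenever $m < n$ or lines are clones).

The diagonal entry $h_{jj} \in [0, 1]$ is observation $j$'s leverage —
its conflict-of-interest factor. For a fold $k$ with estimated residuals
$\hat e_k = \xi_k - \hat\xi_k$, the predicted residuals are

$$ e_k = (I - H_{kk})^{-1} \hat e_k, \qquad
   \mathrm{PRESS} = \sum_k e_k' e_k . $$

**Exactness.** Write $M = (A + \lambda I)^{-1}$. Then
$I - H_{kk} = \lambda M_{kk}$, and the block-inverse identity
$M_{kk}^{-1} M_{k,-k} = -A_{k,-k}(A_{-k,-k} + \lambda I)^{-1}$ gives

$$ e_k = \xi_k - A_{k,-k} (A_{-k,-k} + \lambda I)^{-1} \xi_{-k}, $$

which is precisely the residual of a BLUP refit with fold $k$ deleted,
at the same $\lambda$ and the same whole-sample $\hat\beta$. The test
suite asserts this identity at $10^{-8}$ (it holds to machine precision)
for fold counts 2, 5, 10, and $n$. The *approximation* enters only when
the corrected residuals stand in for a CV that re-estimates
$(\lambda, \beta)$ per training fold; the true-CV engine (`kfoldCV`)
exists precisely to measure that gap rather than assume it.

The fixed-model analogue uses $H_F = X(X'WX)^{-1}X'W$ and, per fold,
$H_{kk} = X_k (X'WX)^{-1} X_k' W_k$ (the weight sub-block multiplies on
the right); weighted PRESS accumulates $e_k' W_k e_k$ with
$e_k = (I-H_{kk})^{-1}\hat e_k$. The mixed hat matrix
$H_M = H_F + H_R(I - H_F)$, with $H_F$ built under $W = V^{-1}$, maps
observed phenotypes to fitted values $X\hat\beta + \hat\xi$ and serves
conditional-residual diagnostics.

Generalized cross-validation replaces per-observation leverages by their
mean: $\mathrm{GRESS} = \sum_j \hat e_j^2 / (1 - \bar h)^2$. When all
leverages are equal ($A \propto I$) GCV and leave-one-out PRESS
coincide exactly; elsewhere they differ slightly, and we prefer PRESS
because its residuals are actual prediction errors.

## REML by eigen-rotation

Rotating $(y, X)$ by $U'$ turns $V$ into the diagonal
$\sigma_\xi^2 (D + \lambda I)$. $\beta$ and $\sigma_\xi^2$ profile out
analytically, leaving a one-dimensional restricted likelihood in
$\lambda$ (including the $\ln|X'V^{-1}X|$ term), maximized by Brent
search on $\log\lambda$ over $[10^{-6}, 10^6]$ with tolerance $10^{-8}$.
A 9-point scan across the bracket runs first: it detects flat profiles
and protects the refinement against multimodality. Additive constants in
the likelihood are dropped — only differences and the argmax are
meaningful.

Numerical choices, and why:

* **Eigenvalue clipping** at $10^{-8}$ relative to the largest
  eigenvalue: $\delta/(\delta+\lambda)$ tolerates exact zeros but a
  negative eigenvalue would produce a shrinkage factor outside $[0,1)$.
* **Leverage saturation** at $1 - 10^{-10}$: a leverage of 1 means the
  observation fully predicts itself (the $\lambda \to 0$ degenerate
  limit) and the predicted residual is undefined; this is a hard error
  naming the observation, not a warning.
* **Flat profile** ($A = I$): only $\sigma_\xi^2 + \sigma^2$ is
  identifiable. If the scan shows a range $< 10^{-8}$ the fit returns
  `identifiable = FALSE` with $\lambda$ = NA rather than an arbitrary
  argmax.
* **Boundary optima** are flagged (`boundary = TRUE`), meaning
  $\sigma_\xi^2 \to 0$ (upper edge) or $\sigma^2 \to 0$ (lower edge).
* Per-fold REML inside `kfoldCV` re-runs the full bracketed search on
  each training sub-block rather than warm-starting from the
  whole-sample $\hat\lambda$: the 1-D profile search is already cheap
  relative to the sub-block eigendecomposition, and independence across
  folds keeps failures attributable to a fold.

## Kinship construction

$A = a^{-1}\sum_k Z_k Z_k'$ with $a = n^{-1}\mathrm{tr}(\sum_k Z_k
Z_k')$, which forces $\mathrm{tr}(A) = n$ — the normalization every
downstream shrinkage factor assumes. Genotypes are coded $-1/0/+1$
(dosage $d$ maps to $d-1$). Defaults and their rationale:

* **Raw (uncentered) coding is the default**, matching the
  normalization formula as printed; `center` and `standardize` flags
  provide the common alternatives. Centered coding makes the code and
  dosage scales give identical kinship (tested); standardization drops
  monomorphic markers (zero variance) with a warning, while raw coding
  retains them.
* **Missing genotypes** default to per-marker mean imputation: it
  preserves marker means and keeps $A$ positive semidefinite. A marker
  with no observed calls is a hard error naming the marker.
* **Sub-setting** (missing phenotypes, CV training folds) always takes
  the sub-block of the whole-sample $A$, never recomputes kinship from
  subset genotypes: the partitioned model conditions one covariance
  matrix.

## Cross-validation engine and fold bookkeeping

Partitions are balanced (sizes differ by at most one), built by a seeded
shuffle plus round-robin labels, and reproducible from $(n, K,
\mathrm{seed})$; fold files round-trip through TSV so external
partitions replay bit-exactly. For $K < n$ the partition itself is a
noise source, so `replicateCV` averages over replicated partitions and
reports mean $\pm$ SE; at $K = n$ the partition is unique and the SE is
zero by construction. Each partition's SS is computed from the
concatenated per-fold $\xi_k = y_k - X_k\hat\beta_{-k}$ of that
partition (each fold centers by its own training $\hat\beta$), and is
reported alongside PRESS. $R^2$ is never clamped: a negative value means
PRESS exceeded SS — the model predicts worse than the mean, which is
worth seeing.

## Tuning the variance ratio (MPE)

`tuneLambda` treats $\lambda$ as a free parameter and maximizes
leave-one-out HAT (or GCV) predictability: a 201-point log-grid spanning
three decades either side of the REML estimate, then Brent refinement
between the best grid point's neighbours. The REML value is always a
grid candidate, so the returned maximum dominates the REML
predictability by construction. The coarse grid is deliberately dense —
the $R^2(\lambda)$ profile can carry shallow secondary bumps, and a
sparse scan followed by local refinement can polish the wrong one (the
dense-grid agreement test in the suite guards this). Re-centering by the
GLS $\hat\beta(\lambda)$ at every candidate keeps the profile honest at
extreme $\lambda$.

## What the simulator emulates — and what it does not

`simulateGenotypes` draws each marker's allele frequency uniformly from
the MAF range (default 0.05–0.5) and genotypes as two independent
Hardy–Weinberg alleles; `simulateTrait` draws $\xi \sim N(0,
A\sigma_\xi^2)$ through $U\sqrt{D}z$ with $\sigma_\xi^2 = h^2$,
$\sigma^2 = 1 - h^2$ (unit total variance), plus an optional
marker-effect mode ($b \sim N(0, (\sigma_\xi^2/a) I)$, $\xi = Zb$) that
exercises the full genotype-to-kinship pipeline, and optional replicated
environments sharing $\xi$ for the ANOVA heritability check. Everything
is deterministic under the seed.

The generator produces **unrelated** individuals: no linkage
disequilibrium, no family or population structure, no dominance or
epistasis. Consequences worth keeping in mind: predictability in such a
population is far below $h^2$ (information accrues only through weak
genomic relationships), whereas real inbred-line panels with strong
kinship show much higher $R^2$ at the same heritability. Passing tests
therefore certify the *algorithms* — exactness of the correction,
unbiasedness of REML, agreement of HAT/GCV/CV — not the magnitude of
predictability one should expect on structured real data.

Problem sizes used by the suite and the acceptance script, chosen as the
smallest that make the statistical assertions stable: a frozen
60-line × 200-marker fixture at $h^2 = 0.5$ (genotype seed 11, trait
seed 12) shared across tests; 200 replicates at $n = 500$, $m = 1000$
per heritability level (0.2 / 0.5 / 0.8) for parameter recovery; a
400-individual cohort with two crossed fixed effects for the end-to-end
pipeline exercise.

## ANOVA heritability

For a balanced genotype × environment table with one observation per
cell, the expected mean squares give $\hat\sigma_E^2 = MS_E$,
$\hat\sigma_G^2 = (MS_G - MS_E)/r$ for $r$ environments, and $H^2 =
\hat\sigma_G^2/(\hat\sigma_G^2 + \hat\sigma_E^2)$, with
$\hat\sigma_G^2$ clamped at zero when $MS_G < MS_E$. Unbalanced layouts
are rejected rather than approximated. This broad-sense $H^2$ from
replicated trials is the natural external yardstick for the
marker-based predictability estimates.

## Known limitations

* Single kinship only: no multi-kernel variance components (dominance,
  epistasis), no RKHS or Bayesian-alphabet models.
* The HAT correction is exact at fixed $\lambda$ but approximate
  against CV with per-fold re-estimation; the bias is upward and small
  in our simulations, and shrinks as $n$ grows — measure it with
  `kfoldCV` when it matters.
* `hatFull` refuses to materialize $H_R$ above $n = 10{,}000$ unless
  forced; diagonals and fold blocks never require the full matrix.
* Fold construction is uniform-random only (no stratified or
  family-aware partitions).
* VCF ingestion handles biallelic sites only and reads the GT field
  (dosages from genotype calls, not imputed posterior dosages).
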