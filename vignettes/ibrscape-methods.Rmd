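---
title: "Methods: isolation-by-resistance inference in ibrscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isolation-by-resistance inference in ibrscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibrscape)
```

## The question the pipeline answers

Landscape genetics asks whether the landscape between populations — not
just the straight-line distance separating them — shapes gene flow.
`ibrscape` implements the comparative isolation-by-resistance (IBR)
workflow for multilocus co-dominant genotypes sampled at georeferenced
populations:

1. fit a presence/background habitat-suitability model per *scenario*
   (a named subset of environmental layers: climate, topography, land use,
   land use over two epochs, or all of them);
2. read each suitability surface as a conductance surface and compute
   circuit-theoretic effective resistances between all population pairs;
3. regress pairwise genetic differentiation (Weir–Cockerham $\theta$ as
   $F_{ST}$, and Jost's $D_{est}$) on each scenario's resistance and on
   Euclidean distance, rank the candidate models by AICc and Akaike
   weights, and corroborate with multiple regression on distance matrices
   (MRDM) under matrix-label permutation.

A scenario that carries high Akaike weight with a significant fit is read
as the landscape component structuring gene flow; when no model beats the
panmictic null, the population is effectively unstructured at the study
scale.

## Genetic differentiation

Per-locus allele frequencies, observed heterozygote fractions and sample
sizes feed the Weir–Cockerham variance components $a$ (among populations),
$b$ (among individuals within populations) and $c$ (within individuals);
the multi-locus estimator is
$\hat\theta = \sum a / \sum (a + b + c)$ over all alleles and loci, and
pairwise values recompute the components on each pair alone. Negative
estimates are reported as computed (the downstream regressions use raw
values) and flagged.

Jost's $D$ uses the sample-size-corrected heterozygosity estimators with
the harmonic mean $\tilde n$ of the pair's sample sizes:
$H_{S,\mathrm{est}} = \frac{2\tilde n}{2\tilde n - 1} H_S$,
$H_{T,\mathrm{est}} = H_T + H_{S,\mathrm{est}} / (2 \tilde n r)$, and
$D = \frac{H_{T,\mathrm{est}} - H_{S,\mathrm{est}}}{1 - H_{S,\mathrm{est}}}\cdot\frac{r}{r-1}$
with $r$ populations ($r = 2$ pairwise). The multi-locus value is the
harmonic mean over loci with positive estimates; when no locus is positive
the pair is reported as 0 and flagged. Both estimators are verified in the
test suite against independently coded brute-force oracles to $10^{-10}$.

Spatially explicit Bayesian clustering is out of scope; its role — ruling
out hidden structure before interpreting IBD/IBR — is played by a
permutation *panmixia screen*: the global multi-locus statistic is compared
with its distribution under random reassignment of individuals to
populations (sizes preserved), `p = (1 + #{perm >= obs}) / (1 + n_perm)`.

Diversity reporting follows allozyme conventions: unbiased expected
heterozygosity $\frac{2n}{2n-1}(1 - \sum p^2)$ averaged over loci (as a
percentage), observed heterozygosity, allelic richness rarefied to a common
number of gene copies via the hypergeometric expectation, and the total and
95% polymorphism criteria. Hardy–Weinberg proportions are tested per
population and locus by a Monte-Carlo shuffle of allele copies (a simpler
exact-test stand-in for the usual Markov-chain enumeration, with the same
guarantee at the stated shuffle count).

## Suitability models

The suitability model is an L1-penalised presence/background logistic
regression on linear and quadratic terms of the standardised continuous
layers plus one-hot indicators of categorical layers. It is a deliberately
reduced stand-in for Maxent: it keeps the presence/background,
maximum-entropy-flavoured character and the bootstrap evaluation protocol
(70/30 presence splits, default 100 replicates, mean suitability across
replicates, rank-based test AUC against the background sample) while
dropping Maxent's hinge/product/threshold features. The total penalty
weight (default 1.0, i.e. `glmnet` lambda = 1/n on standardised features)
is deliberately light; its role is stabilisation, not feature selection.

Two numerical details matter downstream:

* **Logistic-output calibration.** The raw intercept of a
  presence/background fit depends on the arbitrary background sample size,
  which would make the *absolute* suitability — and therefore conductance
  ratios — prevalence-dependent. After each replicate fit the intercept is
  recentred so the typical (mean-logit) training presence scores 0.5,
  mirroring the calibrated logistic output format of the emulated method.
* **Projection without refitting.** The land-use-change scenario fits on
  the current-epoch layer and projects the same coefficients onto the past
  epoch; the replicate's suitability is the *stability surface*, the
  element-wise mean of the two projections. Identical epochs therefore
  reproduce the plain land-use model exactly (asserted in the tests).

Variable contributions are permutation importances: per replicate and
layer, all of the layer's design columns are shuffled together across the
training rows and the drop in training AUC under the stored coefficients is
recorded; mean drops are floored at zero and normalised to sum to 100.
Terrain slope and aspect come from Horn's 3x3 finite differences (aspect in
compass degrees, flat cells flagged -1), and a Pearson $R^2$ screen over
continuous layer pairs (threshold 0.75) flags collinear candidates without
choosing among them.

## Circuit-theory connectivity

Suitability is clamped below at a small positive floor (default $10^{-4}$)
and used directly as cell conductance, so hostile matrix slows movement but
never disconnects the lattice. One node per cell; 4-neighbour edges by
default (the 8-neighbour scheme, with diagonal conductances scaled by
$1/\sqrt 2$, is available); edge conductance is the arithmetic mean of the
two cell conductances, with a harmonic-mean option. For each population
pair a unit current is injected and extracted and the reduced Laplacian
system is solved by a sparse Cholesky factorisation computed once per
surface; the voltage difference is the effective resistance. A dense
Moore–Penrose oracle ($R_{ij} = L^+_{ii} + L^+_{jj} - 2L^+_{ij}$) provides
the independent cross-check on small graphs, and the metric axioms,
Rayleigh monotonicity and the exact conductance-scaling law are enforced as
properties in the tests.

## Model comparison

Each candidate model regresses the unfolded lower triangle of the genetic
matrix on one predictor (a scenario resistance or Euclidean distance).
AICc uses the Gaussian profile likelihood
$L = -\tfrac n2(\ln(2\pi\,\mathrm{RSS}/n) + 1)$ with $k = 3$ parameters
(intercept, slope, error variance) and $n$ = number of pairs; Akaike
weights are $w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$. The reported
regression $R^2$ is adjusted (it can be negative under the null — a
property the published tables of this analysis family show) and the slope
p-value is descriptive only, since pairs are not independent. MRDM
regresses the same unfolded vectors but assesses significance by jointly
permuting rows and columns of the response matrix — permuting the unfolded
vector instead would destroy the within-row dependence of distance data and
is demonstrably anti-conservative (a test asserts the two nulls differ).
When the permutation count reaches the number of distinct label
permutations, the test enumerates exhaustively. No multiple-testing
correction is applied across scenarios, matching the analysis family this
mirrors; the scenario tables flag "supported" models by the
$\Delta\mathrm{AICc} < 2$ + significant-fit rule.

## The synthetic-data generator

No genotypes or GIS layers are deposited for the emulated study, so the
generator is a first-class module producing data with the statistical
structure the analysis assumes:

* **Landscape.** Continuous layers are Gaussian-smoothed white noise
  (kernel width = `patchiness`, default 5 cells) plus a linear
  macro-gradient; altitude is a smoother field on a 300 ± 120 m scale; land
  use is a quantile-thresholded smooth field giving a mosaic of (default) 4
  classes. The past epoch reassigns whole contiguous patches until a target
  fraction of cells (default 0.3) differs; the default `"loss"` mode draws
  strictly better past classes, emulating habitat loss over the inter-epoch
  span.
* **Truth surfaces.** Suitability is a logistic function (gain 3) of the
  standardised land-use class score by default, giving a best:worst
  conductance ratio near 50 — a strongly contrasted habitat/matrix
  landscape, the regime in which a sedentary specialist experiences land
  use. Conductance equals suitability.
* **Genotypes.** A logistic-normal drift approximation rather than a
  forward simulation: per biallelic locus, population logit allele
  frequencies are multivariate normal with covariance
  $\sigma^2 \exp(-R_{ij}/\lambda)$ on the truth effective-resistance matrix
  $R$, then individuals draw two Bernoulli allele copies (Hardy–Weinberg
  within populations). $\sigma = 0$ or $\lambda \to \infty$ gives panmixia.
  The default $\lambda = 2\max(R)$ keeps $\exp(-R/\lambda)$ in its
  near-linear range, so expected differentiation grows approximately
  linearly with resistance — the regime a linear-regression comparison
  assumes; a $\lambda$ far below the resistance range saturates the
  covariance and destroys the rank signal even for the true predictor.
  $\sigma = 1.5$ (default) yields global $\theta \approx 0.08$, the
  magnitude reported for the structured specialist of the emulated study;
  the "strong structure" regime used in the recovery tests sets
  $\sigma = 2$ ($\theta \approx 0.13$).
* **Scale.** The packaged study scale is a 60 x 60 grid, 12 populations, 18
  biallelic loci, 30 individuals per population and 30 presence records —
  the emulated study's site, locus and record counts with cell counts
  reduced to desk scale (its raster had millions of cells; the circuit
  solver here is exact, so scale affects only resolution, not method).

What the generator does *not* emulate: multi-allelic allozymes (loci are
biallelic by default), selection, temporal sampling, coalescent noise
beyond the drift approximation, spatially autocorrelated sampling of
individuals within populations, and any attempt to mimic the real
sampling-site geometry. Passing tests therefore demonstrate that the
machinery recovers structure *of the assumed form*, not that the
biological conclusions of any particular field system are reproducible.

## What the recovery experiments show — and a known limitation

With genotypes generated on the land-use truth conductance, the land-use
scenario's resistance is the best-correlated predictor and the Euclidean
distance model essentially never outranks it. But the land-use-change
scenario is a structural near-duplicate — it shares the land-use layer, and
after spatial integration its resistance matrix correlates above 0.99 with
the land-use resistance, just as the two scenarios are statistically
indistinguishable in the published analysis this mirrors. Top-1
identification of the exact truth scenario is therefore capped well below
certainty: in our experiments, even substituting the *true* resistance
matrix for the land-use predictor yields a ~70% top-1 rate at these
conditions, and the estimated predictor reaches ~45-60%. The package
reports this honestly; analyses of real data should interpret support
shared between the two land-use scenarios as support for the land-use
*family*, which is exactly how the emulated study reads its own tables.

## Numerical and degenerate-input choices

* Deterministic seeding throughout: a single study seed expands into
  per-stage seeds by a stage-name hash, so any stage can be rerun in
  isolation; all RNG use is wrapped so callers' RNG state is untouched.
* Genotype covariance matrices get a jitter-and-retry Cholesky
  ($10^{-10}$ to $10^{-4}$ on the diagonal) because $\exp(-R/\lambda)$ of a
  resistance metric is not guaranteed positive definite; failure after the
  largest jitter is an error, never a silent fallback.
* Exact regression fits floor RSS at $10^{-300}$ with a warning; constant
  predictors are an error naming the scenario.
* Monomorphic loci contribute zero variance components to $\theta$, are
  excluded from the positive-locus harmonic mean of $D$, and give a flagged
  HWE p of 1.
* Focal sites on nodata cells snap to the nearest valid cell within a
  3-cell radius (recorded), two sites may not share a cell, and focal sites
  in different lattice components raise an explicit infinite-resistance
  error naming the pair.
* The AICc tie-break keeps a single zero delta by input order; ties are
  all flagged as supported.

## Problem sizes used by the packaged tests

The test suite and the demo fixtures run at desk scale: resistance oracles
on grids up to 20 x 20 against the dense pseudo-inverse; estimator oracles
on up to 4 populations x 5 loci x 20 individuals; MRDM size checks on 500
null datasets of 12 populations at 199 permutations; recovery experiments
on 20 seeded replicates of the 60 x 60 study scale with 20 bootstrap
replicates per suitability model. These sizes were chosen so the full suite
documents the method's behaviour in minutes while every check remains a
property of the method rather than of a particular seed.
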