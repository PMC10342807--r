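---
title: "Methods: quantifying transcriptional signature reversal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying transcriptional signature reversal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigreverse)
```

# The problem

A drug is a plausible repurposing candidate for a disease when it drives
gene expression in the opposite direction to the disease's own
transcriptional signature. sigreverse implements the full analysis chain
for testing that hypothesis on bulk expression data: global QC of a
treated-versus-control study, a covariate-adjusted differential profile,
meta-analytic composites across disease studies, pathway enrichment,
reversal scoring, and a planar embedding of a compound library around a
disease target. Everything operates on signed per-gene Z scores, so the
methods are rank- and threshold-based and insensitive to the absolute
scale of the upstream normalisation.

# Self-organising map QC

The map is a square lattice (default 10×10) of weight vectors living in
*sample* space. Gene expression vectors, standardized gene-wise to
N(0, 1) across samples, are presented in seeded random order; the
best-matching node (Euclidean-nearest weight) and its lattice
neighbourhood move toward each presented vector:

$$\vec w \leftarrow \vec w + \delta\,(\vec g - \vec w)\,
  e^{-\left((i-i_0)^2 + (j-j_0)^2\right)/\sigma^2}$$

with step size $\delta = 0.01$ and neighbourhood width $\sigma = 2$, both
decaying by 0.99 over training. Two choices here were genuinely open:

* **Neighbourhood kernel.** The Gaussian on squared lattice distance (the
  standard competitive-learning kernel) is the default. A variant that
  attenuates by the squared difference of squared node norms,
  $\exp(-(i^2{+}j^2-(i_0^2{+}j_0^2))^2/\sigma^2)$, is available via
  `som_grid(kernel = "norm_diff")` for comparison; we do not recommend it,
  because it makes all nodes on a ring around the lattice origin update
  identically and therefore cannot form localised islands.
* **Decay schedule.** Decay is applied per full pass over the genes
  (`decay_per = "epoch"`, the default). Applying it after every single
  gene presentation caps the total learning mass at
  $\sum_t \delta_t = \delta/(1-0.99) = 1$, which bounds the contraction
  toward any attractor at $e^{-1}$ — the map then provably cannot
  converge onto even a perfectly homogeneous input set. The
  per-presentation variant is retained (`decay_per = "presentation"`)
  for comparison.

Node weights are regressed on a binary covariate (treatment, sex); the
per-node slope Z scores, displayed on the lattice, show the expression
variation the covariate explains. Global significance uses the maximal
absolute node score with a permutation null over covariate assignments
and the add-one convention $p = (b + 1)/(n_{\mathrm{perm}} + 1)$, which
cannot report zero. Because training never sees the labels, permuting
labels against a fixed map ("regress" mode) is exact for the regression
stage; "retrain" mode (the default) additionally re-initialises the map
per permutation so that training stochasticity enters the null.
Residualising a covariate fits, per gene, an intercept-plus-indicator
linear model and keeps the residuals; residual rows are mean-centred, so
genes orthogonal to the covariate keep their centred values.

One caveat worth knowing: the max-node statistic saturates. If planted
effects are strong enough that a node's weight vector equals the
covariate indicator exactly, the regression t-statistic is limited only
by the gene noise in the weights; after residualising a second covariate
the weights are confined to its orthogonal complement and can no longer
align perfectly with a correlated indicator, so the max score drops for
purely geometric reasons. Comparisons of pre- versus post-residualization
maps are meaningful in the moderate-signal regime, and our tests run
there.

# Differential profiles and composites

The differential profile is the per-gene Z score — coefficient over
standard error — of the treatment term in an ordinary least-squares fit
of expression on treatment plus covariates (sex by default). The
statistic is t-distributed under the null; it is used directly as a Z
because every downstream consumer is rank- or threshold-based and the
residual degrees of freedom are fixed across genes. Collinear designs
(e.g. sex confounded with treatment) are rejected with the offending
column named. Alternative probes for one gene collapse to the probe with
maximal |Z| (sign preserved; exact ties keep the first probe in input
order and are reported).

Profiles from $k$ studies combine gene-wise as the Stouffer composite
$\sum_i Z_i/\sqrt{k}$, where a gene missing from a profile contributes
zero while $k$ stays the total number of profiles. This keeps the
composite standard normal per gene when the inputs are independent
standard normals — the property the null calibration tests assert — at
the price of shrinking composites toward zero for sparsely covered
genes; the per-gene coverage count is recorded so users can filter.
Significance thresholding is strict (|Z| > 2) by default and
configurable.

# Pathway enrichment

For a gene set of effective size $n$ (its intersection with the profile)
on a profile of $N$ genes ranked by Z descending, the observed cumulative
fraction of members is compared with the uniform expectation $r/N$ along
the ranking; with $D^+$ the maximal deviation above and $D^-$ the
(signed) minimal deviation below, the score is $S = D^+ + D^-$. A set
concentrated at the top of the ranking approaches $+1$, at the bottom
$-1$, and a set spread uniformly scores near zero. Steps are unweighted
(each member contributes $1/n$), ties in Z break by stable input order,
and set members absent from the profile are ignored.

$S$ is calibrated to a Z score against a seeded Monte-Carlo null of
random same-size sets drawn from the profile's genes (default 1000
draws). The null depends only on $(N, n)$, so it is cached per set size;
scoring a 2450-set collection costs one null estimation per distinct
effective size. A numerical Brownian-bridge approximation of the null sd
(`bridge_null_sd()`) is provided as an independent cross-check — the
empirical null sd scales close to $n^{-1/2}$ as the bridge limit
predicts — but resampling remains the default because moderate $n$ and
discreteness effects matter at real set sizes. Gene-set resampling (as
opposed to profile permutation) was chosen as the null because the
statistic is a function of member ranks alone, making the two
constructions equivalent under exchangeability while resampling is far
cheaper and cacheable.

# Reversal scoring

Two profiles are compared over the features significant in *both* at the
threshold, cross-classified by direction into counts UU, UD, DU, DD
(first index: direction in the first profile). The correlation score

$$c = \frac{UU + DD - UD - DU}{UU + UD + DU + DD} \in [-1, 1]$$

is $-1$ under perfect reversal and $+1$ under perfect agreement. Its
significance is the exact one-sided Fisher probability of the table
conditioned on its margins: the `"anti"` alternative is the lower
hypergeometric tail of UU (depletion of concordant pairs — the
drug-reverses-disease direction), `"pro"` the upper tail. Both are
transpose-invariant and the two tails overlap in the observed table, so
$p_{\mathrm{anti}} + p_{\mathrm{pro}} \ge 1$. The same machinery applies
unchanged at gene level and at pathway level (profiles of enrichment Z
scores keyed by set name). A plain Pearson comparison with a
Fisher-transform Z is included as a utility for full-profile regression,
not as part of the reversal method.

# Radial embedding

To survey a compound library against one disease target, correlations
become distances: drug–drug $d_{ij} = f(1 - c_{ij})$ and drug–target
$d_{i0} = f(1 + c_{i0})$, so anti-correlated compounds sit near the
centre. The default transform is $f(x) = \sqrt{x/2}$ — the chord distance
between unit vectors with correlation $c$, and a true metric; the linear
variant $f(x) = x/2$ is available (`transform = "half"`). Both are
monotone, so the qualitative picture (anti-correlates plot centrally) is
transform-independent.

Radii are pinned to the target distances throughout; only angles are
free. They are optimised by steepest descent on the stress
$\Phi = \sum_{i>j} (d_{ij} - |\vec r_i - \vec r_j|)^2$ with the
Barzilai–Borwein step
$\gamma_k = \sum\Delta\theta\,\Delta g \big/ \sum \Delta g\,\Delta g$.
The first step (where $\gamma_k$ is undefined) uses $\gamma_0 = 10^{-3}$,
and each raw step is safeguarded by halving until the stress does not
increase, since the raw BB step is non-monotone on this non-convex
objective. The landscape has local minima, so several seeded restarts
(default 5) are run and the lowest-stress layout kept. Pairs with no
co-significant feature have undefined correlation; their distances are
excluded from the stress rather than imputed, and a compound sharing
nothing with the target cannot be assigned a radius and is dropped with a
warning.

# What the synthetic generators emulate

* `generate_expression_study()`: a two-group study (defaults: 7 treated,
  10 control, mixed sexes) with an additive treatment shift on a sparse
  random gene subset, an additive sex shift on a disjoint subset
  (default 10% of genes — disjointness keeps the two signals separable,
  which real data does not guarantee), and i.i.d. Gaussian noise. The
  default effect (2 noise-sd on 5% of genes) gives per-gene detection
  power of roughly 0.95 at |Z| > 2 in this design, a regime where both
  the map and the profile stages are informative.
* `generate_profile_family()`: disease profiles sharing a common signal,
  $\sqrt{s}\,\mathrm{common} + \sqrt{1-s}\,\mathrm{noise}$, so the
  expected pairwise Pearson correlation equals $s$; optional dropout
  makes genes absent (not zero), exercising the composite's missing-data
  rule. The common signal can be supplied — the pipeline's demo feeds it
  the negated treatment profile to plant a reversal relationship.
* `generate_gene_set_collection()`: uniformly random sets, sizes uniform
  on a range, for null calibration.
* `generate_drug_library()`: compound profiles
  $\rho\,\mathrm{target} + \sqrt{1-\rho^2}\,\mathrm{noise}$ with planted
  correlations $\rho$.

These emulate the *statistical* structure the methods assume — Gaussian
additive noise on normalised log-scale intensities, independence across
genes and studies. They do not emulate probe-level structure, batch
effects, gene–gene correlation, count noise, or the heavy annotation
redundancy of real pathway collections. Green tests therefore certify
the algorithms and their calibration under the assumed model, not
robustness to those violations; on real data the enrichment null in
particular is known to be optimistic when genes within a set are
correlated.

# Numerical choices and degenerate inputs

* Constant genes are dropped (with a count) before standardization;
  all-constant matrices are rejected.
* A node whose weight vector is constant across samples gets a
  regression Z of 0; residual variances are floored at machine epsilon so
  perfectly aligned weights give large finite scores.
* Permutation p-values use the add-one convention and require at least
  100 permutations and 2 samples per group.
* The enrichment null errors rather than dividing by a zero sd (only
  reachable when the set is the whole universe).
* Fisher tails are computed from the exact hypergeometric distribution;
  the tests verify them against exhaustive enumeration for all tables up
  to N = 40.
* Layout optimisation treats all-zero radii (every compound maximally
  anti-correlated) as already optimal, since angles then cannot change
  the stress.

# Problem sizes in the test suite

The suite favours many small seeded instances over few large ones:
studies of 300–2000 genes for map and profile checks, 10,000-gene
profiles for composite and enrichment calibration (1000 random sets),
50 replicate null studies for permutation calibration with 100
permutations each in full-retrain mode, and exhaustive Fisher
enumeration to N = 40. These sizes make every distributional check
stable across reruns at fixed seeds while the whole suite stays fast.

# Known limitations

* The differential fit is plain OLS per gene; no moderated variance, and
  deliberately no multiple-testing correction of per-gene Z — downstream
  scoring consumes the full ranked profile.
* Enrichment offers no weighted (GSEA-style) variant, leading-edge
  extraction, or cross-set FDR.
* The embedding is intentionally not a full 2-D MDS: radii are
  constrained by construction, so only the angular arrangement is fitted
  and compound–compound distances are approximated, not reproduced.
* The map supports a single rectangular non-toroidal lattice and a
  single binary covariate per regression.
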