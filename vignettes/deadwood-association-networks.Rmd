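---
title: "Methods: cross-taxon association networks for paired deadwood communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-taxon association networks for paired deadwood communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deadwoodlinks)
```

## The analytical problem

Wood-inhabiting fungi and saproxylic beetles colonise the same deadwood but
are censused with entirely different instruments: fungi as MOTU sequence
counts from wood drill samples normalised to a fixed sequencing depth, and
beetles as individuals from flight-interception traps. Both censuses share
sampling units — a forest plot crossed with a vertical stratum (canopy or
ground) — nested in regions with distinct species pools and in forest
management classes (`unm` unmanaged, `ext` extensively managed, `acf`
age-class forest). `deadwoodlinks` implements the statistical layer that
connects the two censuses: descriptive diversity, constrained ordination of
each community, a global coupling test between the two tables, and a
pairwise screen for candidate beetle–fungus associations.

All user-facing functions take a tibble whose first column is `site_id` and
whose remaining columns are taxon counts, plus a metadata tibble with the
design factors, and return tibbles, so the whole pipeline composes with the
pipe.

## Diversity layer

Alpha diversity is the exponential Shannon index `exp(-sum p_i log p_i)`
(natural log; the exponential makes the base irrelevant), i.e. the Hill
number of order 1 or "effective number of species". Individual-based
rarefaction uses the hypergeometric closed form
`E[S_m] = S - sum_i C(N - n_i, m) / C(N, m)`; sample-based rarefaction
averages pooled richness over site subsets, enumerating all subsets exactly
whenever there are at most 10,000 of them. The field-report summaries —
percentage of taxa shared by all regions, per-stratum species and
individual tallies — round percentages to one decimal, matching how such
figures are conventionally reported. Because strata share species, stratum
species percentages may sum to more than 100; they are intentionally
computed against pooled total richness.

Confidence bands for rarefaction curves are a design choice: a percentile
bootstrap of without-replacement subsamples, 1,000 replicates, 95% level,
seeded. An analytic variance exists for the expected richness itself but
not for the finite-replicate band a reader compares curves with, so the
bootstrap keeps the displayed uncertainty and the resampling process
identical.

## Constrained ordination

`cca_partial()` implements partial canonical correspondence analysis from
first principles. The count table is chi-square standardised:
`Q_ij = (p_ij - r_i c_j) / sqrt(r_i c_j)` with row masses `r` and column
masses `c`; `sum(Q^2)` is the total inertia (Pearson chi-square over the
grand total). Factor designs are dummy-coded, weighted-centred, and scaled
by `sqrt(r)`, so ordinary projections realise row-weighted least squares.
The conditioning factor (region) is regressed out of both `Q` and the
constraint designs; the residual is projected onto the constraints and the
projection decomposed by SVD. Inertia closes exactly:
conditioned + constrained + residual = total (asserted to 1e-8 on every
fit; the unit tests also check the eigenvalues against an explicit
normal-equation oracle and against an independent constrained-ordination
implementation).

Design choices that were genuinely open:

* **Sequential term tests.** Terms are assessed in formula order
  (management, then stratum), each term's inertia being the increment over
  the preceding terms. Marginal ("type III"-like) tests are out of scope.
* **Restricted permutations.** The ANOVA-like permutation test permutes
  whole rows of the condition-residualised matrix *within* region blocks:
  conditioning on region asserts that region is not exchangeable under the
  null, so permutations must preserve it. Blocks of size 1 are unpermutable
  and generate a warning.
* **Aliasing.** Dummy columns whose residual against the condition design
  is negligible relative to their original norm are dropped with a warning
  naming them. Without this, QR's relative tolerance keeps numerically-zero
  directions and spuriously absorbs inertia — visible when a constraint
  coincides with the condition, where the constrained inertia must be 0.
* **P-value convention.** `(1 + exceedances) / (1 + B)` throughout, so no
  permutation p-value is ever zero and the smallest attainable value is
  `1/(B+1)`.

## Co-inertia and the RV coefficient

Both tables are prepared identically — `log(x+1)` then column centring
under uniform row weights `1/n` — which keeps the two hyperspaces
commensurate for count data of very different magnitude (thousands of
beetle individuals versus a fixed 26 sequences). Co-inertia couples the
prepared matrices through the cross-covariance `W = X' D Y`; the SVD of `W`
gives the co-inertia axes and `||W||_F^2` the total co-inertia. The global
association statistic is

    RV = tr(Cab %*% Cba) / sqrt(tr(Caa^2) * tr(Cbb^2))

with `C` the weighted covariance operators. This is the standard RV — the
multivariate generalisation of a squared Pearson correlation, in [0, 1],
and the natural reading of "total co-inertia over the square root of the
product of the squared total inertias": the numerator equals the total
co-inertia and the denominator terms are the squared-covariance norms of
each table. A literal reading as (total inertia) squared per table would
not be bounded by 1 and is not the RV used anywhere in practice, so the
trace form is implemented. The permutation test permutes whole site rows of
the second (fungal) table only — the standard one-table RV null — with
B = 5999 by default.

## The pairwise association screen

The headline procedure screens every (beetle, fungus) pair retained by the
occupancy filter (presence on at least 5 sampling units, which in the
published Hainich-scale layout leaves 152 × 11 = 1,672 pairs):

1. Spearman correlation per pair: Pearson correlation of midranks.
2. Permutation p-values, two-sided, B = 10,000 by default: each replicate
   applies *one* shared random reordering of the fungal table's site rows
   and recomputes all pair correlations as one crossproduct of standardised
   rank matrices. Sharing the permutation across pairs keeps the joint null
   consistent and preserves each site's composition; resampling cells
   independently within rows would destroy compositional structure and was
   rejected. With B = 10,000 the minimum attainable p is about 1e-4.
3. A parametric t-approximation p (`t = rho sqrt((n-2)/(1-rho^2))`) is
   reported alongside for diagnostic comparison only.
4. Benjamini–Hochberg adjustment applied once across the whole family of
   tested pairs (not per fungus), because the screen is reported as a
   single family.
5. Edges with `q <= 0.1` (the conventional exploratory cutoff) form a
   signed bipartite network, ordered by decreasing |rho|.

Pairs involving a constant taxon vector have no rank information; they are
returned with `NA` statistics, excluded from the BH family, and counted out
of `n_pairs_tested`.

For small site counts (`n <= 8`) the screen can enumerate all `n!` row
permutations (`exhaustive = TRUE`), in which case the p-value is the exact
tail proportion; the unit tests verify the Monte-Carlo path against this
enumeration at n = 4.

## The synthetic community generator

No field matrices ship with the package; `generate_paired_communities()`
produces paired tables with the design's structure and known ground truth:

* **Layout.** Regions contain forest plots (managements assigned
  round-robin `unm`, `ext`, `acf`), each plot contributing a canopy and a
  ground sampling unit. The default mirrors the field layout's scale:
  3 regions, 16 plots, 32 units.
* **Species pools.** A fixed fraction of each taxon pool (default 0.15,
  within the 10–18% range typical of such cross-region comparisons) is
  present in every region; the remainder are regional exclusives.
* **Beetles.** Per-taxon means follow a log-series rank-abundance backbone
  (Fisher's alpha, default 8) scaled to ~220 individuals per unit, times
  taxon-specific log-normal shifts per region and stratum (effect =
  standard deviation of the shift, default 0.8); counts are
  negative-binomial (size 0.7), giving long tails and many singletons.
* **Fungi.** Each unit draws a multinomial of size 26 — the fixed
  per-sample sequencing depth — over the regional pool, with log-normal
  shifts per region and management. `normalize_depth()` separately
  implements hypergeometric subsampling of an arbitrary table to a fixed
  depth.
* **Planted associations.** Each planted fungal taxon owns a latent
  Gaussian site series; each planted beetle's latent is the normalised
  combination of its partners' series. Counts are quantile transforms of
  the latents (negative binomial with mean 12/size 4 for beetles; binomial
  within the depth for fungi, success probability budgeted so planted taxa
  expect about half the depth in total). Because discrete marginals tie
  ranks and attenuate Spearman correlations, the latent correlation is
  *calibrated*: a Monte-Carlo population is pushed through the actual
  quantile transforms and the latent r inflated until the realised Spearman
  matches `target_rho`. Rank-targeted copula planting was chosen over
  mechanistic co-colonisation modelling because the downstream screen
  consumes only ranks.
* **Reproducibility.** One RNG stream per scenario seed; the same seed
  reproduces the matrices bit for bit.

What the generator does *not* emulate: phenology of trap captures,
sequence-level artefacts (chimeras, PCR bias), spatial autocorrelation
within regions, and genuine ecological covariance between the two taxon
groups beyond the planted pairs. Passing calibration and recovery tests on
these synthetic conditions therefore demonstrates correctness of the
statistical machinery under the design's sampling structure, not that real
deadwood communities satisfy the null models.

## Calibration and recovery experiments

The test suite runs two experiment families on a null scenario chosen once
as the study-scale condition for single-region screens: one region, 8 plots
× 2 strata = 16 sampling units, beetle pool 45, fungal pool 15, all factor
effects and planted correlations zero.

* **Null calibration** (200 replicate datasets, B = 999): the pooled
  rejection rate of the pairwise permutation test at p ≤ 0.05 must lie in
  [0.03, 0.07], and the fraction of replicates whose q ≤ 0.1 network
  contains any edge — the empirical FDR under a complete null, where every
  edge is false — must stay at or below 0.1.
* **Recovery** (100 seeds, 10 planted pairs at target rho 0.85, B = 999):
  at least 80% of seeds must recover at least 8 of the 10 planted pairs in
  the q ≤ 0.1 edge set.

These problem sizes keep the full suite at roughly a minute on a single
core while leaving the binomial Monte-Carlo error of each rate well inside
its acceptance band.

## Numerical choices and degenerate inputs

* Exceedance comparisons subtract 1e-12 before comparing, so exact ties in
  discrete permutation distributions count as exceedances rather than
  falling to floating-point noise.
* All-zero site rows are retained through alignment (a unit can genuinely
  capture nothing); all-zero taxon columns are dropped with a warning,
  because chi-square standardisation divides by taxon marginals.
* Delimited input refuses non-integer counts by default and points at the
  European thousands-dot dialect (`"1.672"` meaning 1672) rather than
  guessing; `thousands_dot = TRUE` parses that dialect explicitly and
  `integer_counts = FALSE` accepts genuine fractional abundances.
* An empty association network is a legitimate result everywhere: writers
  emit header-only edge lists and empty graphs, and readers restore them.

## Known limitations

* Sequential CCA term tests depend on formula order; there is no marginal
  test.
* The RV permutation test permutes one table only; k-table and Procrustes
  couplings are out of scope.
* BH control is exact under independence or positive dependence; the
  shared-permutation screen induces mild dependence between pairs sharing
  a taxon, and the recovery experiments show the realised false-discovery
  fraction sitting at the nominal level rather than strictly below it.
* The screen is correlational by construction: edges are hypotheses about
  beetle–fungus association (e.g. spore vectoring), not causal claims.
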