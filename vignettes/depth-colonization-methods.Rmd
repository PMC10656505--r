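---
title: "Inferring depth colonization on coral phylogenies: models and methods"
author: "coraldepth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring depth colonization on coral phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coraldepth)
```

## The scientific problem

Scleractinian corals occur from the surface to beyond 6,000 m. Two
phenotypic innovations structure the group: photosymbiosis with
zooxanthellae (which chains a lineage to the photic zone) and coloniality.
`coraldepth` provides the statistical machinery to ask where in the water
column a clade originated, in which direction and how fast lineages
colonized new depths, and whether trait-defined lineages differ in those
dynamics. All components run on synthetic data generated by the package
itself, which is how the test suite and the acceptance script validate
them; no external downloads are involved.

## Data model

A `timetree` is an `ape` `phylo` object with branch lengths in Ma and a
per-branch rate scalar r (default 1). Node indices follow `ape`: tips
`1..n`, root `n+1`. Scalars survive serialization as BEAST-style
`[&r=...]` comment tags in Newick; a plain reader that ignores bracketed
comments still parses the topology and lengths. Species depth data are
log₁₀ meters, with depths below 1 m clamped to 1 m so log depths are
non-negative.

## Curation rules

Three rules filter occurrence records, in a fixed order (filtering is
order-independent within a species because depths are sorted internally):

1. **Bathymetry consistency** — a record whose depth deviates from its
   grid-cell depth by more than 500 m is dropped. The wide tolerance
   reflects the coarse precision of gridded bathymetry.
2. **Photic gap** (zooxanthellate species only) — records below the 165 m
   cutoff are kept only while consecutive sorted depths differ by at most
   50 m; the first larger gap truncates the tail. The first sub-photic
   record is compared against the deepest record at or above the cutoff
   (or the cutoff itself when none exists). Records exactly at 165 m count
   as above the cutoff.
3. **Azooxanthellate cap** — records below 5,740 m are dropped.

Ranges are summarized by the **median** depth rather than the mean because
sampling effort declines with depth, which biases the mean shallow. For
ranges crossing the equator the minimum absolute latitude is set to zero.

## Continuous models

**Brownian motion.** log₁₀ depth evolves with variance σ²·t per branch.
The log likelihood is computed by Felsenstein pruning (C++, linear time)
with a fixed root state; it equals the dense multivariate-normal density
built from the phylogenetic covariance matrix, which the test suite uses
as an independent oracle.

**Pagel's λ** multiplies the shared (off-diagonal) covariance and
preserves tip variances: λ = 1 is plain BM, λ = 0 makes tips independent.
As a tree transform this scales internal branches by λ and stretches each
pendant branch to preserve the tip's root-to-tip distance, so the pruning
algorithm still applies.

**Variable rates.** Each branch may carry a scalar r; `0 < r < 1`
compresses the branch (less change), `r > 1` stretches it (more change).
The reversible-jump chain places scalars on single branches or whole
clades. Priors, none of which the underlying model family fixes, are:
log r uniform on `[-log 100, log 100]`; a geometric prior (p = 0.1) on the
number of active scalars with the location set uniform over subsets (under
this prior the birth/death acceptance reduces to the geometric count
ratio); Jeffreys on σ². Proposals are log-normal for values, random-walk
for σ² and the root state. With a design matrix the coefficients get exact
Gibbs draws from their conditional normal, and scalars act on the residual
covariance (the predictors are not rescaled — the regression variant
scales residual variance only). The **median scaled tree** assigns a
branch its posterior-median scalar only when it is scaled in more than 50%
of draws *and* the median exceeds 2 (or is below 1/2 for compressions —
the symmetric rule; both thresholds are arguments). All other branches
report r = 1.

**Partitioned (local) rates** constrain every branch of a category to one
shared scalar. Only rate *ratios* are identified jointly with σ², so the
sampler recenters the mean log scalar into σ² each sweep (a
likelihood-invariant move) and downstream comparison standardizes each
tree by its minimum category rate before log₁₀ transform.

**Stepping-stone sampling** estimates log marginal likelihoods along a
ladder of power posteriors with β at quantiles of Beta(0.4, 1), short
Metropolis runs per stone and importance-sampling ratios between
neighbouring powers. The default proposal updates one coordinate at a
time, which mixes far better than joint updates in anisotropic posteriors.
On the conjugate normal toy (prior N(0,1), likelihood N(y|θ,1), y = 0) the
estimator is within 0.1 nats of the closed form −½log 4π. Bayes factors
are reported as `log BF = 2(log ML_complex − log ML_simple)` with > 2
"positive" and > 10 "very strong" evidence. Significance of a posterior
coefficient (or difference) is the proportion of draws on the minority
side of zero, declared significant below 0.05.

## Correlated discrete traits

Symbiosis and coloniality form a 4-state chain over AS, AC, ZS, ZC in
which only one trait may change per event: the dual-transition entries
(AS↔ZC, AC↔ZS) are structurally zero, leaving 8 free rates. The
likelihood is pruning with per-branch transition matrices; these come from
a one-off eigendecomposition of Q, validated against scaling-and-squaring
`expm` at the longest branch in the call and replaced by it when the
decomposition is inaccurate (near-defective Q). The root distribution is
the stationary distribution of Q by default (uniform and fixed vectors are
options; the choice is exposed because no principled default exists for a
non-reversible chain). Rates get iid exponential priors whose mean is a
Uniform(0, 10) hyperparameter; a reversible-jump move that pins individual
rates to zero is available behind a flag. Facultative species enter as
ambiguity vectors spreading 0.5/0.5 over their two compatible states.
Marginal ancestral state posteriors use the up–down pass per posterior
draw and are summarized by the across-draw **median**, then renormalized —
medians alone do not sum to one, and the renormalization makes the
reported vectors proper distributions while keeping the median's
robustness to skewed draws.

## Branch classification

Per trait, a node call is the state whose marginal posterior reaches the
support threshold (default 0.7, an argument — the appropriate value
depends on how concentrated the upstream posteriors are), otherwise
"uncertain". A branch then has one of four statuses per trait — a state,
a transition (different assigned states at its two ends: the origin of a
trait state), or uncertain (either end uncertain) — and the 16 raw
combinations merge to eight categories: AS, AC, ZS, ZC; TransS (symbiosis
transition, any coloniality status); TransC (coloniality transition,
symbiosis assigned); UncS (symbiosis uncertain, coloniality colonial or
uncertain); UncC (coloniality uncertain, symbiosis assigned). The three
remaining combinations (transition–transition, uncertain–solitary,
uncertain–transition) are excluded from analysis and logged.

## Ancestral depth reconstruction

Zero-length false tips grafted at every internal node (2n−1 tips total for
an n-tip binary tree) turn ancestral prediction into regression
prediction. The model is depth ~ path-wise rate (root-to-node distance on
the rate-scaled tree) with group-specific intercepts and slopes; real tips
carry hard 0/1 group codes (0.5 for facultatives), false tips carry the
node's posterior state probabilities, with ZS and ZC merged (probabilities
summed) into one column. Node predictions are phylogenetic conditional
means — regression fit plus the kriging term pulling each node toward its
relatives' residuals — with a spread that combines coefficient uncertainty
and the conditional (kriging) variance. Median and maximum depth are
reconstructed in two separate fits; if a node's reconstructed median
exceeds its maximum the two are swapped and the event logged (the source
procedure is silent on this failure mode). The minimum is back-calculated
in meters as `min = 2·median − max` (minimum and maximum assumed
equidistant from the median on the linear scale), clamped at 1 m. Note the
tension, documented rather than resolved: observed species minima come
from occurrence data, while reconstructed minima assume midpoint symmetry.

Two degeneracies are handled explicitly. A group with no real tips is
dropped from the design and its node probabilities folded into the
remaining groups. A group whose tips all share one path-wise distance
(e.g. any group untouched by scalars on an ultrametric tree — a uniformly
scaled clade also keeps its tips equidistant) cannot identify a slope, so
its slope column is dropped and only the intercept fitted.

## Trend statistics

PAD (phylogenetic ancestor–descendant) comparisons are the per-branch
Δ log₁₀ depth (descendant − ancestor), computed for minimum and maximum
limits; they telescope along paths. Direction tests are exact two-sided
binomial tests of shallower vs deeper against 0.5; exact-zero deltas are
counted as "unchanged" and excluded from the trials (the source is silent
on zeros; excluding them keeps the null exact). Cross-tree rate
comparisons standardize per-tree category medians by the tree minimum,
log₁₀-transform, report Shapiro–Wilk descriptively, and test with
Kruskal–Wallis plus pairwise Wilcoxon (normal approximation with tie
correction) under Holm adjustment. Long-term trends regress depth on node
age (Ma before present, larger = older) per category, separately for the
accelerated stratum and the joined constant+decelerated stratum
(decelerations are rare), excluding categories with fewer than ten
members. The depth-vs-scalar regression asks whether fast colonization
(large r) thins out with depth. These node/tip-level regressions are
conjugate Bayesian linear models; the tip-level depth ~ path-wise-rate
association is a phylogenetic regression with λ estimated.

## What the synthetic data emulate — and what they do not

The generator produces: ultrametric birth–death trees conditioned on tip
count; correlated trait histories drawn exactly from `expm(Q t)` per
branch; log-depth under rate-scaled BM with optional per-group
deterministic drifts (a controllable stand-in for trends that are emergent
in real data); and occurrence tables uniform within each species'
depth/latitude box on a synthetic shelf-to-abyss raster, with labelled
rule violations planted so curation recall and precision are computable
exactly. Real data differ in ways the simulations do not capture:
occurrence effort is strongly depth- and region-biased rather than
uniform; bathymetry error is spatially structured; real trait evolution
need not follow a homogeneous 4-state chain; and empirical trees carry
topological uncertainty. Passing tests therefore demonstrate that the
estimators recover what the models assume, not that the models are true of
corals.

## Numerical choices and problem sizes

Chain lengths are chosen for the simulation scales the package runs at,
not the original analysis scale: VR chains of 15,000–20,000 iterations on
60–200-tip trees, PGLS chains of 2,000–4,000, discrete chains of
1,500–2,500, stepping stones 16–24 × 300–400 iterations. Under those
settings the validation suite observes: λ = 0.5 covered by 90% intervals
in ≥ 90% of 20 datasets (200 tips); a clade simulated at r = 25 flagged in
≥ 80% of 20 replicates, with ≤ 10% of branches flagged under an all-r=1
null; a true 10× partition ratio recovered within [5, 20] in ≥ 80% of
replicates; the all-equal partition null keeps category medians within a
factor two (10 replicates at 200 tips — per-category precision grows with
the number of branches, so this check runs near the study's branch
count). The standardized Kruskal–Wallis omnibus is slightly conservative
(~3% rejection at α = 0.05) because row-minimum standardization induces
dependence between categories; it controls type-I error in every regime we
simulate. Matrix exponentials use `Matrix::expm` in R code; the C++
likelihood kernels use a validated eigendecomposition with an `expmat`
fallback. All generators and chains are seed-deterministic.

## Known limitations

Ornstein–Uhlenbeck and other non-Brownian models are out of scope, as is
model selection between dependent and independent trait evolution (the
source analysis imports that result). The covarion-style hidden
rate-switching extension of the discrete model is not implemented because
its parameterization is not restated in the source; the plain correlated
model is the default and only fitted variant. The VR regression scales
residual covariance only. Marginal likelihoods for the reversible-jump VR
model itself are not estimated (stepping stone covers fixed-dimension
models); model comparison in the pipeline therefore contrasts BM with the
partitioned-rate model. NEXUS output drops scalar annotations; use
annotated Newick to round-trip scaled trees.
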