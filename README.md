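# coraldepth

Phylogenetic inference of depth colonization in scleractinian corals.

Stony corals span the whole bathymetric gradient, from sunlit reefs to
abyssal plains below 6,000 m. Whether that diversity arose onshore and
spread into the deep, or the other way round — and whether the two great
coral innovations, photosymbiosis (zooxanthellate vs azooxanthellate) and
coloniality (colonial vs solitary), sped the journey — is a question about
*rates and directions of trait change on a time-calibrated phylogeny*.
`coraldepth` implements the full inference chain needed to ask it, and a
synthetic-data module so every stage can be exercised and validated without
any external downloads.

## What the package does

**Occurrence curation.** Raw occurrence records (species, lon, lat, depth)
are filtered against a bathymetry grid (drop records deviating > 500 m from
the grid depth), a photic-zone rule for zooxanthellate species (records
below 165 m kept only while consecutive sorted depths differ by ≤ 50 m),
and a 5,740 m cap for azooxanthellate records; per-species ranges are then
summarized as min/median/max depth (median, because sampling effort decays
with depth) with log₁₀ depths clamped at 1 m, and two datasets can be
compared by Spearman rank agreement.

**Continuous evolution.** Depth (log₁₀ m) evolves by Brownian motion with
variance σ²·t per branch. The variable-rates (VR) model multiplies each
branch by a scalar *r* — `r = 1` background, `r > 1` stretched
(accelerated colonization), `0 < r < 1` compressed — explored by
reversible-jump MCMC over branch and clade scalars; the *median scaled
tree* keeps a branch's posterior-median scalar only when the branch is
scaled in > 50% of the posterior with median magnitude > 2. Bayesian
phylogenetic regression (PGLS) with Pagel's λ, group dummy coding with 0.5
weights for facultative species, stepping-stone marginal likelihoods, log
Bayes factors (`log BF = 2(log ML_complex − log ML_simple)`, > 2 positive,
> 10 very strong), and posterior crossing-zero significance complete the
toolkit. A partitioned (local-transformation) variant estimates one rate
per trait-defined branch class.

**Discrete evolution.** Symbiosis and coloniality evolve as a correlated
pair of binary traits: a 4-state CTMC over {AS, AC, ZS, ZC} with dual
transitions disallowed (8 free rates), fitted by MCMC under exponential
priors with a Uniform(0, 10) mean hyperprior; exact marginal ancestral
state posteriors come from the pruning up–down pass, summarized by the
across-draw median and renormalized.

**Lineage classification.** Node posteriors are thresholded into per-trait
calls (state vs uncertain); each branch is then one of eight categories —
AS, AC, ZS, ZC, TransS, TransC, UncS, UncC — with the three impossible raw
combinations excluded and logged.

**Ancestral depths and trends.** Zero-length "false tips" grafted at every
internal node let a predictive regression (depth ~ path-wise rate with
group-specific terms; node probabilities as soft group codes, ZS and ZC
merged) reconstruct ancestral median and maximum depths; minimum depth is
back-calculated as `min = 2·median − max` in meters (clamped at 1 m).
Phylogenetic ancestor–descendant (PAD) comparisons — one Δ log₁₀ depth per
branch — feed exact binomial direction tests; per-tree partitioned rates
are standardized by the tree minimum and compared by Kruskal–Wallis plus
pairwise Wilcoxon with Holm correction; long-term depth-vs-age and
depth-vs-scalar regressions quantify the trends.

## A worked example

```r
library(coraldepth)

tree <- simulate_tree(60, seed = 1)                      # ultrametric, 60 tips
cl   <- coraldepth:::.clade_edges(tree)
edges <- cl[[which(vapply(cl, length, 1L) >= 8 & vapply(cl, length, 1L) <= 16)[1]]]
truth <- timetree(tree, replace(rep(1, ape::Nedge(tree)), edges, 25))
sim   <- simulate_depth(truth, sigma2 = 0.005, root_depth_log = 3, seed = 2)

chain  <- vr_rjmcmc(tree, sim$tip_depths, n_iter = 15000, burnin = 4000,
                    thin = 10, seed = 3)
scaled <- summarize_scaled_tree(chain)
summary <- attr(scaled, "summary")
median(summary$median_scalar[edges])   # 26.92  -- the planted r = 25 clade
mean(summary$significant[-edges])      # 0.038  -- 4 of 105 background branches
table(attr(scaled, "rate_class"))
#> accelerated    constant decelerated
#>          17         101           0
```

The chain recovers the planted acceleration (posterior median scalar ≈ 27
on the 13 clade branches, all flagged significant) and leaves almost all
other branches at the background rate. `enumerate_pads()`, `classify_branches()`,
`reconstruct_node_depths()` and `compute_pad_deltas()` continue the chain
from here; the vignette walks through the full pipeline.

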