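---
title: "Null-model assembly partitioning and co-occurrence networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null-model assembly partitioning and co-occurrence networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoassembly)
```

This vignette is the package's account of its science: the models it fits,
the parameters that matter, what the synthetic-data generator does and does
not emulate, and the design decisions taken where the methods literature
leaves room.

## The inference problem

Community ecology distinguishes deterministic assembly — environmental
filtering and biotic interactions sorting taxa by their niches — from
stochastic assembly — drift, probabilistic dispersal, priority effects.
Neither is observable directly from a survey; both must be inferred from
the *pattern* of pairwise community turnover. The framework implemented
here uses two complementary null models:

1. **Phylogenetic turnover (βMNTD / βNTI).** If niches are phylogenetically
   conserved, selection leaves a phylogenetic signature: communities
   filtered toward the same optimum are composed of closer relatives than
   chance expects, communities filtered apart of more distant ones. βMNTD
   measures, for each taxon, the patristic distance to its nearest relative
   in the partner community (abundance-weighted by default). The null
   shuffles taxa labels across the entire phylogeny — every OTU in the
   study table, not merely those present in the pair or habitat at hand —
   and βNTI is the resulting standardized effect size. |βNTI| > 2 is the
   conventional two-standard-deviation cut: βNTI < −2 ⇒ homogeneous
   selection, βNTI > +2 ⇒ heterogeneous selection.

2. **Taxonomic turnover beyond chance (RC on Bray–Curtis).** Pairs not
   classified as selection are compared against probabilistic reassembly:
   each sample is rebuilt `reps` times, preserving its observed richness
   and total abundance, drawing species identities without replacement with
   probability proportional to occupancy frequency and assigning the
   remaining individuals multinomially by regional relative abundance (each
   drawn species keeps at least one individual, which is what preserves
   richness exactly). RC rescales the percentile of the observed Bray–Curtis
   value to [−1, 1]. RC > 0.95 ⇒ dispersal limitation (more turnover than
   chance), RC < −0.95 ⇒ homogenizing dispersal (less), otherwise
   "undominated".

The partition is applied per habitat: sediment and water samples are never
pooled into one pair set, though the tip-shuffle pool and the Raup–Crick
occupancy pool always span the full study table.

### Boundary policy

The literature's verbal rules leave |βNTI| = 2 and |RC| = 0.95 unassigned.
We count equality as the non-null class (selection, respectively the
dispersal class) so that every non-degenerate pair is classifiable; the
thresholds are arguments of `partition_processes()`. Pairs whose null βMNTD
distribution has zero spread (possible when two samples share every taxon,
since a joint shuffle keeps shared taxa at distance zero) are flagged
`degenerate`, reported with `bnti = NA`, and excluded from fractions with a
warning rather than silently dropped.

### Null-model conventions

* The tip shuffle is the "taxa.labels" randomization of the picante
  tradition: one permutation of the taxa-to-tip assignment per repetition,
  reused for every sample pair. This keeps all pairs' nulls consistent
  within a repetition and makes 999 repetitions affordable (the C++ kernel
  recomputes the full βMNTD matrix per shuffle).
* 999 repetitions is the default everywhere a permutation count is needed
  (βNTI, RC, Mantel, random networks), the only permutation count the
  source tradition states.
* RC nulls are built on counts at each sample's original total, and
  Bray–Curtis is always computed on relative abundances.
* Ties in the RC counting formula are resolved with half weight inside a
  1e-10 tolerance band.

## The synthetic-data generator

The generator emulates the study design the package targets: `n_lakes`
(default 23) lakes sampled in two habitats, a shared species pool
(default 500 OTUs), ~10^4 reads per sample, one selective environmental
axis (TP) plus uncorrelated noise variables with habitat-specific
distributions. Each regime is a ground-truth construction — the surveys the
package analyzes are observational, so these mechanisms are the package's
own, chosen so that each assembly process leaves the signature its
classifier looks for, and validated by the recovery tests.

* **Species pool** — lognormal abundance distribution, `sdlog = 1`.
  Flat enough that the abundance-weighted βMNTD averages over many taxa
  (which is what gives the null distribution a small spread and the
  classifier its power), steep enough to retain a rare tail for the
  occupancy-based RC null.
* **Niche trait** — Brownian motion on a copy of the tree whose node
  heights are raised to `conservatism = 0.2`. The transform concentrates
  trait variance toward the root, i.e. habitat preference is conserved at
  clade level. This is deliberate and matters: with a plain Brownian trait
  the set of taxa within a niche band is scattered across many small
  clades (the trait recrosses any value repeatedly along the tree), and
  βNTI has essentially no power to detect even strong selection. Deep
  conservatism is also the regime the βNTI framework itself assumes when
  it interprets clustered nearest-taxon distances as selection.
* **Selection regimes** — sampling weights ∝ pool × exp(−(z−opt)²/2σ²)
  with σ = `selection_sd` = 0.15 on the standardized trait (strong
  filtering), times a per-sample colonization lottery: Bernoulli presence
  with `colonization = 0.6` and a lognormal abundance lottery with
  `lottery_sd = 0.5`. The lottery is essential, not decorative: without
  it, samples filtered toward the same optimum share their dominant taxa,
  shared taxa contribute zero nearest-taxon distance under both the
  observed and the shuffled assignment, and the homogeneous-selection
  signature vanishes. Ecologically it is priority effects/drift *within*
  the selected niche. Under `homogeneous_selection` all lakes share one TP
  value (variance zero on the selective axis); under
  `heterogeneous_selection` TP runs a uniform gradient (0.02–0.5 mg/L)
  mapped linearly onto trait optima in [−1.5, 1.5].
* **Dispersal limitation** — independent Wright–Fisher drift per sample:
  50 multinomial resampling generations at community size 500 from the
  common pool, with a small residual migration (`migration = 0.01`) from
  the pool each generation. Strictly zero migration is *not* used: at
  drift strengths high enough to create the required turnover it fixes
  communities on a handful of taxa, and the collapse in richness inflates
  the Raup–Crick null (identity draws from a small, even occupancy pool)
  until the RC > 0.95 signature disappears. A trickle of immigration
  preserves the rare tail while dominant abundances diverge — "limited",
  rather than absent, dispersal.
* **Homogenizing dispersal** — mass effects: one realized regional
  community (a multinomial draw of 2000 individuals from the pool) is
  shared by every sample at migration `m = 0.95`, mixed with a 5% local
  lottery component. Independent draws from the *pool distribution* would
  not do: the Raup–Crick null reassembles from the meta-community's own
  marginals, so iid sampling is statistically indistinguishable from its
  null and RC hovers near zero. Sharing one realized regional community
  makes observed pairs genuinely more similar than reassembly predicts,
  which is the phenomenon the RC < −0.95 class denotes. `m = 1` exactly is
  avoided as the default because identical count vectors degenerate the
  βNTI null.
* **Neutral mix** — drift with intermediate migration (0.3).

Recovery, measured at the defaults (46 samples, 500 OTUs, 199-repetition
nulls) in the acceptance suite: a majority of classified pairs carry the
generating label for homogeneous selection, dispersal limitation and
homogenizing dispersal; heterogeneous selection recovers a majority of
βNTI > 2 pairs in the planted-gradient association test.

What the generator does **not** emulate: sequencing error, chimeras, copy
number variation, compositional biases of library preparation, spatial
autocorrelation among lakes, and temporal dynamics. Passing recovery tests
therefore says the *inference machinery* is correct under its own
assumptions — niche conservatism, adequate depth, a closed regional pool —
not that those assumptions hold in any particular real survey.

## Diversity and ordination conventions

* **Chao1** uses the bias-corrected form S + F1(F1−1)/(2(F2+1)), defined
  when no doubletons exist; it requires integer counts and refuses
  proportions.
* **Shannon** defaults to log base 2, matching the QIIME-era toolchain
  that popularized these α-diversity panels; the base is an argument.
* **Faith's PD** includes the path to the root ("whole-tree" PD), via
  picante.
* **βMNTD** is abundance-weighted by default (the framework norm);
  unweighted is an option. OTUs absent from the tree are dropped from
  phylogenetic metrics with a counted warning; taxonomic metrics keep
  them.
* **PCoA** reports negative eigenvalues as-is (Bray–Curtis is
  non-Euclidean) instead of applying corrections.
* **β-diversity group contrasts** compare within-group pairwise distances
  with a Wilcoxon rank-sum test. Pairwise distances are not independent
  observations, so that p-value is descriptive, not inferential.
* **Rarefaction** is not applied before α-diversity; depth in the
  simulator is constant by design, and for field data the choice is left
  to the caller.

## Network conventions

* Filtering: mean relative abundance strictly > 0.01% (computed within
  the habitat's sample set) and presence in at least 7 samples.
* Edges: Spearman with average ranks, two-sided p from the t
  approximation (the same large-sample form `cor.test` switches to under
  ties; at 23 samples per habitat exact enumeration is neither feasible
  nor needed), Benjamini–Hochberg across all upper-triangle pairs, and
  |rho| > 0.6 with q < 0.01. The q < 0.01 default follows the stricter of
  the two conventions in circulation (0.05 is common in figure captions);
  both are arguments, and the pipeline logs the thresholds actually used.
  Correlations are computed on relative abundances; within one sample set
  the per-sample normalization is rank-preserving, so counts would give
  identical edges.
* Topology of possibly disconnected graphs: average path length and
  diameter over reachable pairs only; eccentricity within components;
  closeness centralization on the largest component; clustering
  coefficient means global transitivity (3 × triangles / connected
  triples), with the local mean also available per node. Negative edges
  participate as ordinary unweighted edges and are counted separately.
* Modules: deterministic greedy modularity optimization
  (`igraph::cluster_fast_greedy`), chosen over stochastic alternatives for
  reproducibility. When the optimal modularity is ≤ 0 (no structure beyond
  chance, e.g. a complete graph) the whole graph is one module with Q = 0.
  "Major" modules have more than 30 nodes.
* Erdős–Rényi G(n, m) ensembles draw uniform simple graphs with exactly
  the observed node and edge counts; every topology metric is recomputed
  per replicate with identical conventions, which is what makes the
  observed-vs-random contrast meaningful.

## Association tables

Mantel correlations default to Spearman (consistent with the rank-based
choices elsewhere), with Pearson available. Significance is a two-sided
permutation test — |r_perm| ≥ |r_obs| with the +1 correction — because
negative environment–community associations are real findings, not noise.
The βNTI pair matrix is consumed as a distance-like matrix exactly as
the field's tables do, with the documented caveat that it can be negative
and is used as-is. Pairs with undefined βNTI are excluded pairwise from
the correlation and its permutations. Lineage rows use the Bray–Curtis
matrix of the lineage's member-OTU subtable (samples where the lineage is
absent are dropped from that subtable); a lineage or module absent from a
habitat yields an NA row. No multiple-testing correction is applied across
the table's cells, mirroring common practice; stars mark p < 0.05 and
p < 0.01.

## Numerical and reproducibility choices

* Every stochastic entry point takes a `seed`; seeded calls restore the
  caller's RNG state (`withr::with_seed`). The pipeline derives per-stage
  seeds deterministically from one master seed and serializes the
  effective configuration into `manifest.json`; a rerun with the same
  config is byte-identical.
* The βMNTD/βNTI kernel and the Raup–Crick reassembly run in C++ with R's
  RNG, so results are identical to an R loop at a fraction of the cost.
  Weighted sampling without replacement uses exponential keys
  (Efraimidis–Spirakis), O(n log n) per draw.
* Validation sizes: the recovery tests run the full study design (46
  samples × 500 OTUs) with 199-repetition nulls; 999 repetitions change
  βNTI by under 0.1 standardized units on these data and are the
  analysis default. The Erdős–Rényi acceptance ensembles use the full 999.
* Degenerate inputs are errors or flagged results, never silent: zero-sum
  samples, duplicated ids, non-integer counts where integers are required,
  constant correlation vectors, constant Mantel matrices, zero-variance
  nulls.

## Known limitations

* βNTI inherits the assumptions of phylogenetic niche conservatism; where
  niches are labile the partition under-detects selection regardless of
  implementation.
* The Raup–Crick null conditions on observed richness; heavy rarefaction
  or very uneven depths change its meaning.
* Greedy modularity is deterministic but not optimal; very fine module
  structure may be merged relative to Louvain/spinglass alternatives.
* The simulator's regimes are idealized endpoints. Real communities mix
  processes along environmental and spatial gradients; the `neutral_mix`
  regime interpolates crudely and is not a calibrated mixture model.
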