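---
title: "Inferring community assembly processes with phylogenetic and taxonomic null models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring community assembly processes with phylogenetic and taxonomic null models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betanull)
```

## The inference problem

Microbial and viral communities turn over in space for different reasons:
deterministic environmental filtering (selection), limited or overwhelming
dispersal, and pure demographic drift. `betanull` implements the two-stage
null-model framework of Stegen and colleagues that attributes every *pair*
of communities to one of five processes, together with the ordination,
spatial and variation-partitioning statistics that typically accompany it
in marker-gene biogeography studies (e.g. of T4-like cyanophage *g20*
amplicon communities along a shelf-to-open-sea gradient).

The two stages are:

1. **Phylogenetic turnover.** The between-community mean nearest taxon
   distance,
   \[
   \beta\mathrm{MNTD}(k,m) = \tfrac12\Big[\sum_{i\in k} f_{ik}\,
   \min_{j\in m} d_{ij} + \sum_{j\in m} f_{jm}\, \min_{i\in k} d_{ij}\Big],
   \]
   with \(d_{ij}\) the patristic distance between OTUs and \(f\) relative
   abundances, is compared with a null distribution obtained by shuffling
   taxa across the tips of the phylogeny (equivalently, jointly permuting
   the rows and columns of the patristic matrix) while the community table
   stays fixed. The standardized deviate is
   \(\beta\mathrm{NTI} = (\beta\mathrm{MNTD}_\mathrm{obs} - \mu_\mathrm{null})
   / \sigma_\mathrm{null}\).
   \(\beta\mathrm{NTI} > +2\) marks heterogeneous selection (more turnover
   than the null expects), \(\beta\mathrm{NTI} < -2\) homogeneous selection.
   The comparison only carries information when niches are phylogenetically
   conserved — close relatives must have similar environmental optima.

2. **Taxonomic turnover for the stochastic remainder.** Pairs inside the
   \(|\beta\mathrm{NTI}| \le 2\) band are passed to the abundance-informed
   Raup–Crick metric on Bray–Curtis dissimilarities. Null community pairs
   preserve each sample's observed richness (species drawn with probability
   proportional to metacommunity occurrence frequency) and total abundance
   (individuals assigned proportionally to metacommunity relative
   abundance); RC\(_\mathrm{BC}\) is the rank of the observed Bray–Curtis in
   the null distribution, ties at half weight, rescaled to \([-1, 1]\).
   RC\(_\mathrm{BC} > +0.95\) is read as dispersal limitation (acting with
   drift), RC\(_\mathrm{BC} < -0.95\) as homogenizing dispersal, and the
   interior as drift alone. All inequalities are strict; values exactly on a
   threshold fall to the stochastic/drift side.

`classify_processes()` applies this decision table and reports the fraction
of classified pairs per process — the usual stacked-bar summary of such
studies. Pairs whose null SD is zero (e.g. two identical communities) are
reported as degenerate rather than silently coerced to 0, which would bias
the summary toward stochasticity.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_null` | 999 | Null replicates for both models; the framework's convention. At 999 replicates the finest RC resolution is 1/999. |
| `weighted` | `TRUE` | Abundance-weighted betaMNTD; the unweighted variant uses \(1/\)richness weights. The framework is abundance-weighted in its standard form. |
| `bnti_threshold` | 2 | Two null SDs; approximately a two-sided 5% criterion. |
| `rc_threshold` | 0.95 | The conventional \(\pm0.95\) cut on the rescaled rank. |

The null randomization shuffles tip labels across the *whole* harmonized
tree; no within-pool restriction is applied because no pool structure is
assumed for the input. RC\(_\mathrm{BC}\) is computed for all pairs in one
pass (simpler caching and reporting) but consulted only where
\(|\beta\mathrm{NTI}| \le 2\).

## The synthetic-community generator

Every stage of the pipeline is validated by *process recovery*: communities
are assembled under one known process and the inference must label them
accordingly. `sim_scenario()` fixes the study conditions:

* 16 samples, 200 OTUs, \(10^4\) reads per sample — the scale of a small
  amplicon biogeography study (row sums are exact by multinomial closure);
* a lognormal metacommunity (meanlog 0, sdlog 1.5), giving the heavy-tailed,
  "inverted exponential" rank-abundance curve typical of such data;
* niche optima evolved by Brownian motion (rate `sigma_bm = 1` niche
  units\(^2\) per unit branch length) on a birth–death phylogeny, so
  phylogenetic niche conservatism holds by construction;
* selection scenarios filter OTU \(i\) in sample \(j\) with Gaussian weight
  \(\exp(-(o_i - e_j)^2 / 2\sigma_\mathrm{sel}^2)\); heterogeneous selection
  uses two environments at \(\pm 2\) niche units with
  \(\sigma_\mathrm{sel} = 0.5\), a deliberately strong regime in which the
  expected classification is unambiguous; homogeneous selection uses a
  single environment;
* drift inserts an intermediate bottleneck resample of `n_eff` individuals
  per sample; homogenizing dispersal draws every sample from one shared
  pool; dispersal limitation runs a serial founder chain along a
  one-dimensional transect (each community is an `n_eff`-sized resample of
  its predecessor mixed with the metacommunity at rate `migration`), with
  coordinates increasing along the chain.

Samples carry coordinates along a subtropical shelf-to-open-sea transect
(near 18°N, 110–118°E),
the selection environment is exposed as `temperature`, and each generated
bundle stores its truth label. One scenario per dataset — no mixtures — so
recovery tests are exact.

What the generator does *not* emulate: sequencing error, chimeras, PCR and
primer bias, compositional coupling between samples, or any quantitative
property of a real survey (effective metacommunity sizes and selection
strengths are chosen for testability, not to mimic a particular ocean).
Passing recovery tests therefore demonstrates correctness of the inference
chain under its own assumptions, not field performance.

## Numerical choices

* **Degenerate pairs**: null SD below \(10^{-12}\) masks the pair (listed,
  excluded from fractions).
* **RC ties**: null Bray–Curtis values within \(10^{-9}\) of the observed
  count as half; this centres RC\(_\mathrm{BC}\) under its own null (the
  rank-uniformity calibration in the test suite checks exactly this).
* **Subsampling** is without replacement (multivariate hypergeometric per
  sample); a multinomial variant is available behind `replace = TRUE` for
  very large depths. "Singleton" means total count across the dataset equals
  one — per-sample singletons with larger totals are kept.
* **NMDS** minimizes Kruskal stress-1 by monotone regression from a
  principal-coordinates start plus random restarts; the returned stress
  never exceeds the metric start's. Ties receive primary treatment.
* **ANOSIM and Mantel p-values** use the add-one permutation convention and
  are therefore never exactly zero. Mantel tests take an `alternative`
  argument; distance-decay uses `"less"` (a negative association is the
  hypothesis).
* **Partial Mantel** residualizes linearly on the control matrix; the
  Spearman variant rank-transforms all three matrices first. A control
  matrix collinear with either input is refused.
* **Shannon diversity** uses natural logarithms.
* **log(x+1)** transforms of similarity/Euclidean matrices are provided
  where conventional, and documented as rank-neutral: Spearman statistics
  are unchanged by them.

## Ordination, spatial statistics and variation partitioning

Community–environment analysis defaults to CCA (an `rda` switch is
available); detrended correspondence analysis is deliberately not
implemented — its gradient-length heuristic is recorded as an explicit
method switch instead, because detrending-by-segments is
implementation-idiosyncratic and contributes nothing downstream.
Explanatory variables are pruned by iterative VIF elimination (threshold
10). Geographic distances use a spheroidal Earth model by default (WGS84),
a 6371-km sphere or planar coordinates for synthetic data. PCNM spatial
eigenvectors follow the classic construction: distances beyond the
truncation (default: longest minimum-spanning-tree edge) are replaced by
four times the truncation, and eigenvectors with positive eigenvalues are
returned; positive-Moran's-I filtering is not applied by default since no
criterion is assumed.

Three-block variation partitioning runs RDA on Hellinger-transformed counts
with adjusted \(R^2\) (CCA-based partitioning lacks a clean adjusted
\(R^2\) and is not offered; the transform is an argument). A second
community enters as principal-coordinate axes of its Bray–Curtis matrix,
the number of axes chosen by a broken-stick rule unless overridden. The
seven fractions plus the residual always sum to one by inclusion–exclusion;
individual adjusted fractions may legitimately be negative. Pure fractions
are tested by permutation on the corresponding partial RDA.

Water-mass clustering uses partitioning-around-medoids on standardized
temperature and salinity (their units are incomparable), choosing the
number of clusters by maximum average silhouette width.

## The pipeline

`run_pipeline()` chains the stages — harmonization, singleton removal,
subsampling to the minimum sample total, diversity, Bray–Curtis, NMDS,
ANOSIM/SIMPER, VIF-pruned constrained ordination, both null models and the
classification, distance-decay, and PCNM + variation partitioning — and
writes TSV/JSON artifacts plus a manifest recording inputs, parameters and
the per-stage seeds. One global seed expands into per-stage seeds by a
fixed counter scheme (`seed + 1000 * stage`), so identical configs give
byte-identical artifacts and any stage can be re-run in isolation with its
recorded seed. Content-hash caching of intermediates was considered and
dropped: deterministic per-stage seeds plus individually exported stage
functions give the same re-run economics with far less machinery. The
package's functions and this vignette are the intended interface;
`run_pipeline()` with a YAML config covers shell-driven use.

## Problem sizes and test design

The test suite validates the implementation at three scales: exact worked
examples (4-tip trees, 2–3 samples), oracle equivalence against independent
loop-based reimplementations on 50 random instances of up to 8 samples ×
15 OTUs (tolerance \(10^{-10}\)), and process recovery at the study scale
(200 OTUs, 16 samples, \(10^4\) reads, 999 null replicates). Calibration
checks confirm that RC\(_\mathrm{BC}\) is approximately uniform on
\([-1,1]\) for data generated by its own null (Kolmogorov–Smirnov over 500
draws) and that ANOSIM/Mantel permutation p-values are uniform under
independence (200 seeds).

## Known limitations

* **The RC null absorbs part of a true dispersal-limitation signal.**
  Because null communities conserve each sample's *observed* richness and
  the table's occurrence frequencies, a founder chain that collapses
  richness (strong bottlenecks, low migration) raises the null expectation
  of turnover along with the observed turnover. In that regime many distant
  pairs sit at RC\(_\mathrm{BC}\) around 0.5–0.9 rather than beyond +0.95,
  even though the distance-decay Mantel test detects the spatial signal
  decisively. Drift without spatial structure is recovered cleanly. This is
  a property of the richness/occurrence-conserving null itself and users
  should read RC-based dispersal-limitation fractions as conservative.
* betaNTI inherits the usual caveats: it requires genuine phylogenetic
  niche conservatism and an adequately sampled tree; with very similar
  communities the null SD can collapse (such pairs are masked).
* Process attribution is at the whole-community pair level; per-OTU
  (feature-level) attribution is out of scope.
* The geographic model treats coordinates as exact; no depth-aware 3-D
  distances are attempted (depth can enter as an environmental variable
  instead).
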