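---
title: "Methods: community assembly, co-occurrence and spatial analysis of sediment microbiomes"
author: "sedcomm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community assembly, co-occurrence and spatial analysis of sediment microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedcomm)
```

# Scope

`sedcomm` implements the statistical inference chain used in
salinity-gradient studies of estuarine sediment microbiomes: diversity
estimation on rarefied OTU tables, phylogenetic null-model partitioning
of community assembly processes, Spearman co-occurrence networks,
spatial/environmental ordination with variation partitioning, and
nitrogen-cycle functional-gene profiling. A synthetic-data generator
produces gradient-structured communities under four named assembly
regimes so that every downstream method can be exercised — and its
discriminating power checked — without sequencing data.

# The synthetic gradient

The generator's defaults describe a 15-site transect (~300 km) with a
monotone salinity ramp from 0.12 to 35.8 ppt, split into low/mid/high
groups by terciles of the configured range. Tercile cuts on the
*configured* range (rather than on the realized data) keep the 5/5/5
design stable when measurement noise perturbs salinity near a
boundary. Salinity noise defaults to 0.3 ppt — small relative to the
~2.5 ppt between-site increment, as befits replicate field
measurements. Auxiliary sediment variables are generated as simple
functions of salinity plus noise: NH4-N rising, NO3-N falling, TOC
u-shaped (minimum at mid salinity), moisture content rising, the rest
weakly structured. These emulate the correlation structure the
ordination methods assume; they are calibration choices, not estimates
of any real estuary, because field effect sizes for such gradients are
rarely published.

Communities are built in three steps. A Yule (pure-birth) phylogeny
supplies the taxa; Brownian motion along its branches (rate
`trait_sigma`, root fixed at the midpoint of the salinity range so all
niches are reachable) supplies phylogenetically conserved salinity
optima; and a lognormal(0, 1) metacommunity abundance distribution — the
standard neutral baseline for species-abundance data — supplies the
regional pool. Per sample, reads are a single multinomial draw of
`depth` from regime-specific weights:

* **selection** — metacommunity abundance times a Gaussian niche kernel
  `exp(-(trait - salinity)^2 / (2 w^2))`, evaluated in log space so that
  very narrow niches (`w -> 0`) remain well defined;
* **drift** — one shared weight vector; all between-sample variation is
  multinomial sampling;
* **dispersal_limitation** — per-taxon Gaussian-process log-abundance
  fields across sites with covariance `exp(-d / decay_scale)`
  (exponential decay is the simplest mechanism that produces
  distance-decay of similarity);
* **homogenizing** — a mass-effect blend `(1 - m) * local + m * pool`
  with `m >= 0.9`; the local component is sample-specific lognormal
  noise, so the regime is distinguishable from pure drift while the
  shared pool dominates.

The KO-table generator draws negative-binomial counts (size 5, lognormal
baseline means) and multiplies the mean of `n_affected` KOs by `effect`
in one designated group, emulating salinity-structured nitrogen genes.
Gene lengths are uniform on 500–3000 bp; recorded per-sample totals are
25 times the simulated KO reads plus a constant, reflecting that
nitrogen genes are a small fraction of a metagenome.

What the generator does *not* emulate: sequencing error, chimeras,
compositional artifacts of amplification, taxon-specific copy-number
variation, or hydrodynamics. Passing tests demonstrate that the
inference chain recovers the processes it targets under its own model
assumptions — they are internal-consistency evidence, not field
validation.

# Diversity estimators

Alpha diversity follows the classical mothur/QIIME-era index set.
Shannon entropy is reported in nats: on tables with several hundred
OTUs this gives values in the 3–6 range typical of published sediment
surveys, whereas log2 would roughly double them. Simpson is reported as
dominance (`sum p^2`), so the most diverse samples have the *smallest*
values. Chao1 uses the classic form `S_obs + F1^2 / (2 F2)` with the
`F1(F1-1)/2` fallback when doubletons are absent; ACE uses the standard
rare/abundant split at 10 reads with the coefficient-of-variation term,
falling back to Chao1 in the degenerate case where every rare read is a
singleton (ACE's sample coverage is then zero). Good's coverage is
`1 - F1/N`. Rarefaction is a single draw without replacement at a fixed
depth (no averaging over repetitions), seeded and logged; the study
convention of using the minimum sample total (3581 reads in the
motivating design) is the pipeline default.

# Assembly null models

The partitioning follows the two-stage null-model framework standard in
microbial ecology. Between-community mean nearest taxon distance
(beta-MNTD) is abundance-weighted by default; the observed value is
compared to a null distribution obtained by shuffling tip labels across
the whole tree ("taxa shuffle", the framework default; phylogeny-pool
alternatives are out of scope), with 999 randomizations in study
configuration. The z-score is betaNTI; pairs with |betaNTI| > 2 are
deterministic (heterogeneous selection above, homogeneous selection
below), the remainder stochastic. Stochastic pairs are split by the
Raup–Crick metric on Bray–Curtis: null communities preserve each
sample's richness and read total, drawing taxa with probability
proportional to occupancy, seeding each drawn taxon with one read and
allotting the rest multinomially by metacommunity relative abundance.
`RC > 0.95` is dispersal limitation, `RC < -0.95` homogenizing
dispersal, the rest drift. The ±0.95 bound is the framework default and
lives in the configuration, as does the choice to run the null models on
the rarefied table. Ties between null and observed Bray–Curtis count at
half weight, making RC granularity exactly `1/n_reps`. Pairs whose null
standard deviation is zero (e.g. identical communities) have undefined
betaNTI; they are flagged, excluded from partitions and tallied.

Process fractions are reported as percent of classified pairs, with the
three stochastic sub-fractions expressed as percent of *stochastic*
pairs (so they sum to 100 on their own); this is the convention that
makes published triplets such as 57.69/38.46/3.85 internally
consistent.

The all-pairs beta-MNTD kernel is compiled (C++ via Rcpp) because the
randomization loop evaluates it hundreds of times per dataset; the R
surface is unchanged and the kernel is checked against an independent
brute-force implementation and against `picante::comdistnt`.

# Co-occurrence networks

Networks are built on the 100 OTUs with the highest summed relative
abundance (ties broken lexicographically for determinism). Edges are
pairwise Spearman correlations (midrank ties) of relative abundances
with two-sided p-values from the t approximation, kept when
`rho > 0.6` **and** `p < 0.01`. Both thresholds are conjunctive and
uncorrected by default, matching common practice in the field; a
Benjamini–Hochberg switch and an `absolute` switch (admitting negative
correlations) are provided but off by default, the latter because the
positive-only reading is the literal form of the published rule.
Topology metrics: average degree `2E/V`; average path length over
connected pairs only (documented caveat for disconnected graphs);
diameter within the largest component; mean local clustering with
degree-<2 nodes contributing zero; modules by greedy modularity
maximization (deterministic, seeded for form) and Newman Q of that
partition. Modularity and clustering above 0.4 are conventionally read
as evidence of modular structure.

# Ordination, space and variation partitioning

PCoA is classical scaling of `-0.5 D^2` with negative eigenvalues
reported but excluded from explained proportions. NMDS minimizes
Kruskal stress-1 with monotone regression, 20 random starts by default,
300 iterations, tolerance 1e-7, seeded. UPGMA is average-linkage
clustering returned as an ultrametric tree. ANOSIM and the Mantel test
are rank/permutation procedures with the add-one p-value rule.

Geographic distances are haversine on a 6371.0 km sphere. PCNM
truncates the distance matrix at the longest minimum-spanning-tree edge,
replaces larger distances by four times the threshold, and keeps
positive-eigenvalue principal coordinates (floor `1e-8` of the largest
eigenvalue) as multiscale spatial predictors. Linear detrending of the
response on raw coordinates before PCNM is available as an option and
off by default, since published accounts are ambiguous about whether
coordinates are detrended or simply accompany the eigenfunctions.

RDA operates on Hellinger-transformed counts (the standard choice for
species data when the transformation is unstated) with standardized
predictors; CCA uses the chi-square weighting of the raw table.
Per-variable significance is a marginal permutation test (each variable
tested with the others retained) — matching per-variable p-value
reporting; forward selection is deliberately not implemented. Variation
partitioning uses Ezekiel-adjusted R² of the env-only, space-only and
joint RDA models: pure fractions are differences against the joint
model, the shared fraction is the inclusion–exclusion remainder, and
`a + b + c + d = 1` holds to numerical precision. Adjusted fractions can
be slightly negative and are not clamped except for display. On small
designs the pipeline caps the spatial block (default: the 5
broadest-scale PCNM vectors, fewer if needed) so the joint model keeps
positive residual degrees of freedom.

# Nitrogen-cycle profiling

KO read counts are RPKM-normalized
(`reads / (length_kb * total_mapped_millions)`), summed into gene
families and then pathway modules; aggregation is exactly additive and
unmapped KOs are tallied. The packaged KO → family → module map is a
representative default covering denitrification (narG/H, napA/B,
nirS/K, norB/C, nosZ), dissimilatory nitrate reduction (nirB/D,
nrfA/H), assimilatory nitrate reduction (nasA/B, narB, nirA),
nitrification (amoA/B/C–pmoA/B/C, hao), nitrogen fixation (nifD/H/K)
and anammox (hzsA/B/C, hdh — hydrazine dehydrogenase, the gene
sometimes loosely written "Hds" in the literature). Comammox is not a
separate module: its marker genes share K numbers with nitrification
and denitrification (nxrA/B are K00370/K00371, the same as narG/H), and
the map enforces a one-KO-one-family invariant; users needing a
different resolution supply their own map file. Group differences use
the Kruskal–Wallis H test (midrank ties, chi-square approximation) with
an optional Benjamini–Hochberg column; constant features are flagged
degenerate with p = 1.

# Determinism and numerical choices

Every stochastic stage takes a seed; the pipeline derives per-stage
seeds from one master seed via a polynomial string hash, so stages have
decorrelated streams and a whole run is bitwise reproducible (the test
suite checks byte-identical output files across repeated runs). Null
Bray–Curtis ties use a 1e-12 comparison tolerance; zero-length terminal
branches read from newick are replaced by 1e-8 with a warning;
distance-matrix symmetry is enforced at 1e-12. Ranking ties in top-OTU
selection and dendrogram input orderings are broken deterministically.

# Problem sizes used in validation

The packaged checks run the generator at the study design (15 samples,
200 taxa, 10,000 reads per sample, rarefied to 3581) with 199
randomizations per null model and 20 paired seeds for regime-recovery
comparisons, and 200 replicates for permutation-test calibration; these
sizes give stable comparisons while keeping the default validation run
in the minutes range. The null-model replication count is configurable,
with 999 the study-scale setting.

# Known limitations

* The assembly classification inherits the framework's assumptions:
  informative phylogenetic signal in niches, a meaningful regional
  pool, and thresholds (±2, ±0.95) that are conventions rather than
  estimated quantities.
* Bray–Curtis is a semimetric; triangle-inequality violations are
  possible and are recorded, not asserted, in the property tests.
* Average path length on a disconnected graph averages reachable pairs
  only, which flatters fragmented networks.
* The nitrogen map is representative, not exhaustive; real KEGG
  annotations should be supplied for production use.
* The generator's environmental covariates are stylized; tests passing
  on synthetic data do not validate field inference.
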