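# sedcomm

Statistical inference chain for sediment-microbiome biogeography along
environmental gradients — for microbial ecologists analysing OTU
tables, phylogenies, sample chemistry and metagenome-derived KO counts
from estuarine or coastal sediment surveys.

The package covers, end to end:

* **Diversity** — single-draw rarefaction; Sobs, Shannon (nats),
  Simpson dominance, classic Chao1 `S_obs + F1^2/(2F2)`, ACE (rare
  split at 10), Good's coverage `1 - F1/N`; Bray–Curtis dissimilarity.
* **Community assembly** — the two-stage phylogenetic null-model
  framework. Between-community mean nearest taxon distance,
  `betaMNTD(k,m) = 1/2 [ sum_i f_ik min_j d_ij + sum_j f_jm min_i d_ij ]`,
  is z-scored against a tip-shuffle null (999 randomizations at study
  scale) to give betaNTI; |betaNTI| > 2 marks selection. Stochastic
  pairs are split by the Raup–Crick metric on Bray–Curtis
  (`RC = 2[#(null < obs) + 0.5 #(null = obs)]/n_reps - 1`): RC > 0.95
  dispersal limitation, RC < -0.95 homogenizing dispersal, else drift.
* **Co-occurrence networks** — Spearman rho > 0.6 with p < 0.01 on the
  top-100 OTUs by summed relative abundance; average degree, path
  length, diameter, clustering, greedy-modularity modules and Newman Q.
* **Ordination and space** — PCoA, NMDS (stress-1), UPGMA dendrograms,
  ANOSIM, Mantel tests, haversine distances, PCNM spatial
  eigenfunctions, CCA/RDA with marginal permutation tests, and
  adjusted-R² variation partitioning
  (`a = adjR2(joint) - adjR2(space)`, etc., with `a+b+c+d = 1`).
* **Nitrogen cycling** — RPKM normalization
  (`reads / (length_kb x total_mapped_millions)`), aggregation into
  gene families and pathway modules via a packaged (overridable)
  KO map, Kruskal–Wallis group comparison.
* **Synthetic data** — Yule phylogenies, Brownian niche traits,
  a 15-site salinity transect (0.12–35.8 ppt, low/mid/high terciles)
  and communities under four assembly regimes (selection, dispersal
  limitation, drift, homogenizing dispersal), plus group-structured KO
  tables; everything bit-reproducible from one seed.

See `vignettes/sedcomm-methods.Rmd` for the models, assumptions and
numerical choices.

## Worked example

```r
library(sedcomm)

cfg <- simulation_config(n_taxa = 200, n_samples = 15, depth = 1e4,
                         regime = "selection", seed = 7)
run <- pipeline_config(simulate = cfg, rarefaction_depth = 3581,
                       null_model = null_model_config(n_reps = 199),
                       out_dir = "run7", seed = 7)
report <- run_pipeline(run)
print(report)
```

```
sedcomm pipeline report (seed 7)
  15 samples x 200 OTUs rarefied to 3581 reads
  ANOSIM R = 0.9218 (p = 0.001); Mantel r = 0.6700 (p = 0.001)
  CCA axes 1-2: 75.59%; VPA total explained: 0.977
  network: 100 nodes, 1787 edges, avg degree 35.74, modularity 0.377
  assembly partition:
 group n_pairs pct_deterministic pct_stochastic pct_dispersal_limitation
   low      10             40.00          60.00                     0.00
   mid      10             60.00          40.00                    50.00
  high      10              0.00         100.00                     0.00
 total     105             75.24          24.76                    11.54
 pct_homogenizing_dispersal pct_drift
                     100.00      0.00
                       0.00     50.00
                     100.00      0.00
                      65.38     23.08
```

Reading the report: ANOSIM R near 1 says the low/mid/high salinity
groups have almost non-overlapping community compositions; the Mantel r
correlates community and environmental dissimilarity. Under a
selection regime three-quarters of sample pairs fall outside the
|betaNTI| <= 2 band, i.e. the null model attributes their turnover to
deterministic (niche) processes — on a matched `regime = "drift"`
dataset this fraction drops to a few percent. The per-stage TSVs
(alpha diversity, distance matrices, ordination scores, per-pair
assembly labels, network node/edge lists, nitrogen-gene tests) are in
`run7/`, together with `report.json`.

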