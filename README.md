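# mtphylogeo

Phylogeography of mtDNA control-region haplotypes for structured animal
populations, with a formal test of the riverine-barrier hypothesis.

The package is aimed at population geneticists working with aligned mtDNA
haplotype surveys — tens of populations sampled non-invasively, a
~1-kb alignment, and a landscape whose rivers may or may not restrict gene
flow. It implements the complete analysis chain as composable R functions
plus a numbered analysis workflow:

1. **Haplotypes** — collapse per-sample sequences into haplotypes
   (`collapse_haplotypes()`), tally locality-specific vs shared haplotypes.
2. **Distances** — pairwise difference counts and Tamura–Nei (TN93)
   distances with pairwise deletion; within/between-clade summaries with
   net (corrected) means.
3. **Trees and haplogroups** — neighbor-joining with site-bootstrap
   support (`bootstrap_support()`), collapse of branches below 70%
   support, deterministic extraction of haplogroups as maximal supported
   clusters (`extract_clades()`); UPGMA population tree on net distances.
4. **Population statistics** — haplotype diversity
   `h = n/(n−1)(1 − Σp²)`, mean pairwise differences Π, nucleotide
   diversity π = Π/L; distance-based Phi-ST per population pair with
   permutation tests; one-level AMOVA with method-of-moments variance
   components, where difference counts act as squared distances:
   `Phi_ST = σ²_a / (σ²_a + σ²_w)`.
5. **Riverscape** — population centroids, haversine straight distances,
   large-river crossing counts, and the headwater-detoured distance (the
   shortest path that crosses no large river, passing around its upstream
   terminus) computed on a visibility graph.
6. **Barrier inference** — Pearson correlations of Phi-ST with each
   geographic index per site, Kolmogorov–Smirnov normality check, and
   Gaussian-GLM model selection by
   `AIC = n log(2π·RSS/n) + n + 2(k+2)` across straight distance,
   detoured distance, crossings and the straight+crossings model.
7. **Synthetic data** — a seeded landscape-genetics generator
   (`sim_config()`, `simulate_dataset()`) producing clade-structured
   haplotypes (infinite-sites by default), Dirichlet-decay population
   frequencies with an optional river penalty
   `d_eff = straight + β · crossings`, and files in exactly the dialects
   the readers consume — so the entire pipeline runs offline.

## Worked example

```r
library(mtphylogeo)

cfg <- sim_config()                       # study-scale defaults
sim <- simulate_samples(cfg, seed = 1, dir = "results/data")

res <- run_pipeline(
  alignment = "results/data/samples.fasta",
  metadata  = "results/data/metadata.tsv",
  rivers    = "results/data/rivers.geojson",
  cohorts   = "results/data/cohorts.tsv",
  out_dir   = "results/tables",
  exclude_population = "TL2", seed = 1)

res$haplotypes
#> Haplotype table: 35 haplotypes, 7 populations, 136 samples
res$clade_summary
#> Clade distances: between 34.12 +/- 3.67, within 7.79 +/- 0.99 (ratio 4.38)
res$amova_populations
#> AMOVA: Phi = 0.3029, among-stratum variation 30.29%
```

The 136 simulated samples collapse to 35 observed haplotypes; NJ with 1000
bootstrap replicates and 70% collapse resolves the 6 haplogroups the
generator planted, with between-clade divergence ~4.4× the within-clade
level. The AMOVA line says ~30% of molecular variance lies among
populations. Stage by stage the same analysis is available as numbered
scripts:

```sh
Rscript analysis/01_simulate.R            # synthetic field data
Rscript analysis/02_haplotypes_clades.R   # haplotypes, NJ tree, haplogroups
Rscript analysis/03_diversity_structure.R # diversity, Phi-ST, AMOVA, UPGMA
Rscript analysis/04_geography.R           # centroids + geographic indices
Rscript analysis/05_barrier_models.R      # correlations, KS, GLM/AIC
```

which ends with the barrier verdict for the simulated landscape, e.g.

```
KS normality of the 21 Phi-ST values: D = 0.14, p = 0.78
Model ranking (excluded: none): best by AIC = straight (AIC -1.91, n = 21)
Model ranking (excluded: TL2): best by AIC = straight (AIC 2.91, n = 15)
```

— under the default generator rivers are genetically inert (`beta = 0`),
and straight distance duly wins the AIC comparison.

All outputs are plain TSV/Newick/GeoJSON/JSON under `results/`; the run log
records the seed, parameters and input checksums, and rerunning with the
same seed reproduces every file byte for byte.

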