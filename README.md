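# gammapop

Does chemical pollution erode the genetic diversity of river invertebrates?
`gammapop` is an R toolkit for regional surveys that pair **tissue
chemistry** of a sentinel amphipod (*Gammarus pulex* and relatives) with
**microsatellite population genetics** across many sites along several
rivers. It reimplements, as tested and reusable components, the full
analysis chain such studies need:

* **Toxic units from tissue residues.** Measured internal concentrations
  `C^tG` (ng/g wet weight) are converted to an estimated freely dissolved
  water concentration by equilibrium partitioning,

  `C^fd = C^tG / (f_LIPID * D_ow)`,

  with `f_LIPID` the lipid fraction of wet body weight (default 1.34%) and
  `D_ow` the pH-dependent octanol–water distribution coefficient. Toxic
  units `TU_i = C^fd_i / LC50_i` (mean 24/48-h LC50 for the target species,
  *Daphnia magna* fallback) are summed per site under concentration
  addition; sums above 0.01 indicate acute and above 0.001 chronic hazard
  for crustaceans.
* **Per-site diversity.** Observed and Nei-unbiased expected
  heterozygosity, `F_IS = 1 − H_o/H_e`, exact hypergeometric rarefaction of
  allelic richness and private alleles, Monte-Carlo Hardy–Weinberg exact
  tests, Chakraborty/Brookfield null-allele screening, and
  linkage-disequilibrium effective population size (Burrows composite
  disequilibrium with the standard sample-size bias correction and a
  delete-one-locus jackknife CI).
* **Structure and space.** Weir–Cockerham pairwise θ with permutation
  nulls, hierarchical AMOVA (catchment/river/site), Mantel and partial
  Mantel tests of isolation by distance and pollution-difference matrices.
* **Inference.** Random-intercept linear mixed models (river as grouping
  factor) with exact profiled REML/ML, AICc all-subsets selection
  ("dredge"), and recursive path models with standardized direct, indirect
  and total effects.
* **Synthetic studies.** A forward Wright–Fisher stepping-stone simulator
  generates complete bundles — genotypes, chemistry, LC50 records,
  metadata, waterway distances, ground truth — emulating a 3-catchment,
  6-river, 34-site survey in which pollution rises below wastewater
  treatment plants and intensifies local drift.

## Worked example

```r
library(gammapop)

## a complete synthetic study: 34 sites, 6 rivers, 16 loci
sim <- simulate_study(sim_config(), seed = 7)

## toxic units from tissue chemistry
tu <- toxic_units(sim$bundle$tissue, sim$bundle$compounds, sim$bundle$lc50)
summary(tu$per_site$sum_tu)
#    Min.  1st Qu.   Median     Mean  3rd Qu.     Max.
# 0.0001431 0.0012388 0.0132072 0.0308704 0.0362541 0.1730287

## rarefied allelic richness declines with pollution-driven drift
ar <- rarefied_allelic_richness(allele_counts(sim$dataset, "site"))
cor(ar$mean[sim$truth$site_id], sim$truth$pollution, method = "spearman")
# [1] -0.499

## differentiation follows the river network
fst_river <- fst_matrix(sim$dataset, "river")
round(fst_river$matrix[1:3, 1:3], 3)
#       R1    R2    R3
# R1 0.000 0.112 0.350
# R2 0.112 0.000 0.365
# R3 0.350 0.365 0.000

fs <- fst_matrix(sim$dataset, "site")
wd <- sim$bundle$distances$values[rownames(fs$matrix), rownames(fs$matrix)]
mantel(fs$matrix, wd, n_perm = 199, seed = 1)
# Mantel r = 0.9084, p = 0.005 (greater, 199 permutations)
```

The summed toxic units span the below-chronic (<0.001) to acute (>0.01)
range across sites; allelic richness correlates negatively with the latent
pollution score because polluted demes drift at reduced effective size; and
pairwise θ increases with waterway distance (isolation by distance), with
rivers strongly separated.

The full pipeline — toxicity, diversity, structure, association models,
delimited outputs plus a YAML run-metadata sidecar — runs from a config:

```r
generate_study(sim_config(), seed = 7, out_dir = "bundle")
res <- run_pipeline(pipeline_config("bundle", "results", seed = 7,
                                    permutations = 999))
```

A command-line front end with `simulate | tu | diversity | fst | mantel |
models | run` subcommands is installed at `inst/cli/gammapop.R`.

## Vignette

`vignettes/gammapop-methods.Rmd` documents the statistical methods, every
tunable parameter with units and defaults, what the synthetic generator
does and does not emulate, and the numerical choices (tolerances,
boundaries, tie-breaks) made throughout.
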