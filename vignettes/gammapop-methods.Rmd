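---
title: "Methods: pollution burden and population-genetic diversity in river amphipods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pollution burden and population-genetic diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gammapop)
```

# The problem

Regional field surveys of anthropogenic organic micropollutants (AOM) and
sentinel macroinvertebrates ask two linked questions: (1) does genetic
differentiation among sites follow the river network (isolation by
distance) or chemical gradients, and (2) are within-site diversity
parameters — allelic richness, heterozygosity, inbreeding, effective
population size — degraded where pollution is high? `gammapop` provides
the complete analysis chain for such designs: toxic-unit scoring of
tissue chemistry, per-site microsatellite statistics, differentiation and
spatial association tests, and mixed-model / path-model inference, plus a
simulator that generates whole study bundles with known ground truth.

# Toxic units from tissue chemistry

## Model

Internal concentrations integrate exposure over time, so scoring starts
from tissue rather than water chemistry. Equilibrium partitioning links
the lipid-normalized tissue concentration to a freely dissolved
concentration:

$$C^{fd}_i = \frac{C^{tG}_i}{f_{LIPID}\, D_{ow,i}}$$

* `f_lipid` (unitless fraction of wet body weight, default **0.0134**):
  the lipid content predicted for *Gammarus pulex*. The lipid phase is
  assumed to hold effectively all of the body burden.
* `log_dow` (unitless, per compound): log10 of the pH-dependent
  octanol–water distribution coefficient, used as a surrogate for the
  lipid–water partition coefficient. Whether site-specific pH correction
  was applied is up to the supplier of the table; the package takes
  `log_dow` as given per compound.
* **Unit bridge.** `C^tG` is in ng/g wet weight; at tissue density
  1 g/mL, ng/g ≡ ng/mL ≡ µg/L, so `C^fd` is directly comparable with
  LC50 values in µg/L. No hidden factor of 1000 is applied; the worked
  value `freely_dissolved(134, 0.0134, 3) = 10` µg/L documents this.

Toxic units are `TU_i = C^fd_i / LC50_i`, summed per site under
concentration addition. The LC50 for a compound is the arithmetic mean of
all 24 h and 48 h records for the target species; if none exist, the
fallback species (*Daphnia magna* by default) is used; if neither has
records, the compound is excluded and listed in `compounds_skipped` —
absence of toxicity data is a value, not an error. Records at other
durations (e.g. 96 h) are never pooled.

Thresholds (`toxicity_config`): summed or per-compound TU **> 0.01**
flags acute and **> 0.001** chronic hazard for crustaceans. Comparisons
are strict because the thresholds are phrased as levels that must be
*exceeded*; a value exactly at a boundary falls in the band below it.
`log10(sum TU)` is undefined (`NA`) when nothing quantifiable was
detected; not-detected concentrations are stored as 0, never `NA`, so
totals are always well defined.

# Per-site diversity

* **Heterozygosity.** `H_o` is the fraction of heterozygous genotypes;
  `H_e` is Nei's unbiased gene diversity
  `n/(n-1) (1 - Σp² - H_o/(2n))` with `n` the non-missing genotype
  count. `F_IS = 1 - H_o/H_e`. The group-level `F_IS` uses summed
  components, `1 - ΣH_o/ΣH_e` over polymorphic loci, which is stable
  when some loci are nearly monomorphic; monomorphic loci have undefined
  `F_IS` and are excluded from that sum.
* **Rarefaction.** Allelic richness at `g` gene copies is the exact
  hypergeometric expectation `AR(g) = Σ_i [1 - C(N-N_i, g)/C(N, g)]`,
  computed in log space. Private-allele richness multiplies each
  allele's presence probability in the focal group by its absence
  probability in every other group. The default `g` is, per locus, twice
  the smallest per-group count of complete genotypes (so every group can
  contribute); a global override exists. Private alleles are most
  meaningful at river level (sites pooled), the default in the pipeline
  is site level for the diversity table and river level for
  private-allele summaries.
* **QC.** Individuals with more than 20% missing loci are removed first,
  then loci with more than 20% missingness across the retained
  individuals. Individual-first ordering maximizes locus retention; the
  order is configurable and recorded in the removal report.
* **Hardy–Weinberg.** A Monte-Carlo exact test: gene copies are pooled
  and re-paired conditional on allele counts; the p-value is the
  proportion of tables (observed included) with conditional probability
  ≤ the observed one. Requires ≥ 5 genotypes; monomorphic samples return
  `NA`.
* **Null alleles.** Chakraborty's `(He-Ho)/(He+Ho)` and Brookfield's
  `(He-Ho)/(1+He)` are reported raw (negatives are not floored) with a
  conventional 0.2 screening flag. A locus with consistent null-allele
  signal can be excluded from the structure analyses via the pipeline's
  `exclude_loci`; diversity statistics keep all loci.
* **Effective size.** The LD method: Burrows composite disequilibrium
  `Δ` for every allele pair at every locus pair (alleles with frequency
  < `pcrit = 0.05` screened out; at diallelic loci one allele is used
  since the dosages are collinear), `r² = Δ²/(p(1-p)q(1-q))`, weighted
  mean across comparisons, sampling expectation `E[r²] = 1/S + 3.19/S²`
  for `S ≥ 30` (small-sample variant below), and inversion to `N_e`
  under random mating. Excess LD ≤ 0 yields `Inf` — "no drift signal
  detectable", not an error. The CI is a delete-one-locus jackknife on
  mean r², transformed to the `N_e` scale. The "alpha < 0.05" setting of
  the conventional tool chain is interpreted as this allele-frequency
  screen; the jackknife confidence level is a separate `conf` parameter.

# Differentiation and spatial association

* **θ (F_ST).** Weir–Cockerham variance components `a`, `b`, `c` per
  allele per locus, summed before the ratio. Slightly negative θ is
  reported as computed. The all-pairs matrix is built from per-locus
  sufficient statistics (allele frequencies, heterozygote frequencies,
  sample sizes), which is algebraically identical to the per-pair
  computation and two orders of magnitude faster.
* **Permutation significance.** Multilocus genotypes (whole individuals)
  are the exchangeable unit, permuted between the two groups;
  `p = (1 + #{θ* ≥ θ})/(1 + n_perm)` never reaches 0. A loci-permutation
  mode is retained behind `unit = "loci"` for comparability with
  analyses described as permuting loci; individuals are the
  statistically defensible unit and the default.
* **AMOVA.** Squared distance = number of allele differences summed over
  loci (rescaled over loci scored in both individuals, so missing data
  are tolerated). Three levels with unbalanced-design coefficients.
  Permutation schemes per level: individuals anywhere (`Φ_ST`),
  individuals within groups (`Φ_SC`), whole populations among groups
  (`Φ_CT`). With few populations per group the `Φ_CT` null has few
  distinct states and its p-value is coarse — a design limit, not a bug.
* **Mantel / partial Mantel.** Pearson correlation of lower triangles;
  simultaneous row/column permutation of one matrix; one-sided positive
  by default (the isolation-by-distance direction), two-sided available.
  The partial test correlates residuals of `A ~ C` and `B ~ C`
  (Smouse–Long–Sokal), re-residualizing the permuted matrix. An
  exhaustive mode enumerates all `n!` relabelings for `n ≤ 7` and is the
  oracle for the Monte-Carlo path. Pollution-difference matrices use
  `|log10(total_i) - log10(total_j)|` by default (totals span orders of
  magnitude); quantities already on a log scale (log summed TU) use the
  identity transform.

# Mixed models and path models

The LMM is `y = Xβ + Zu + e` with a single random intercept (river). The
variance ratio `λ = σ_u²/σ²` is profiled: Brent search on `log λ`
followed by secant refinement on the analytic gradient, giving
closed-form agreement (balanced one-way REML = ANOVA estimators) to
better than 1e-12; the boundary `λ = 0` is always a candidate, where the
fit collapses to OLS. Model comparison uses ML likelihoods (REML
likelihoods are not comparable across fixed-effect structures); reported
coefficient tables use REML. `AICc = -2logL + 2k + 2k(k+1)/(n-k-1)` with
`k` counting fixed effects plus both variances. p-values use t statistics
with `n - k_fixed` residual degrees of freedom — approximate, as is
conventional for such tables, and documented as such. `dredge_lmm` fits
all fixed-effect subsets (intercept always retained) on the complete
cases of the global model so every candidate sees the same data, ranks by
AICc, reports models with ΔAICc < 5, and always keeps the intercept-only
model among the candidates so "nothing beats the null" is a visible
outcome. Sites lacking tissue chemistry are dropped before fitting.

Path models are recursive systems over observed variables, which are
just-identified: per-equation least squares on standardized variables
coincides with the GLS/ML covariance fit, so no iterative estimation is
used. Direct effects are the standardized coefficients; total effects
come from `(I - B)^{-1} - I`; indirect = total − direct. The pipeline's
default structure is `TU ← Tot`, `Abundance ← Tot`,
`AR ← Tot + TU + Abundance + Distance`, using tissue totals (a water
variant is possible by supplying water totals — the literature is not
unanimous about which matrix the global model used, so both are
supported and tissue is the default).

# The synthetic generator

`simulate_study()` emulates the survey design: 3 catchments × 2 rivers,
34 sites (5–6 per river), 16 microsatellite loci, 20–30 genotyped
individuals per site (the genotyping protocol's range), with the leading
1–2 sites per river upstream of any wastewater treatment plant (≈ 8
reference sites).

* **Pollution.** A latent score in [0, 1] rises gently with distance
  (diffuse run-off) and jumps below each WWTP. Compound concentrations
  are lognormal (sdlog 0.5) around class-specific means scaled by
  `10^{2.5(pollution - 1)}` — a ~300-fold dynamic range so summed TUs
  span below-chronic to acute and log-totals are roughly linear in the
  score. The compound catalogue is synthetic but shaped like
  central-European mixtures: hydrophilic insecticides carry the
  toxicity, bulk industrial/household chemicals the mass, and LC50
  coverage deliberately includes target-species, fallback-only and
  no-data compounds.
* **Genotypes.** Founder frequencies per catchment from a symmetric
  Dirichlet(1) over 8 alleles; catchment pools drift 300 generations and
  river pools another 100 (Ne 500); then each river runs a
  stepping-stone chain for 150 generations with adjacent-site migration
  `m = 0.03` and site-specific `Ne = 150·exp(-1.2·pollution)` (45–150),
  stepwise mutation `µ = 5e-4`. These values were fixed once to
  reproduce the field scales reported for such surveys — between-river θ
  far above within-river θ, within-river θ up to ≈ 0.1, ~8–9 alleles per
  locus, F_IS reaching ≈ 0.2–0.4 at disturbed sites, LD-N_e in the tens
  to low hundreds — and are not tuned against test outcomes.
* **Wahlund substructure.** Sites above pollution 0.6 carry a hidden
  deme contributing `w = 0.2` of sampled individuals. The deme splits
  off its site deme 40 generations before sampling and then drifts
  unconnected: recent enough to import essentially no novel alleles,
  long enough (≈ 0.3 of a coalescent unit at the eroded Ne) to diverge
  frequencies and depress heterozygosity in the mixed sample. An
  isolated-since-founding deme was rejected because it inflates allelic
  richness at polluted sites, contradicting the emulated pattern of
  jointly reduced richness and elevated inbreeding. Selfing was rejected
  as biologically unavailable to amphipods.
* **Distances.** Cumulative kilometres within a river; rivers of a
  catchment join at a confluence below their last sites; catchments
  connect only through a 150 km main stem.

**What a green test establishes — and what it does not.** The generator
produces drift, migration, substructure and pollution effects with known
truth, so recovery tests validate estimator implementations and the
directional logic of the analysis chain. It does not emulate selection at
linked loci, genotyping artefacts (allele dropout, stutter), null
alleles, temporal variation in chemistry, or chemistry-to-mortality
mechanisms; effect sizes are phenomenological. Agreement with the
generator is therefore necessary, not sufficient, for field validity.

# Numerical choices

* Rarefaction binomials in log space (`lchoose`) — exact to ~1e-15 even
  at the largest survey sizes.
* Permutation p-values use the add-one estimator everywhere except the
  exhaustive Mantel mode, where the exact enumeration proportion
  (identity included) is returned.
* LMM profile: Brent on `log λ` over e^±30, then secant on the analytic
  gradient; explicit λ = 0 comparison; ties at the boundary resolve to 0.
* θ denominators of 0 (no usable variation) yield `NA`, not 0.
* HWE table probabilities are compared with a 1e-12 slack so ties count
  as "at least as extreme".
* GenePop: a zero half-call (`001000`) is read as a whole missing call —
  half-missing genotypes are not representable.
* Seeds: every stochastic routine takes one; the pipeline derives all
  stage behaviour from a single config seed and reruns are
  byte-identical.

# Known limitations

* `F_CT` p-values are coarse when groups contain few populations (small
  permutation space).
* LD-N_e assumes unlinked loci, random mating and closed demes;
  migration and the Wahlund mixture bias it downward at structured
  sites — at such sites the estimate is a local, not census-scale,
  quantity.
* Fixed-effect p-values use a residual-df t approximation, not
  Satterthwaite/Kenward-Roger.
* The AMOVA top level defaults to river (the level with replication in
  the emulated design); catchment-level decomposition is available but
  weakly identified with 3 catchments.
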