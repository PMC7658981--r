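# corediv

Phenotypic diversity, trait repeatability and core-collection inference for
perennial germplasm.

`corediv` is built for breeders and genebank curators characterizing in-situ
sampled tree collections from raw field measurements. Its reference use case
is the miracle berry *Synsepalum dulcificum*, sampled as 203 accessions from
seven populations across two West African ecological regions — the Dahomey
Gap (DG) savannah corridor and the Upper Guinea (UG) rain-forest block —
with fruit traits measured on replicate 10-fruit bulks. The package covers
the full chain from raw tables to a quality-evaluated core collection, plus
a seeded synthetic-germplasm generator so the whole chain can be exercised
and validated without field data.

## What it computes

* **Trait derivation** — nine analysis traits per accession from raw
  measurements: DiamGr = C/π, PlHgt, CrDiam (mean of two directional
  measures); AvFM, AvSM (replicate-mean bulk mass / 10),
  EdRt = (FM₁₀ − SM₁₀)/FM₁₀ (replicate mean, in %); AvFL, AvFW,
  FrSh = AvFL/AvFW.
* **Diversity statistics** — descriptive summaries (n, min, max, mean, SD,
  CV%); habitat/population effects with a Shapiro–Wilk-gated choice between
  Welch-t/ANOVA and Mann–Whitney/Kruskal–Wallis; DG-vs-UG linear contrasts;
  Pearson/Spearman correlation matrices; standardized major axis (SMA)
  allometry with sequential common-slope (likelihood ratio) and
  elevation-shift (Wald) tests between regions.
* **Multivariate structure** — Hopkins clustering tendency
  (H = Σw/(Σu+Σw); low = clusterable), correlation-matrix PCA with
  retention policies, Ward clustering on retained components with
  inertia-gain k selection and k-means consolidation, v-test cluster
  profiles, cluster-by-region χ².
* **Repeatability** — adjusted repeatability
  R = σ²_among/(σ²_among + σ²_within) of replicate-measured fruit traits
  from an exact profiled REML fit of the random-intercept model with
  population as fixed effect; parametric-bootstrap SE/CI; boundary-corrected
  likelihood-ratio test; logit-scale handling of the edible ratio.
* **Core collection** — Gower distances, core selection maximizing the
  average entry-to-nearest-entry distance
  E-NE(S) = (1/|S|) Σ_e min_{e'≠e} d(e,e') by seeded multi-restart
  steepest-ascent swaps (default 20% intensity: 203 → 41 entries), and the
  CR/VR/VD/MD quality statistics with whole-vs-core trait tests.

The methods vignette (`vignettes/corediv-methods.Rmd`) documents every
model, default and numerical choice.

## Worked example

```r
library(corediv)

col <- generate_collection(germplasm_config(seed = 2026))
col
#> Synthetic germplasm collection
#>   accessions:       203 (7 populations, regions: DG/UG)
#>   fruit bulks:      609 replicates of 10 fruits
#>   fruit dimensions: 1015 measured fruits

tm <- derive_traits(col$accessions, col$fruit_bulks, col$fruit_dimensions)
describe_traits(tm)
#>    trait   n    min    max   mean      sd    cv
#> 1 DiamGr 203  0.767 53.209 20.079 10.0320 49.96
#> 2  PlHgt 203  0.285  6.929  3.564  1.2788 35.88
#> ...
#> 6   AvFM 203  0.481  1.761  1.100  0.2879 26.17
#> 8   EdRt 203 54.777 77.968 66.274  4.3378  6.55

long <- trait_replicates(col, "AvFM")
repeatability_estimate(long$y, long$accession_id, long$population,
                       n_boot = 200, seed = 1, trait = "AvFM")
#> Repeatability of AvFM: R_adj = 0.877 (SE 0.013, 95% CI [0.848, 0.899]), LRT p = 3.77e-141

core <- select_core(gower_distances(tm), seed = 1)
core
#> Core collection: 41 entries, E-NE objective = 0.16200 (9 local-search steps)

evaluate_core(tm, core$ids)
#> Core-quality statistics (aggregates over 9 traits):
#>     CR     VR     VD     MD
#>  97.34 123.92  33.41   2.68
```

Reading the numbers: the generator reproduced the study design (203
accessions, 3 × 10-fruit bulks, 5 measured fruits each); fruit mass came
back with repeatability 0.877 against a generating target of 0.883 —
strongly heritable in the broad sense; the 41-entry core retains 97.3% of
every trait's range (CR), inflates the per-trait CVs to 124% of the whole
collection's (VR — a core should over-represent spread), and shifts trait
means by only 2.7% (MD). `run_pipeline()` executes the same chain end to
end, writing one CSV per stage and a JSON manifest of seeds, method choices
and file hashes.

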