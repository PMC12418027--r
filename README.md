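# cytoniche

Climatic niche comparison and ploidy-aware variant filtering for
cytotype delimitation.

## What this is for

Splitting a diploid species out of a widespread polyploid (here modeled
on a diploid, 2n = 32, segregate of a tetraploid, 2n = 64, *Cyclocarya*)
rests on three computable lines of evidence, and this package implements
all of them as one tested R pipeline:

1. **Climatic niches.** Occurrence records are deduplicated by
   great-circle distance (haversine, 1-km default), bioclim-style raster
   layers are sampled at the points, collinear predictors (|r| > 0.8)
   pruned, the rest z-scored and projected to a 2-D PCA niche space.
   Gaussian-KDE density grids (100 × 100) per species yield

   - Schoener's overlap  D = 1 − ½ Σ |p₁ − p₂|,
   - standardized Levins' breadth  B = (1/Σp² − 1)/(n − 1),
   - 50% highest-density isopleths, and
   - a one-tailed permutation test (label reshuffling, add-one
     corrected p) for whether observed overlap is lower than expected.

2. **Morphometrics.** Wilcoxon rank-sum and Welch t comparisons of trait
   tables, leaflet-pair contingency tables, and a determination-key
   classifier over leaflet counts, stamen counts, flower diameters and
   flowering phenology (character overlaps abstain; contradictions are
   "ambiguous").

3. **Neutral markers.** A ploidy-aware VCF filter cascade — depth window
   [mean/3, 2·mean], CDS ± 2 kb and TE exclusion, ploidy-aware singleton
   removal, 20-kb spacing — plus 1000-bp/20-kb fragment sampling for
   species-tree input, Dxy over allele copies of arbitrary ploidy, and a
   mixed-ploidy STRUCTURE writer (diploids padded with −9 rows).

A seeded synthetic-data module generates occurrences, environmental
rasters (ESRI ASCII grid), trait tables and mixed-ploidy VCFs with known
ground truth, so the entire chain is testable offline. See the vignette
`vignettes/cytoniche-methods.Rmd` for the models, defaults and design
decisions.

## Worked example

```r
library(cytoniche)

## two-cytotype synthetic scenario: broad tetraploid vs narrow diploid
sim <- simulate_occurrences(niche_sim_config(seed = 7))
res <- run_niche_pipeline(sim$occ, sim$layers, replicates = 1000, seed = 7)
res$overlap
#> Schoener's D = 0.075 (p = 0.000999, 1000 permutations)
#> Levins' B: C. paliurus = 0.196, C. serrata = 0.066
```

The two niches barely overlap (D = 0.075 on the shared grid; D = 1 would
be identical niches), the tetraploid's niche is about three times
broader (B 0.196 vs 0.066), and no permuted labeling of the pooled
scores produced an overlap as low as the observed one
(p = 1/1001 ≈ 0.001).

```r
## ploidy-aware neutral-SNP filtering with generator ground truth
vsim <- simulate_variants(variant_sim_config(seed = 7))
flt <- run_variant_pipeline(vsim$vm, vsim$cds, vsim$te)
flt$report
#>       stage n_input n_removed n_survivors
#> 1     depth    5000       400        4600
#> 2    region    4600      2989        1611
#> 3 singleton    1611       242        1369
#> 4   spacing    1369      1241         128
```

Each row is one cascade stage; the survivor counts equal the generator's
independent bookkeeping exactly (`vsim$truth`), and the 128 survivors are
mutually ≥ 20 kb apart, outside genic/TE regions, inside the depth
window, and free of singletons.

```r
## determination key
classify_specimen(leaflets = 12, stamens = 19, diameter_mm = 3.5)$species
#> [1] "C. serrata"
classify_specimen(leaflets = 9)$species   # 9 sits in both key ranges
#> [1] "ambiguous"
```

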