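# ravinehab

Range-wide habitat modeling and conservation gap analysis for
stream-breeding insects of dissected ravine landscapes — dragonflies whose
nymphs develop in first- and second-order forested seepage streams incised
into sandy uplands, and whose adults forage in the open-canopy terrestrial
matrix around them.

The package implements the complete analysis chain as tested, reusable R
code, and ships a synthetic-landscape generator with a known suitability
truth so that every stage is verifiable end to end without any external
data.

## What it does

1. **Terrain and hydrology** — slope and topographic position index over
   circular focal windows; 10-class geomorphon landform classification
   (ternary line-of-sight patterns in 8 directions); depression-filled D8
   flow routing; extraction of Strahler order 1–2 headwater flowlines from
   a flow-accumulation threshold; and a five-rule artifact-cleaning cascade
   (waterbody interiors, straight "sunburst" artifacts, distance to a
   reference network, valley-landform + woody-wetland context, isolated
   short fragments).
2. **Occurrence processing** — deduplication, downslope snapping of adult
   records to the nearest not-higher stream reach within 300 m, and spatial
   thinning to one record per reach with nymphs preferred.
3. **Covariates** — the 12-layer stack (slope, TPI, landform, soil
   conductivity/pH/% sand, distance to streams, distance to open-canopy
   terrestrial cover, % developed and % agriculture per subwatershed, March
   temperature and precipitation), collinearity screening (Pearson r and
   ANOVA correlation ratio η), focal-radius selection by weight-of-evidence
   information value, and relative land-cover-change accounting.
4. **Maxent engine (from scratch)** — the presence–background maximum
   entropy model as an L1-regularized convex program:

   minimize over λ:  −mean_presence(f·λ) + log Σ_background exp(f·λ) + Σ_j rm·β_j·|λ_j|

   with linear/quadratic/product/hinge/categorical features scaled to
   [0, 1], bias-matched background sampling (landform classes 6–10,
   exp(−d_road/τ) road weighting), cloglog output
   1 − exp(−e^H·raw), AICc model selection, and k-fold cross-validation.
5. **Evaluation** — ROC/AUC (Mann–Whitney), equal-sensitivity/specificity
   threshold, TSS, SEDI, accuracy, permutation importance, percent
   contribution, response curves.
6. **Habitat delineation** — binary threshold → upper Jenks natural-breaks
   class (exact two-class Fisher partition) → isolated-patch screen →
   urban-embedded screen → 500-m terrestrial extension over open-canopy
   evergreen/shrub/herbaceous cover.
7. **Gap analysis** — protected-area coverage, adjacent plantation /
   agriculture / development exposure in a one-cell ring, and projected
   urbanization threat split at 50% probability, per region and in total.

All rasters are plain-text ESRI ASCII grids (no binary dependencies);
vector outputs are CSV/JSON.

## Worked example

```r
library(ravinehab)

w   <- generate_world(world_config(size = 300, seed = 42))
res <- run_pipeline(w, seed = 1,
                    params = pipeline_params(accum_threshold = 25,
                                             n_background = 4000,
                                             k_folds = 10),
                    verbose = TRUE)
#> flowlines: 1259 raw -> 118 cleaned segments
#> occurrences: 211 in -> 211 clean -> 127 snapped -> 63 thinned
#> occurrences: 63 retained on 63 reaches
#> model data: 63 presences, 4000 background
#> evaluation: test AUC 0.864 (excellent), TSS 0.56, SEDI 0.72
#> habitat: breeding 5.81 + terrestrial 8.46 = 14.27 km^2

print(res$gap)
#> breeding: 5.81 km^2, 26% protected, 10% of unprotected projected developed
#> terrestrial: 8.456 km^2, 13% protected, 25% of unprotected projected developed
#> combined: 14.27 km^2, 18% protected, 20% of unprotected projected developed
```

Reading the log: 211 simulated records collapse to 63 presences after
cleaning, snapping and one-per-reach thinning; the cross-validated model
separates presences from bias-matched background with a held-out AUC of
0.864; the refinement cascade plus the 500-m terrestrial extension yields
a 14.3 km² habitat model, of which 18% falls inside protected areas and
20% of the unprotected balance is projected to urbanize.

Published-table arithmetic works directly from scalar inputs:

```r
g <- gap_arithmetic(habitat_km2 = 2731, protected_km2 = 819,
                    projected_km2 = 956)
round(c(g$protected_pct, g$unprotected_km2,
        g$projected_pct_of_unprotected, g$projected_pct_of_habitat))
#> [1]   30 1912   50   35
```

(30% of the 2731 km² habitat model is protected; 956 of the 1912 km²
unprotected balance — 50%, or 35% of all habitat — is projected to be
developed.)

## Command line

```sh
Rscript inst/scripts/ravinehab-cli synth  config.yaml   # write a world bundle
Rscript inst/scripts/ravinehab-cli all    config.yaml   # full pipeline
```

where `config.yaml` sets at least `seed` and `out_dir` (any
`pipeline_params()` field may be overridden).
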