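# dfrfa — coupled dynamic factor and random forest analysis of vegetation time series

`dfrfa` is an R package for landscape ecologists and remote-sensing
analysts who want to separate the *continuous, regional* drivers of
vegetation greenness from the *discrete, local* ones. It implements a
three-part pipeline over monthly NDVI rasters:

1. **Dynamic factor analysis (DFA).** Polygon-mean NDVI series
   (polygons = 50-mm mean-annual-precipitation bands × catchments) are
   modeled as

   y_t = μ + Γ α_t + D x_t + ε_t,  ε_t ~ N(0, diag(R)),
   α_t = α_{t−1} + η_t,  η_t ~ N(0, I_M),

   where x_t are monthly environmental covariates (precipitation,
   temperature, soil moisture, PET, fire) and α_t are M random-walk
   common trends. The model is fitted by EM with a Kalman smoother
   (sequential updates, so missing months are skipped, not imputed),
   under the standard identifiability constraints (zero upper triangle
   of Γ, non-negative diagonal), with AIC-based model selection.

2. **Residual trend surface.** Every pixel's residual series
   d(i,t) = NDVI_obs(i,t) − NDVI_pred(polygon(i),t) is tested with the
   seasonal Mann-Kendall test (tie-corrected, continuity-corrected,
   α = 0.1) and sized with the month-wise Sen's slope
   β_i = median{(x_ij − x_ik)/(j − k)}, β = median{β_1 … β_12}.
   Significant positive trends mark **under-prediction** (greener than
   the regional model expects), negative ones **over-prediction**.

3. **Random-forest attribution.** Points sampled from the significant
   classes are explained from discrete covariates (elevation, slope,
   aspect, land cover, soil, country, population, protected areas,
   inundation, distances and buffers for roads/settlements/rivers) with
   a 500-tree random forest; OOB error, permutation (mean decrease in
   accuracy) and Gini importances, and per-class covariate histograms
   describe which covariates drive the divergence. The two stages
   combine as `combined = correct + OOB_accuracy · (100 − correct)/100`.

A seeded synthetic-savanna generator (north–south rainfall gradient,
wet-season phenology, planted protected-area and settlement effects with
known ground truth) makes the whole pipeline testable offline; rasters
are read and written as plain-text ESRI ASCII grids and vectors as
GeoJSON.

## Worked example

```r
library(dfrfa)

cfg <- pipeline_config(scene = scene_config(seed = 1))
res <- run_pipeline(cfg)
res$report[c("correct_pct", "under_pct", "over_pct",
             "rf_oob_accuracy_pct", "combined_explained_pct")]
#> $correct_pct            [1] 72.44
#> $under_pct              [1] 13.64
#> $over_pct               [1] 13.92
#> $rf_oob_accuracy_pct    [1] 86.67
#> $combined_explained_pct [1] 96.33

head(res$report$mda[, c("feature", "importance", "normalized")], 3)
#>           feature importance normalized
#> 1 dist_settlement      0.123      1.000
#> 2  protected_area      0.109      0.882
#> 3 within_1km_settlement 0.065      0.524
```

Reading: the DFA alone reproduces 72.44% of this synthetic landscape's
pixels; 13.64% trend significantly above the regional prediction
(under-predicted — here, the planted protected-area effect) and 13.92%
below it (over-predicted — the planted settlement effect). The forest
explains 86.67% of those divergent points out-of-bag, so the coupled
analysis accounts for 96.33% of the landscape, and the importance
ranking recovers the two planted drivers (settlement proximity and
protected-area membership) at the top.

The same pipeline runs from a shell:

```sh
Rscript $(Rscript -e 'cat(dfrfa::dfrfa_cli_path())') run-all \
    --config config.yaml --seed 1 --outdir out
# [dfrfa] correct 72.44% | under 13.64% | over 13.92% | ...
```

with subcommands `simulate | dfa | trend | attribute | report` for stage-
by-stage runs; see `read_pipeline_config()` for the YAML schema.

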