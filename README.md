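# monkeyhab

Village-development-aware habitat quality modelling for the Yunnan
snub-nosed monkey (*Rhinopithecus bieti*).

The Yunnan snub-nosed monkey survives in high-elevation forest of the Three
Parallel Rivers region of northwest Yunnan, surrounded by thousands of rural
villages whose growth converts and degrades its habitat. `monkeyhab`
implements, as a tested and reusable R pipeline, the analysis chain used to
quantify that pressure:

1. **Village development grading** — PCA on the correlation matrix of 30
   socio-economic indicators, Kaiser retention (eigenvalue > 1), composite
   score `Z = Σ wᵢ sᵢ` with variance-explained weights, seven ordinal grades
   I–VII, and a quartic kernel-density surface of development.
2. **Plot ecological quality** — seven typed forest indices,
   `Y = Σ Wᵢ Xᵢ` with expert weights (0.19, 0.18, 0.17, 0.14, 0.13, 0.13,
   0.06), four grades (lower Y is better), plus an empirical estimator of a
   threat's maximum effective distance from plot–distance correlations.
3. **Habitat degradation and quality** — 12 threat factors (villages by
   grade, roads, cropland, economic forest, construction, other non-forest
   land) radiate influence that decays with distance to the nearest source
   (exponential `exp(−2.99 d/d_max)` or linear, hard cutoff at `d_max`).
   Per pixel of land-cover class j:

       D = Σ_r (w_r / Σw) · i_r · S_jr        (degradation)
       Q = H_j · (1 − D^z / (D^z + k^z))      (quality; k = 0.5, z = 2.5)

   with suitability `H` and sensitivity `S` shipped for the 14 land-cover
   classes, then five quality grades with an area table.
4. **Spatial statistics** — global Moran's I (permutation + analytic
   inference), Getis-Ord Gi\* hot-spot classes, and zonal mean quality over
   monkey-group range polygons.
5. **Synthetic scenes** — a seeded generator (patchy land cover, villages
   driven by a latent development factor, roads, plot grids, group
   polygons) so the whole pipeline is testable without any field data.

All I/O is plain text: ESRI ASCII grids, GeoJSON, CSV, JSON. See the
methods vignette (`vignettes/habitat-quality-methods.Rmd`) for the models,
assumptions, parameter defaults and design decisions.

## Worked example

```r
library(monkeyhab)

cfg   <- scene_config(grid_shape = c(120L, 120L), pixel_size = 100,
                      n_villages = 60L, n_groups = 3L, seed = 42L)
scene <- generate_scene(cfg)
scene
#> <hq_scene> 120x120 land-cover raster, 60 villages, 42 road segments, 36 plots, 3 groups

vs <- village_scores(scene$villages)   # standardize -> PCA -> Z -> grades
attr(vs, "pca")
#> <hq_pca> 1 components retained (eigenvalue > 1) of 30
#>   variance explained by retained set: 94.1%

hq <- habitat_quality(scene$lulc, vs, scene$roads)
hq$area
#>   grade     label area_km2 percent
#> 1     1 very poor     51.8      36
#> 2     2      poor      0.0       0
#> 3     3    medium     28.8      20
#> 4     4      good     26.0      18
#> 5     5 excellent     37.4      26
sprintf("mean habitat quality: %.4f", hq$mean_quality)
#> "mean habitat quality: 0.5236"

units <- aggregate_to_units(hq$quality, 5L)
mi <- morans_i(units$values, spatial_weights(units$adjacency, "row"), seed = 42)
sprintf("Moran's I = %.4f (E[I] = %.4f, permutation p = %.3f)",
        mi$I, mi$expectation, mi$p_perm)
#> "Moran's I = 0.1417 (E[I] = -0.0017, permutation p = 0.001)"

zonal_mean(hq$quality, scene$groups)$groups
#>   group mean_quality n_pixels
#> 1    C1        0.601        9
#> 2    C2        0.715       21
#> 3    C3        0.708       10
```

Reading: on this synthetic scene about a third of the landscape is
very-poor habitat (settlement, cropland and their 1–4 km halos of
degradation), quality is weakly but significantly spatially clustered
(I = 0.14 > E[I] ≈ 0, p ≈ 0.001), and the three simulated monkey ranges —
grown in high-suitability forest — retain above-average quality (0.60–0.72
versus the landscape mean 0.52).

The full pipeline (scores, rasters, hot spots, zonal table, manifest) runs
with:

```r
run_pipeline(pipeline_config("out", scene_config = cfg, seed = 42L))
```

or from the shell via the installed CLI:

```sh
Rscript inst/cli/monkeyhab run --config cfg.json --out out/
```

Reruns with the same config and seed are bit-identical.

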