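# standres

Tree- and stand-level drought-response analysis for mixed mountain forests.

`standres` is for forest ecologists and dendroecologists who work with
long-term thinning experiments: mapped stand inventories remeasured every
few years, tree-ring series from progressively harvested stems, and monthly
climate records. It turns those inputs into the quantities the field uses to
ask *"does stand density, species mixing or management change how trees
weather a drought?"* — and, because the raw data of such experiments are
usually restricted, it ships a synthetic-data generator with known
ground-truth effects so every stage of the analysis can be tested end to
end.

## What it computes

**Growth.** Ring-width series (Tucson RWL, multiple radii per tree) are
averaged per tree, corrected for bark (species-specific bark ~ DBH models),
and converted to annual basal area increment by backwards reconstruction of
inside-bark DBH: BAI(t) = π(r_t² − r_{t−1}²). Stand BAI is the sum over the
trees standing in each year.

**Drought.** Monthly potential evapotranspiration follows Hargreaves,
PET = 0.0023 (Ra/λ)(T + 17.8)√(Tmax − Tmin), with FAO-56 extraterrestrial
radiation Ra. The climatic water balance P − PET, summed over a k-month
window, is transformed through a three-parameter log-logistic distribution
(fitted by unbiased probability-weighted moments) into the standardized
index SPEI = Φ⁻¹(F(D)). The growth-relevant window (by default July at a
5-month scale, i.e. March–July) can be selected by correlation with a
ring-width chronology, and drought years are picked as within-period minima
or by thresholds and classed mild/severe.

**Competition and structure.** A distance-dependent competition index
NI = Σᵢ BAᵢ/dᵢ over neighbors within a radius (default 10 m, selectable by
the R² of BAI ~ NI), per-species shares of NI, Shannon diversity of
basal-area composition, stand basal area, and management covariates
(residual BA, BA removed, interventions, years since last thinning).

**Drought response.** Lloret indices around each event year with a 2-year
window: resistance Rt = BAI_dr / mean(BAI_pre), recovery
Rc = mean(BAI_post) / BAI_dr, resilience Rs = Rt·Rc — on raw BAI and on
spline-detrended series (50% frequency response at 2/3 of the series
length).

**Models.** Predictors are scaled and centered, screened by pairwise
correlation (|r| ≥ 0.5) and variance inflation (VIF > 2), then every subset
of fixed effects respecting marginality is fitted — linear mixed models with
a plot random intercept at the tree level (ML), ordinary least squares at
the stand level — and ranked by AICc. The best model is reported with
Nakagawa's R²m/R²c (or adjusted R²) and per-predictor effect sizes: the
variance of each term's partial predictor over the total model variance.

## Worked example

```r
library(standres)
cfg <- pipeline_config(synthetic = list(n_sites = 2), seed = 3)
res <- run_pipeline(cfg)

res$events
#>   year      spei  class
#> 1 1984 -1.603970 severe
#> 2 1998 -1.412634   mild
#> 3 2003 -2.160361 severe
#> 4 2011 -1.479786   mild

subset(res$tables$coefficients, class == "severe" & response == "resistance")
#>  level  class   response        term estimate     se stars   r2m   r2c
#>   tree severe resistance (Intercept)  -0.8376 0.0213   *** 0.475 0.477
#>   tree severe resistance  speciesfir   0.5155 0.0262   *** 0.475 0.477
#>   tree severe resistance        spei  -0.0363 0.0129    ** 0.475 0.477
```

The generator embedded two mild and two severe drought years in the climate;
the pipeline re-identified all four from SPEI alone. The selected tree-level
model says fir's log-resistance under severe drought is 0.52 higher than
spruce's (the generator made spruce more drought-sensitive), and the species
term carries most of the explained variance:

```r
subset(res$tables$effect_sizes, class == "severe" & response == "resistance")
#>  level  class   response    term effect_size
#>   tree severe resistance species      0.4650
#>   tree severe resistance    spei      0.0095
```

Kruskal–Wallis confirms severe events depress resistance relative to mild
ones (`res$comparisons$resistance`: H = 359.3, df = 1, p < 1e-79).

Writing intermediates and a manifest: `run_pipeline(cfg, out_dir = "run1")`
persists every stage as tab-delimited tables plus `manifest.json` (seeds,
parameters, md5 digests); identical configuration and seed reproduce the
manifest byte for byte.

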