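# catselect

Trait-based inference of prey-selection mechanisms from stomach-content
data.

## The problem

Along a gradient in predator body size, food webs show recurring structure:
larger predators consume more prey, larger prey, and prey of higher trophic
level. Three non-exclusive mechanisms can generate these patterns —
**energy demand** (M1: consumption rate rises with body size, independent
of prey traits), **gape limitation** (M2: small predators cannot ingest
large prey; the constraint relaxes with size), and **optimal foraging**
(M3: preference shifts toward prey with higher energy reward as predators
grow). Any subset may act at once, giving seven competing hypotheses
H1 = {M1} … H7 = {M1, M2, M3}.

`catselect` is for ecologists with stomach-content data — one count per
(predator individual, prey item) — plus predator standard lengths and two
prey traits (body size, trophic group: primary producer,
herbivore/detritivore, or carnivore). It determines which mechanism
combination the data support.

## The method

Predators are binned into equal-count body-size classes (default 31 per
class; 619 individuals give 20 classes with 30 in the largest). Two
complementary analyses follow:

**Diet-weighted means (DWM).** For each class,
`DWM = Σᵢ pᵢ · traitᵢ`, with `pᵢ` the relative abundance of prey item *i*
in the class diet — the diet analogue of the community-weighted mean.
Trends of the DWM along class mean length (OLS `R²` and *p*) describe how
prey-trait representation changes with predator size.

**CATS regression.** A community-assembly-through-trait-selection model:
the class × item counts `n_ci` follow a Poisson mixed regression

```
log E[n_ci] = log(π_i) + x'_ci β + u_c + v_i
```

where `π_i` is the pooled relative frequency of item *i* across all classes
(a "prior abundance" offset, so β measures selection *relative to
availability*), the fixed effects cross predator size (linear + quadratic,
standardized) with prey log-size and trophic group, and `u_c`, `v_i` are
size-class and prey-item random intercepts. The model is fitted by a
Laplace-approximation Poisson mixed-model fitter (penalized IRLS inner
loop in C++, deterministic outer search over the variance components).
Nested models are compared by AIC, Akaike weights and Wilks' likelihood
ratio tests; fitted **selection curves** (the trait-dependent part of the
linear predictor along predator size, per trophic group at the 0.05 / 0.5 /
0.95 prey-size percentiles) plus the model-selection evidence are
classified into the H1–H7 verdict.

A synthetic stomach-content generator with separately switchable M1/M2/M3
components (scenario presets `"H1"`–`"H7"`) makes every stage testable
without field data; generating-scenario recovery experiments back the
verdict thresholds. See the vignette in `vignettes/cats-prey-selection.Rmd`
for the model, the generator and every numerical convention.

## Worked example

Simulate the all-mechanisms scenario at the study design (619 predators of
4 species, 20 size classes of 31, 60 prey items) and run the complete
pipeline:

```r
library(catselect)
report <- run_pipeline(pipeline_config(preset = "H7", seed = 42,
                                       ladder = "standard"))
print(report)
#> CATS prey-selection report
#>   20 size classes, 60 prey items, total count 35180
#>   count-size correlation r = 0.905 (p = 4.16e-08)
#>   full model AIC 7397.43, weight 0.269; pseudo-R2 0.775 (dev) / 0.932 (corr)
#> Mechanism support:
#>   M1 energy demand:   TRUE (class-RE dAIC = 746.20, r = 0.91, p = 4.16e-08)
#>   M2 gape limitation: TRUE (3/3 groups small-prey pref, quad dAIC = 38.52)
#>   M3 optimal foraging:TRUE (producer inversion: TRUE, peak ordering: FALSE)
#>   hypothesis: H7

print(report$dwm_trends, digits = 3)
#>               trait     level    slope intercept r_squared        p df
#> 1 trophic_frequency  producer -0.00983    0.7365     0.980 1.15e-16 18
#> 2 trophic_frequency herb_detr  0.00287    0.3203     0.721 2.17e-06 18
#> 3 trophic_frequency carnivore  0.00696   -0.0567     0.982 4.61e-17 18
#> 4         body_size       all  0.04244    0.4172     0.994 1.19e-21 18
```

Reading the output: total consumption rises steeply with class size
(r = 0.91) and the size-class random intercept is decisively supported
(ΔAIC ≈ 746) — energy demand. All three trophic groups show small-prey
preference at small predator sizes that weakens with a saturating
(quadratic-block-supported) profile — gape limitation. The producer
size-preference inverts toward large producers at large predator sizes —
optimal foraging. Jointly: hypothesis H7. The DWM trends show producers
dropping out of the diet with predator size while carnivorous prey and mean
prey size increase.

Real data enter the same way through CSV files:

```r
cfg <- pipeline_config(stomach_path = "stomach.csv",     # pred_id,item_id,count
                       predator_path = "predators.csv",  # pred_id,species,standard_length_mm
                       prey_path = "prey_traits.csv",    # item_id,taxon,trophic_group,body_size_mm
                       out_dir = "results")
report <- run_pipeline(cfg)
```

which also writes coefficient / model-comparison / DWM / selection-curve
TSVs, a verdict JSON and a run log.

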