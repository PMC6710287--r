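# harvestsel

Tools for quantifying **harvest-induced selection on behavior** in hunted
wildlife populations, built around the data a GPS-collared brown bear
population provides: hourly relocations, 5-minute accelerometer summaries, a
road network, and per-bear-year harvest fates. The package is aimed at
movement ecologists and wildlife managers who want to ask, with mixed-model
machinery rather than ad-hoc comparisons, *do hunters remove individuals
with particular behaviors?*

## What it computes

From raw telemetry restricted to 1 August - 30 September (the window around
the 21 August hunting-season start) and to bear-years in which the bear was
legally harvestable, three behavioral traits are derived:

* **movement rate** - Euclidean displacement over 1-hour fix intervals (m/h,
  log scale), modeled in the 02:00-12:00 window around the morning
  hunting-risk peak;
* **activity during legal hunting hours** - with SA_h, SA_nh the summed
  accelerometer values inside/outside hunting hours (one hour before sunrise
  to two hours before sunset) and D_h, D_nh the durations,

  index = (SA_h/D_h - SA_nh/D_nh) / (SA_h/D_h + SA_nh/D_nh)  in [-1, 1];

* **distance to road** - daily mean distance to the nearest road (log m),
  with road density (km/km^2) in the bear-year's 100% minimum convex polygon
  as covariate.

Each trait is related, per sex, to two survival proxies - hunting-season
fate and remaining lifespan (years until the bear was harvested) - with
Gaussian additive / linear mixed models carrying bear and bear-year nested
random intercepts and AR1 residual correlation. Candidate sets built
hierarchically over the controls (age, Julian date, hour of day) are ranked
by AICc with a parsimony tie-break, and the best model yields the adjusted
repeatability

    R = S2_bear / (S2_bear + S2_bearyear + S2_residual)

with a boundary-corrected likelihood-ratio p-value. A synthetic telemetry
generator with known ground truth (latent intercepts, variance components,
selection slopes) backs parameter-recovery and sign-recovery tests of the
whole chain.

## Worked example

```r
library(harvestsel)

# a small synthetic population: 12 bears per sex, hunters remove bears that
# use habitat close to roads (negative selection on distance)
cfg <- synthetic_config(n_bears_per_sex = 12, years = 2013:2016,
                        selection_dist = -0.8, seed = 42)
ds <- simulate_dataset(cfg)
report <- run_analysis(ds, sexes = "male")
print(report)
```

```
Analysis report
male   movement  n= 12999 (12 bears, 25 bear-years)  best: controls         R=0.142 (p=0.00494)
       remaining-lifespan beta = -0.0027 [-0.3998, 0.3944]
male   activity  n=  1387 (12 bears, 25 bear-years)  best: controls         R=0.049 (p=0.0778)
       remaining-lifespan beta = -0.0460 [-0.1078, 0.0159]
male   distance  n=  1387 (12 bears, 25 bear-years)  best: null             R=0.118 (p=0.0761)
       remaining-lifespan beta = 0.2796 [0.0110, 0.5482]
```

Reading the distance line: bears that lived longer used habitat farther from
roads (remaining-lifespan coefficient 0.28 on log distance, 95% CI excluding
zero) - the imprint of the negative road selection the generator applied -
and 12% of the residual behavioral variance is among-individual. The
per-family AICc tables and the repeatability object are in the report:

```r
r <- report$results$male$distance
print(r$ranking_lifespan)
```

```
     model k    logLik     AICc     delta selected
1 lifespan 9 -223.5830 465.5556 0.0000000    FALSE
2     null 5 -227.9430 466.0148 0.4592012     TRUE
3    roads 8 -225.3326 466.9763 1.4207309    FALSE
4      age 6 -227.9028 467.9863 2.4307030    FALSE
5 controls 7 -227.7561 469.7536 4.1980422    FALSE
```

(at this small size the parsimony rule prefers the intercept-only model:
the lifespan model fits best but sits within 2 AICc units). Trait tables,
fitted models, prediction curves (`predict_curve`), repeatability with a
permutation option, and CSV/GeoJSON readers and writers for external
datasets (`analyze_dataset`) are all exported; see the methods vignette
(`vignettes/harvest-selection-methods.Rmd`) for the full model description
and design rationale.

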