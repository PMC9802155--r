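# fermrsm

Designed-experiment optimization of microbial fermentation media in R,
with the bioassay statistics used in probiotic strain screening.

Fermentation yield — here, the spore concentration of a *Bacillus
licheniformis* strain isolated from common carp gut in a rice–fish
coculture system — depends jointly on several medium components. After a
one-factor-at-a-time (OFAT) screen picks the components and centers
their ranges, a Box–Behnken design (BBD) probes the region jointly and a
second-order response surface is fitted on coded factors
*x*ᵢ = (actual − center)/step:

Y = β₀ + Σᵢ βᵢxᵢ + Σᵢ<ⱼ βᵢⱼxᵢxⱼ + Σᵢ βᵢᵢxᵢ²

`fermrsm` implements the full workflow as pipeable, data-frame-first
functions:

- **Designs** — factor definitions with exact coded↔actual transforms
  (`rsm_factors()`, `code_value()`), Box–Behnken layouts with replicated
  centers (`bbd_design()`), OFAT winner selection (`select_best_level()`).
- **Fitting** — ordinary least squares for the full quadratic via QR
  (`fit_quadratic()`), with broom-style `tidy()`/`glance()` and
  `predict()`.
- **ANOVA** — partial (Type III) per-term sums of squares by explicit
  nested refits, residual split into lack of fit and pure error from
  replicated runs, F/p per term, R², Adj-R², CV%
  (`anova_quad()`, `fit_statistics()`, `rank_effects()`).
- **Optimization** — stationary-point analysis with Hessian
  classification (`stationary_point()`) and global maximization over the
  coded design cube (`maximize_in_cube()`), reported in g/l, plus
  contour slices (`surface_slice()`, `autoplot()`) and the
  measured-vs-predicted `validation_ratio()`.
- **Bioassays** — DPP-IV inhibition from the four-arm plate scheme
  (`dppiv_inhibition()`), IAA standard curves and quantification
  (`fit_standard_curve()`, `quantify_iaa()`), acid/bile-salt
  `survival_rate()`, and two-group seedling `growth_promotion()` with
  Welch tests from summary statistics.
- **Simulators** — seeded generators with known ground truth for every
  input (`simulate_surface()`, `simulate_dppiv_plate()`,
  `simulate_seedlings()`).

The 29-run FYN-22 medium-optimization experiment ships as a bundled
fixture (`fyn22_runs()`, `fyn22_factors()`, `fyn22_tolerance()`,
`fyn22_seedlings()`), so the whole analysis reproduces offline.

## Worked example

```r
library(fermrsm)

runs <- fyn22_runs()          # 29 BBD runs, spore conc in 1e9 CFU/ml
fct  <- fyn22_factors()       # starch (A), yeast (B), NH4Cl (C), FeCl3 (D)
rep  <- run_pipeline(runs, fct)

rep$fit_stats
#>      r2 adj_r2 cv_percent
#> 1 0.922  0.843       2.72
```

The ANOVA shows a highly significant model (F = 11.76, p < 0.0001) with
non-significant lack of fit (F = 4.76, p = 0.0731) — the quadratic is
adequate relative to the pure error of the five center replicates:

```r
rep$anova
#>  Source          Sum of squares DF Mean square F value Prob > F
#>  Model           0.3459         14 0.0247      11.76   <0.0001  Significant
#>  A               0.0320          1 0.0320      15.25   0.0016   Significant
#>  ...
#>  Lack of fit     0.0271         10 0.0027      4.76    0.0731
#>  Pure error      0.0023          4 0.0006
```

All four linear terms matter (influence order A > C > B > D by partial
F), the starch×yeast interaction is significant, and the fitted surface
is concave with an interior maximum:

```r
rep$optimum
#>  symbol           name      coded    actual    g_per_l
#>       A soluble_starch -0.5197571 1.0960486 10.9604858
#>       B          yeast -0.2691201 2.3654400  2.3654400
#>       C          nh4cl  0.7616056 1.8808028  1.8808028
#>       D          fecl3  0.4941059 0.8494106  0.8494106
#> Predicted response: 1.89252 (interior)

validation_ratio(1.913, rep$optimum$predicted)
#> [1] 101.0823   # measured confirmation run, % of theoretical
```

That is: soluble starch 10.96 g/l, yeast 2.37 g/l, NH₄Cl 1.88 g/l and
FeCl₃ 0.85 g/l are predicted to yield 1.8925 × 10⁹ CFU/ml, and the
measured confirmation (1.913 × 10⁹ CFU/ml) reaches 101.1% of that
prediction. The companion assay tables compute the same way:

```r
survival_rate(fyn22_tolerance())     # e.g. pH 2.0 -> 85.98% survival
growth_promotion(fyn22_seedlings())  # shoot length +48.3%, p = 6.8e-14
```

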