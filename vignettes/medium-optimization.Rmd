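---
title: "Response-surface optimization of a fermentation medium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-surface optimization of a fermentation medium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermrsm)
```

## The problem

Spore yield of a fermenting *Bacillus* strain depends jointly on the
carbon source, organic and inorganic nitrogen sources, and trace
inorganic salts in the medium. One-factor-at-a-time (OFAT) screening
finds a good component of each class and a promising concentration, but
cannot see interactions. The standard remedy is a designed experiment:
center a Box–Behnken design (BBD) on the OFAT winners, fit a full
second-order polynomial to the measured responses, test its adequacy by
ANOVA, and maximize the fitted surface over the tested region.

`fermrsm` implements that workflow end to end, together with the assay
statistics that surround strain screening (DPP-IV inhibition, IAA
quantification, stress-survival rates, seedling growth promotion). The
bundled fixture is a four-factor, 29-run BBD measuring *Bacillus
licheniformis* FYN-22 spore concentration (×10⁹ CFU/ml) as a function
of soluble starch, yeast, NH₄Cl and FeCl₃.

## The model

Factors enter on the coded scale $x_i = (v_i - c_i)/s_i$, where $c_i$
is the concentration at the design center and $s_i$ the half-range, so
the tested levels map to $-1, 0, +1$. The response model is the full
quadratic

$$Y = \beta_0 + \sum_i \beta_i x_i + \sum_{i<j} \beta_{ij} x_i x_j +
\sum_i \beta_{ii} x_i^2 + \varepsilon,\qquad
\varepsilon \sim \mathcal{N}(0, \sigma^2)\ \text{i.i.d.}$$

For $k$ factors this has $1 + 2k + k(k-1)/2$ terms (15 for $k = 4$); a
BBD with $4\binom{k}{2}$ edge runs plus $n_c$ centers estimates it with
all coded columns balanced (sum 0, sum of squares $4(k-1)$) and the
linear/interaction block exactly orthogonal. `fit_quadratic()` solves
the least-squares problem by QR decomposition of the model matrix in
the canonical term order (intercept, linear, interactions in
lexicographic pair order, quadratics); a rank-deficient design aborts
with the collinear terms named. No regularization or term selection is
performed — the design exists precisely to estimate this fixed model,
and coefficients are reported on the coded scale (an actual-scale
re-expression is available via `actual_scale_coefficients()` but is
derived output only).

```{r fit}
runs <- fyn22_runs()
fct  <- fyn22_factors()
fit  <- fit_quadratic(runs, fct)
tidy(fit)
```

## ANOVA conventions

`anova_quad()` reports, per model term, the **partial (Type III) sum of
squares**: the increase in residual SS when that term alone is removed
from the full model, computed by an explicit refit rather than a
shortcut formula. On the orthogonal linear/interaction block of a BBD
these reduce to the contrast closed forms $SS_i = 12\beta_i^2$ and
$SS_{ij} = 4\beta_{ij}^2$ (for $k=4$), which the test suite verifies to
1e-8; for quadratic terms, whose columns are mutually correlated, the
partial SS genuinely differs from a sequential decomposition, and the
per-term SS need not sum to the model SS.

The residual splits into **pure error** — within-group deviations over
runs with identical coded vectors (the replicated centers here, 4 df)
— and **lack of fit** (10 df); their mean-square ratio tests model
adequacy. Replicate detection is by identical coded rows generally, not
by "center point" specifically, so fractional replication elsewhere
would be used too. With no replicated rows the lack-of-fit rows are
`NA` and a classed warning (`fermrsm_lof_undefined`) is raised — the
residual row is still usable. F statistics use the residual mean
square; p-values come from the F distribution. Fit quality is
summarized by $R^2$, adjusted $R^2$, and the coefficient of variation
$CV\% = 100\sqrt{MS_{res}}/\bar y$.

```{r anova}
an <- anova_quad(fit)
an
fit_statistics(fit)
```

Two reporting conventions follow response-surface software: p-values
below $10^{-4}$ print as `<0.0001`, and the significance flag is
recomputed from $p < \alpha$ (default $\alpha = 0.05$, configurable)
rather than copied from any source table. Influence ordering
(`rank_effects()`) uses descending partial F for main effects and
descending partial SS for interactions, with exact ties sharing a rank
— on the fixture, A:C and A:D tie exactly by symmetry of their
coefficients.

A numerical note: with responses interpolated exactly (zero residual),
per-term F ratios are reported as `Inf` and the table carries an
`exact_fit` attribute instead of propagating 0/0.

## Optimization

The fitted surface is a quadratic form $Y = \beta_0 + g'x + x'Hx/2$
with $H_{ii} = 2\beta_{ii}$, $H_{ij} = \beta_{ij}$.
`stationary_point()` solves $Hx = -g$ and classifies the point by the
Hessian eigenvalue signs. `maximize_in_cube()` maximizes over the coded
cube $[-1,1]^k$ — the tested factor range; the package deliberately
refuses to recommend extrapolated settings. If the stationary point is
interior and $H$ negative definite it is returned exactly (no iterative
error); otherwise the maximum lies on the boundary and an L-BFGS-B
search with analytic gradient is multistarted from all $2^k$ vertices,
all $2k$ face centers, the cube center and the clipped stationary
point, keeping the best. A seeded 10⁵-point sampling oracle in the test
suite confirms dominance.

```{r optimum}
opt <- maximize_in_cube(fit)
opt
validation_ratio(1.913, opt$predicted)
```

The optimum is reported on three scales: coded, the actual design units,
and g/l via the per-factor `g_per_l` conversion declared with the
factors (the fixture's starch unit is 10⁻² g/ml = 10 g/l per unit).
`surface_slice()` grids the surface over a factor pair (default 101×101)
with the held factors clamped at coded 0 — the center levels, the
conventional choice for contour panels — and `autoplot()` renders the
filled-contour plot with the slice maximum marked.

## Supporting assay statistics

- `dppiv_inhibition()` implements the four-arm microplate correction
  $100(1 - (\Delta X - \Delta P)/(\Delta S - \Delta T))$: the sample
  well is blanked by its enzyme-free background, the enzyme control by
  the substrate-only blank. Values outside $[0, 100]$ are returned as
  computed but flagged; by construction the statistic depends only on
  the two differences.
- `fit_standard_curve()` regresses concentration on OD (the orientation
  used for Salkowski-reaction IAA curves), so `quantify_iaa()` is a
  direct read-off times the dilution factor, floored at zero and
  flagged outside the calibrated OD range.
- `survival_rate()` is $100 \cdot \text{final}/\text{initial}$ viable
  count, scale-invariant in the counting units.
- `growth_promotion()` computes per-trait percent change of means and a
  two-sample t test **from summary statistics** (mean, SD, n per
  group), since published seedling tables report exactly that. Welch's
  unequal-variance test is the default — the safer choice when group
  SDs differ, as they do for shoot length here (0.40 vs 1.29 mm) — with
  the pooled Student's t available via `var_equal = TRUE`.

## Synthetic data and what the tests show

Each pipeline input has a seeded simulator with known ground truth:

- `simulate_surface()` draws $y = $ true quadratic $ + \mathcal{N}(0,
  \sigma)$ on a generated BBD — exactly the ANOVA's assumed model. The
  reference noise level used throughout the tests is $\sigma = 0.046$,
  the fixture's residual SD ($\sqrt{0.0021}$), on a 29-run, 5-center
  layout matching the experiment. A log-normal multiplicative-error
  option exists because CFU counts are positive, but the additive
  default is what the fitted model assumes.
- `simulate_dppiv_plate()` builds wells whose noiseless inhibition
  equals the requested truth, then adds per-well Gaussian noise.
- `simulate_seedlings()` draws individual Gaussian measurements from
  per-group means/SDs, letting summary-statistic tests be checked
  against `t.test()` and a permutation oracle on raw samples.

All simulators take a mandatory seed, restore the caller's RNG state,
and are byte-reproducible. Monte-Carlo checks in the test suite use
500 replicates for coefficient unbiasedness, 1000 for 95% CI coverage
(within 3 points of nominal), 1000 plates for inhibition recovery,
2000 replicates for the seedling power check, and 10⁴ permutations for
the Welch-vs-permutation comparison — sizes at which each check runs
in seconds while keeping Monte-Carlo error well below the asserted
margins.

What passing these tests shows: the estimator is unbiased and correctly
calibrated *under the assumed model* — Gaussian, independent,
homoscedastic errors on a balanced design. Real fermentation data can
violate all three (heteroscedastic counts, batch effects, run-order
drift), and the simulators deliberately do not emulate plate-reader
drift or mechanistic growth kinetics; conclusions about robustness to
those features cannot be drawn from this suite.

## Design choices on open points

- **Center-level mapping.** The fixture's factor table fixes coded 0 at
  the level the five center runs actually use (starch 1.2×10⁻² g/ml),
  which is also the OFAT winner; the −1/+1 levels are center ∓/＋ step.
- **Run order.** Ingested tables keep their printed order; generated
  designs use deterministic pair-block order (ANOVA is order-invariant,
  and determinism makes diffs meaningful). An optional seed permutes
  rows reproducibly for randomized execution.
- **OFAT ties** break toward the lowest concentration — deterministic
  and the cheaper medium.
- **Refit vs printed equation.** All downstream numbers (ANOVA,
  optimum) use the refit of the bundled data, not rounded published
  coefficients: 4-dp rounding of the coefficients visibly shifts the
  stationary point in the third decimal. Where a printed equation term
  disagrees with its own ANOVA line, the refit is taken as the source
  of truth.
- **Percent rounding.** Assay percents are returned at full precision;
  rounding to 2 dp is left to report formatting, so no information is
  lost in chained computations.

## Limitations

Single-response optimization only (no desirability combination of
multiple responses); no ridge analysis or confidence region on the
optimum location; no sequential model-order selection, PRESS, or
Box–Cox transformation; designs beyond the pair-block Box–Behnken
family (central composite, Plackett–Burman, D-optimal) are out of
scope.
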