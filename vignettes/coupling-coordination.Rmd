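---
title: "Measuring supply-demand coupling coordination of regional service resources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring supply-demand coupling coordination of regional service resources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(couplecoord)
```

## The problem and the model

A regional service system — here, elderly-care service resources across the
31 province-level regions of mainland China — has a supply side (staff,
institutions, beds, floor space, subsidies) and a demand side (the size of
the elderly population, the dependency ratio, purchasing power, realized
institutional use). Whether the two sides develop in step is the question
this package quantifies, with one number per region-year: the coupling
coordination degree $D \in [0, 1]$.

The chain, run independently within each year $t$:

1. **Standardization.** Each indicator $j$ is min-max rescaled across the
   $n$ regions: $Z'_{pj} = (Z_{pj} - \min_p Z_{pj}) / (\max_p Z_{pj} -
   \min_p Z_{pj})$ for positive-orientation indicators, with the mirrored
   branch $(\max - Z) / (\max - \min)$ for negative ones.
2. **Entropy weights.** For each subsystem separately, indicator $j$'s
   weight is proportional to one minus the Shannon entropy of its
   cross-region proportion distribution $S_{pj} = Z'_{pj} / \sum_p Z'_{pj}$:
   $K_j = -\tfrac{1}{\ln n}\sum_p S_{pj}\ln S_{pj}$, $W_j \propto 1 - K_j$.
   Indicators that discriminate more between regions weigh more, with no
   subjective input.
3. **Composite scores.** $T_1 = \sum_j W_j Z'_j$ over the supply
   indicators, $T_2$ likewise over the demand indicators, both in $[0,1]$.
4. **Coupling and coordination.** The coupling degree
   $C = 2\sqrt{T_1 T_2}/(T_1 + T_2)$ measures balance (1 iff $T_1 = T_2$);
   the coordination degree $D = C\,(\alpha T_1 + \beta T_2)$ additionally
   rewards level of development, with $\alpha = 0.4$, $\beta = 0.6$.
5. **Classification.** $D$ falls into ten half-open bins of width 0.1
   (`coordination_levels()`), grouped into poor ($D < 0.4$), medium
   ($0.4 \le D < 0.6$) and excellent ($D \ge 0.6$) coordination.
6. **Spatial autocorrelation.** Global Moran's I of the per-year $D$
   vector under a contiguity weight matrix, with a one-sided permutation
   test as the inferential layer.
7. **Forecasting.** Each (region, indicator) series is extended five years
   ahead by a small feed-forward network in sliding-window form, and the
   chain re-runs on the forecast panel.

```{r example}
sim <- generate_panel(synthetic_config(m_regions = 8, years = 2010:2015,
                                       seed = 7))
head(couple_panel(sim$panel), 4)
```

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `alpha`, `beta` | 0.4, 0.6 | relative importance of supply vs demand in $D$; must sum to 1. Demand weighs slightly more: demand pressure is the driver supply policy responds to. |
| `scope` | `"per_year"` | min/max taken across regions within each year, which is what per-year weight trajectories require; `"pooled"` uses the panel-wide range for sensitivity analysis. |
| `sqrt_variant` | `FALSE` | part of the coupling-coordination literature defines $D = \sqrt{C(\alpha T_1 + \beta T_2)}$; the plain product is the form implemented as primary, the square root is available behind this flag. |
| `weights_scheme` | `"binary"` | contiguity weights enter the Moran statistic unnormalized (the statistic divides by the total weight itself); `"row_standardized"` is available and is what some GIS tools apply silently. |
| `lag`, `hidden_units` | 3, 8 | sliding-window geometry; with ten yearly observations, lag 3 yields 7 training pairs and 8 tanh units (41 parameters with L2 decay) are near the identifiability ceiling. |

## The ten-level classification

Bin edges are half-open, $[a, a + 0.1)$, with $[0.9, 1]$ closed, so every
$D$ has exactly one level. The three-category thresholds are 0.4 and 0.6,
resolved so a boundary value belongs to the upper category
($D = 0.6$ is excellent).

```{r levels}
coordination_levels()
```

## What the synthetic generator emulates — and what it does not

`generate_panel()` draws, per region, a latent supply capacity $u_p$ and
demand pressure $v_p$, bivariate normal with standard deviation
`region_scale_sd` and correlation `coupling_rho`; indicator $j$'s level is
$\mathrm{base}_j \exp(\lambda_j u_p)(1 + \mathrm{trend})^{t - t_0}
\varepsilon$ with unit-mean lognormal noise. This is multiplicative
throughout because all fourteen indicators are nonnegative counts or
amounts (persons, beds, m², yuan) whose cross-region dispersion is
scale-like.

Defaults, chosen once as what province-level panels of this kind look like:
31 regions and years 2010–2019 (the study conditions);
`region_scale_sd = 0.6`, so large provinces run roughly 3–10× small ones;
`trend_rate = 0.08`, the order of magnitude of 2010s elderly-care capacity
growth; `noise_cv = 0.1` for year-to-year measurement and reporting
wobble; `coupling_rho = 0.6`, supply broadly following demand but
imperfectly.

The generator reproduces the features the method is sensitive to — scale
effects, growth, supply-demand correlation, completeness — and *not*
others real data have: no spatial structure (deliberately: it provides the
null for calibrating the permutation test), no heteroskedastic policy
shocks, no cross-indicator correlation beyond the shared latent, no
calibration of magnitudes to actual yearbook values. Passing tests on
synthetic panels therefore demonstrate the arithmetic and the statistical
mechanics, not that any particular real region is well coordinated.

## Numerical choices

- **Degenerate indicators.** An indicator constant across regions carries
  no ordering information; every standardized entry is set to 0.5. Equal
  proportions give entropy exactly 1, hence weight exactly 0 — the one
  self-consistent treatment, enforced exactly in code (the entropy of a
  flat column is snapped past the last ulp of `log`).
- **$0 \ln 0 := 0$.** Exact zeros always exist after min-max
  standardization; the continuity limit is used.
- **Zero totals.** $C$ is defined as 0 when $T_1 + T_2 = 0$; composite
  scores are clamped against $\le 10^{-9}$ floating-point overshoot of 1.
- **Reporting rounding.** Published tables round decimal halves up
  (0.42795 → 0.4280); `round_half_up()` reproduces that, where base R's
  `round()` is half-even. Four of the 31 published 2010–2019 row means are
  half-cases that only match under half-up rounding.
- **Forecast training.** Per-series min-max scaling to $[0,1]$; one
  hidden tanh layer with linear output; full-batch BFGS with analytic
  gradients, best of 5 seeded initializations; recursive multi-step
  forecasting; inverse scaling and clipping at 0. Deterministic
  optimization was chosen over stochastic training because bitwise
  reproducibility under a seed is a requirement here, and on 7-pair
  training sets stochasticity buys nothing. A constant series bypasses the
  network (its scaled form is undefined) and forecasts itself.
- **Moran's I.** Implemented exactly in the printed normalization
  ($\sum W_{pq}$ in the denominator), so binary contiguity is the natural
  default; the statistic is invariant to positive rescaling of $W$ either
  way. The permutation p-value uses the add-one convention
  $(1 + \#\{I_\pi \ge I_{obs}\})/(n_{perm} + 1)$.

## Design choices where the design was open

- **Per-year standardization scope.** The min/max subscripts in the source
  formulation are ambiguous, but yearly weight trajectories are reported
  downstream, which forces per-year cross-region standardization; the
  pooled mode is kept as a flag, not a default.
- **Proportions over regions.** The entropy step's summation indices are
  internally inconsistent in the source; the standard entropy-weight
  reading (proportions across regions within an indicator) is the only one
  under which "less entropy → more discriminating → more weight" makes
  sense, and is what is implemented.
- **Plain-product $D$.** The printed formula has no square root; it
  governs. Whether the published tables were actually produced with the
  square-root variant cannot be determined without the raw panel — noted,
  not guessed.
- **Contiguity fixture.** The original weight matrix is unspecified. The
  package ships first-order queen contiguity among the 31 units with a
  Hainan–Guangdong bridge, as one conventional choice, and treats published
  Moran values as non-reproducible: the published sequence repeats
  cyclically across years, which looks like a transcription defect, so the
  analysis scripts log comparison values and assert nothing.
- **Per-indicator forecasting.** Forecasts are fitted per (region,
  indicator) series, then aggregated by re-running the pipeline — rather
  than forecasting composite scores — because indicator-level weight
  trajectories in forecast years are part of the downstream analysis.

## Problem sizes and verification

The test suite verifies the pipeline against literal loop transcriptions
of the formulas (500 random 5-region panels to $10^{-12}$; Moran's I
against a naive double loop and against an independent reference
implementation), closed forms ($C(T,T) = 1$, $D(T,T) = T$, checkerboard
Moran's I of $-1$ on a 4-ring, null mean $-1/(n-1)$ over 1000 draws), and
recovery properties on synthetic panels at the default 31×10×14 size:
median coupling rises monotonically in `coupling_rho` over 100 replicates,
and the permutation test's size over 500 spatially-null replicates stays
near its nominal 5%. Forecast behaviour is checked on constant, linear,
exponential and trendless-noisy series and on the full 434-series panel.

## Known limitations

- Min-max standardization ties every score to the yearly cross-region
  extremes, so a single outlier region compresses everyone else's scores;
  this is inherent to the method, not a bug, and is why $D$ values
  concentrate below 0.5 for skewed panels.
- Entropy weights are re-estimated each year; weight trajectories conflate
  genuine importance shifts with sampling noise at $n = 31$.
- Recursive multi-step forecasting compounds one-step error; horizons
  beyond roughly half the training length should be read as trend
  extrapolation, not prediction.
- Global Moran's I summarizes the whole map in one number; local
  autocorrelation (LISA) is out of scope here.
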