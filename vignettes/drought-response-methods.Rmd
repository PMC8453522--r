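---
title: "Methods: tree and stand drought responses from rings, climate and maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tree and stand drought responses from rings, climate and maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures `standres` implements, the
assumptions behind them, and the choices made where the design was genuinely
open. It states no empirical result that the package's tests and
`scripts/acceptance.R` do not themselves compute.

## The scientific setting

Long-term thinning experiments in mixed silver fir / Norway spruce stands
record, over decades: mapped tree positions and periodic DBH, the removal
year of every harvested tree, and ring-width series measured on discs of
those harvested trees. The analysis question is how drought responses of
individual trees and whole stands depend on species, neighborhood
competition, stand density and management. `standres` covers the full chain
from raw inputs to fitted models, plus a generator that fabricates such an
experiment with known ground truth.

## Growth: rings to basal area increment

Radii measured on the same disc are averaged on ring widths, per year, over
whichever radii cover that year; the per-tree mean series is then treated as
the tree's radial increment. Averaging before (not after) BAI conversion is
the standard dendro choice and gives a single DBH reconstruction per tree;
it is an assumption, since the alternative order is also defensible.

Bark is removed with a species-specific model of bark thickness against
over-bark DBH. The functional form is linear by default with a square-root
option; regional bark models are commonly curvilinear, but over the DBH
range of a single experiment a linear fit is the minimal defensible choice
and the form is a configuration option, not a constant.

Inside-bark DBH is reconstructed backwards from the sampling date:
`DBH_ib(t-1) = DBH_ib(t) - 2 w(t)`. Measurement and bark-model error can
make twice the cumulated widths exceed the reconstructed diameter; an excess
up to 5% is rescaled proportionally (flagged, with a warning) so radii stay
non-negative, a larger excess is an error naming the tree. The ring of
calendar year t is the growth of year t (sampling after the growing
season), and removal happens in the winter before the growing season, so a
tree removed in year y last contributes growth in y − 1.

## Drought indexing

PET uses the Hargreaves temperature-only formula; the package deliberately
provides no Penman–Monteith or Thornthwaite option, since monthly min/mean/
max temperature and precipitation are all the experiment's climate sources
offer. Extraterrestrial radiation follows the FAO-56 solar geometry,
evaluated at the 15th of each month; latitudes beyond ±66.5° are refused
rather than approximated.

The SPEI at target month m and scale k standardizes the k-month sum D of
monthly P − PET ending at m. One distribution is fitted per target month so
seasonality does not leak into the index. The distribution is the
three-parameter (shifted) log-logistic, fitted from the first three
L-moments with unbiased PWM estimators — the standard published estimation
choice, stable at the 30–60 calibration years this design provides. It is
parameterized in generalized-logistic form (location, scale, shape
k = −t3), which handles water-balance samples of either skew; probabilities
are clipped to [1e-6, 1 − 1e-6] before the normal quantile transform.
Calibration defaults to the full series and is configurable; at least 30
complete calibration years are required.

Drought events can be selected two ways, because the source design ranks
years within sub-periods while a fixed cutoff is the more common generic
rule: `mode = "rank"` takes the n lowest cross-site mean SPEI years per
configured period, `mode = "threshold"` takes every year below the mild
cutoff. Classification defaults to mild for SPEI in (−1.5, −0.5] and severe
below −1.5; these are configuration values, documented here, not asserted
as the experiment's own rule.

## Competition and stand covariates

NI sums neighbor basal area over distance within a radius (default 10 m);
the radius can be chosen by maximizing the R² of periodic annual BAI
against NI over a candidate grid, ties going to the smallest radius
(parsimony). Species-group ratios NI_sp/NI quantify who exerts the
competition; they are undefined (flagged) for isolated trees. Trees closer
than the radius to a plot edge have truncated neighborhoods; they are
flagged and excluded from model fitting by default (configurable). The
exclusion mirrors the treatment of light-absorption estimates near plot
boundaries and is documented as this package's extension, since the source
protocol states the exclusion only for the radiation model. Distances are
planar; positions are assumed already projected.

## Lloret indices

With a window w (default 2) around event year e: resistance
`Rt = x_e / mean(x_{e-w..e-1})`, recovery `Rc = mean(x_{e+1..e+w}) / x_e`,
resilience `Rs = Rt * Rc`. The 2-year default reflects growth
autocorrelation (legacies of 1–2 years) while keeping unrelated events out
of the windows; events closer together than 2w + 1 years are rejected
rather than silently truncated. Trees harvested within a window are
excluded (logged), and their absence propagates to stand sums: the stand
index is computed on the summed BAI of surviving measured trees, not on the
mean of tree-level ratios — a deliberate reading of "stand BAI is a sum",
which the tests pin down with a two-tree hand example. Indices on
spline-detrended series are provided to check that size/age trends do not
drive the raw-BAI results.

## Detrending

The detrending spline is a discrete cubic smoothing spline (second-
difference roughness penalty) with its smoothing constant set from the
frequency-response definition: interior transfer function
`H(omega) = 1/(1 + lambda (2 - 2 cos omega)^2)`, so a 50% response at
wavelength p gives `lambda = 1/(16 sin^4(pi/p))`, with p defaulting to
⌈2n/3⌉. Constant and linear series pass through exactly (zero penalty on
linear trends). Because a series of length n contains only 1.5 cycles of
its own 2n/3 wavelength, the 50% attenuation property is verified on the
central third of the series, where the natural boundary conditions do not
contaminate the estimate; the tests check 0.50 ± 0.05 there and the
package's acceptance script reports the measured attenuation.

## The model protocol

Responses (Rt, Rc, Rs) are modelled on the natural-log scale by default.
The source tables' negative resistance intercepts are consistent with a
log-ratio response, but the transformation is not stated there, so the raw
scale remains available (`log_response = FALSE`). Predictors are scaled and
centered; screening first removes, within every pair correlated at
|r| ≥ 0.5, the member less correlated with the response, then iteratively
drops the largest-VIF predictor while any VIF exceeds 2.

Tree-level models are linear mixed models with a random intercept for plot,
fitted by maximum likelihood — not REML — because AICc is compared across
fixed-effect sets. Species uses treatment contrasts with spruce as the
reference. The all-subsets search respects marginality (no interaction
without its main effects), caps candidates at 12 terms, skips subsets with
n − k − 1 ≤ 0, and breaks AICc ties (< 1e-8) toward fewer parameters.

Two deliberate numerical choices:

* **Singular fits stay in the ranking.** A boundary fit (random-intercept
  variance estimated at zero) is a valid ML estimate; excluding it would
  bias selection whenever the true group variance is small. Only optimizer
  failures are excluded (logged). When the grouping factor is degenerate
  (fewer than two groups with two observations), the model falls back to
  fixed effects only, with a message, and reproduces OLS exactly.
* **Effect sizes are β²-weighted.** The effect size of a term is the
  variance of its partial fixed-effect predictor (β² for one standardized
  column; the variance of the combined columns for factors and
  interactions) divided by the total model variance (fixed + random +
  residual). Read literally, "the variance of the standardized predictor"
  is 1 by construction; the implemented reading is the one that makes
  effect sizes sum to R²m under orthogonality, which the tests assert.

R²m and R²c follow Nakagawa: the fixed-predictor variance over, and the
fixed-plus-random variance over, the total. Stand-level models use the same
screening and AICc machinery with ordinary least squares and adjusted R².

## What the synthetic generator emulates — and what it does not

The generator's defaults describe one plausible central-European mixed
mountain-forest experiment and are fixed once: 0.25 ha plots (50 m side),
600 stems/ha at establishment, species mix 50% fir / 35% spruce / 15%
other, lognormal DBH (median 27 cm, σ_log 0.35) truncated at the 4 cm
mapping threshold, monthly climate with 7 °C mean, 8.5 °C seasonal
half-amplitude, AR(1) = 0.3 temperature noise (SD 1.2 °C), gamma monthly
precipitation (shape 4, scale 30 mm), and March–July precipitation
multipliers embedding two mild (1984: 0.75, 1991: 0.78) and two severe
(2003: 0.45, 2011: 0.55) drought years — chosen to reproduce the
mild/severe SPEI contrast of the motivating experiment. Thinning regimes
remove 0 / 12% / 22% of basal area every 5 years, DBH-weighted at random.

Growth follows a log-linear model,

    log BAI = a_sp + b log DBH_ib − c NI + d_sp SPEI − e BA_stand
              + plot effect + ε,

with defaults a = (1.1, 1.0, 0.9), b = 0.55, c = 5e-5 per cm²/m, d =
(0.12 fir, 0.30 spruce, 0.20 other), e = 0.006 per m²/ha, ε lognormal with
σ = 0.20 and a plot intercept SD of 0.08. The multiplicative form makes
Lloret ratios analytically predictable — the expected fir-vs-spruce
log-resistance contrast is `(d_fir − d_spruce)·SPEI_dr` minus the log of
the 2-year mean of the exponentiated pre-drought SPEI responses — which is
exactly the oracle the end-to-end recovery tests use. Note the sign
convention: d multiplies SPEI, so a *larger* d means a *more*
drought-sensitive, less resistant species; fir's smaller d encodes its
higher resistance. Drought enters generation through the same SPEI the
pipeline computes, removing any index mismatch between simulation and
analysis. The light-absorption covariate is a size-correlated proxy, not a
radiative-transfer computation.

Not simulated: regeneration/ingrowth, non-harvest mortality, bark-beetle
dynamics, 3-D crown geometry, cross-dating error, spatial clustering of
species, and climate trends. Passing tests therefore demonstrate that the
pipeline recovers known effects under these idealized conditions; they do
not certify behavior under dating errors, mortality-biased sampling or
non-stationary climate, all of which real data bring.

## Validation problem sizes

The package's own validation uses: 10,000 random series for the algebraic
identity suite; 40–50 trees for exact brute-force competition checks; a
60-year single-site climate for the 144-window SPEI standardization sweep;
50 seeds each for SPEI-window recovery (noise SD 0.2 on the chronology) and
competition-radius recovery (300 trees, radius 8 m, candidates 4–14 m); and
100 replicates of a two-plot, ~420-tree, two-drought experiment for
end-to-end species-effect recovery plus 100 replicates of its null
(zero-contrast) control. These sizes are the package's choices, balancing
Monte-Carlo error against convenience.

## Known limitations

* The Tucson reader accepts the two common stop-marker dialects (999 at
  0.01 mm, −9999 at 0.001 mm) and contiguous series only; headers and
  non-decadal variants are out of scope.
* The SPEI fit requires |L-skewness| < 1 and errors on degenerate
  (zero-variance) water-balance samples rather than guessing.
* Stand-level model frames in small designs (few plots × few events) may
  not support any candidate subset; the pipeline then reports the skip and
  carries on rather than failing the run.
* The effect-size decomposition attributes shared variance of correlated
  predictors to neither term (it is not a commonality analysis); with the
  screening thresholds in place, predictor correlations are bounded, which
  is why the simple decomposition is defensible here.
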