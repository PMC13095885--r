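---
title: "An expolinear-logistic model of individual leaf size in three C4 cereals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An expolinear-logistic model of individual leaf size in three C4 cereals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafprofile)
```

## The problem and the model

Canopy development in maize, sorghum and pearl millet is commonly
simulated leaf by leaf: the area of each main-culm leaf, together with the
thermal-time schedule of leaf appearance, determines light interception
and transpiring surface through the season. The classical description is a
bell-shaped curve of mature leaf area against leaf position, whose
empirical breadth and skewness coefficients are only stable over a limited
range of total leaf numbers. `leafprofile` instead models the two blade
dimensions separately and composes area from them, which keeps the
parameters interpretable (a first-leaf size, a growth slope, a decay rate)
and lets genotypic differences in blade width — a trait linked to
transpiration efficiency — enter the model explicitly.

For one trait (blade length or blade width, both in mm) the size of the
leaf at position $x$ (1 = coleoptile leaf, TLN = flag leaf) is

$$y(x) = L_1 + \frac{c_m}{r_m}\,\ln\!\big(1 + e^{r_m (x - t_b - 1)}\big),
\qquad x < x_s,$$

$$y(x) = \frac{Y_{max}\, Y_{slevel}}
  {Y_{max} + (Y_{slevel} - Y_{max})\, e^{d_r (x - x_s)}},
\qquad x \ge x_s,$$

with $Y_{max} = y(x_s)$ evaluated through the rising branch and
$Y_{slevel} = Y_{max} + d_{sl}$. The rising branch is expolinear:
exponential growth at rate $r_m$ (per leaf) that straightens into a line
of slope $c_m$ (mm per leaf); the falling branch is a logistic decay at
rate $d_r$ whose upper asymptote sits $d_{sl}$ mm above the maximum. The
two branches meet at the real-valued largest-leaf position $x_s$ by
construction, since both equal $Y_{max}$ there. Leaf area is
$\mathrm{length} \times \mathrm{width} \times 0.71$, with $0.635$ for the
flag leaf.

Two parameters carry the dependence on total leaf number. The largest-leaf
position follows $x_s = a + b\,\mathrm{TLN}$ for maize and pearl millet
and a continuous segmented line for sorghum (one intercept, two slopes,
breakpoint at TLN 20.5 — a single-intercept parameterization is the only
continuous form recoverable from the published coefficients). The decay
rate declines linearly with TLN up to a species- and trait-specific
breakpoint and is constant beyond it; the plateau value is defined as the
declining line evaluated at the breakpoint, again for continuity, since no
separate plateau constant is published. The remaining five parameters are
fixed per species and trait; the packaged values with their standard
errors live in `inst/extdata/species_params.yaml`.

## Parameters at a glance

| parameter | units | meaning |
|---|---|---|
| `L1` | mm | first-leaf (coleoptile leaf) blade size; lower asymptote of the rising branch |
| `cm` | mm/leaf | maximum slope of the linear phase |
| `rm` | /leaf | rate of the exponential phase |
| `tb` | leaf positions | offset of the expolinear term |
| `xs` | leaf positions | position of the largest leaf (real-valued, from TLN) |
| `dr` | /leaf | logistic decay rate (from TLN) |
| `dsl` | mm | offset of the upper asymptote above `Ymax` |

Two documented quirks are worth knowing. First, `tb` is often described as
the position where the extrapolated `cm` slope crosses the x-axis, but the
rising-branch formula, taken literally (as this package does), puts that
crossing at $t_b + 1 - L_1/c_m$; we follow the formula, not the gloss.
Second, `L1` is the lower *asymptote*, not the value at $x = 1$: the model
value at position 1 always exceeds `L1` slightly.

Validation requires `L1, cm, rm > 0`, `xs > 1`, `dr >= 0`, `dsl >= 0`. We
deliberately do **not** require `xs > tb + 1`: the packaged pearl millet
blade-width values (`tb = 14.79` with `xs` below 15.8 for most of the
observed TLN range) violate that stricter condition while remaining
mathematically well-defined — the peak then falls inside the curved part
of the expolinear phase, which is exactly what a slow-widening millet
culm looks like. `dsl = 0` or `dr = 0` degenerate to a flat post-peak
profile and are accepted, not errors.

`build_params()` restricts TLN to a plausibility range (default 8–45,
spanning the observed extremes across the three species: minima of 9 and
maxima of 44 in the training compilations) and can be overridden.

## Numerical choices

The rising branch is evaluated as a softplus,
$\log(1+e^z) = z + \log(1+e^{-z})$ for $z > 0$, so it is finite for
exponent arguments far beyond overflow (the tests push
$r_m(x - t_b - 1)$ to $10^4$). The falling branch tolerates overflow of
$e^{d_r(x - x_s)}$ gracefully (the ratio correctly underflows to zero).
Integer leaf positions are evaluated against the real-valued $x_s$; the
largest *integer* position can therefore sit on either side of $x_s$, and
profile maxima land within one position of it.

## The calibration pipeline

`calibrate_species()` reproduces the estimation strategy used to obtain
species-generic values:

1. observations are grouped by genotype × TLN within each trait (groups
   under 8 observations are skipped and logged);
2. each group is fitted by Levenberg–Marquardt nonlinear least squares
   (`minpack.lm::nls.lm`) with bound constraints; standard errors come
   from the Jacobian-based covariance at the optimum. The data-driven
   initialization (`default_init()`: smallest value for `L1`, position of
   the largest value for `xs`, largest successive increase for `cm`,
   `rm = 1`, `tb = 2`) is augmented by a small fixed set of alternative
   starts varying `rm` and `tb`, and the lowest-RSS fit wins. The extra
   starts matter for slow-exponential traits such as pearl millet blade
   width (`rm = 0.19`, `tb = 14.79`), where a single heuristic start can
   sit in the wrong basin; they are deterministic, so fits remain
   reproducible and permutation-invariant;
3. the fixed parameters are pooled as unweighted means of per-group
   estimates (an inverse-variance option exists behind
   `calib_config(pool = "invvar")`);
4. per-group `xs` estimates are regressed on TLN — ordinary least squares,
   or for sorghum a continuous segmented fit whose free breakpoint is
   found by profiling the RSS on a 0.1-TLN grid (the profiled problem is
   linear in the remaining coefficients) and polishing with 1-D
   optimization. The breakpoint may also be fixed (e.g. at 20.5) to
   reproduce the published rule exactly;
5. per-group `dr` estimates are screened for bivariate (TLN, dr) outliers,
   then fitted with the continuous decline-then-plateau form by the same
   grid-plus-polish profiling.

The outlier screen implements one admissible reading of an
under-specified published rule ("removed based on their bivariate
distribution quantile"): a one-step reweighted minimum covariance
determinant (raw MCD at 75 % coverage, then classical moments of the
points the raw distances accept at the 0.999 chi-square quantile), with
points flagged beyond the chi-square(2) quantile 0.975 (configurable).
The 75 % coverage and the reweighting step stop the estimator from
collapsing onto the plateau arm of the point cloud and flagging the
legitimate low-TLN decline; a grossly inflated decay-rate estimate is
still flagged on its own. With exactly collinear or insufficient points
the screen degrades to flagging nothing, with a warning.

Degenerate regression inputs are reported rather than hidden: equal
slopes make a segmented breakpoint unidentifiable (`degenerate` flag), a
pure decline pins the plateau breakpoint at the largest TLN with a
warning, and one-sided data fall back to a linear fit.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` emulates the *structure* of the multi-experiment
training compilations: several genotypes per species, TLN spreads matching
the observed ranges (maize 11–25, sorghum 9–44, pearl millet 11–27 in
`table1_style_panel()`), several plants per TLN, and per-leaf measurement
noise. Because no observation-noise model is published, the default is
additive Gaussian noise with per-trait standard deviations of 20 mm
(length) and 3 mm (width), loosely scaled to the reported dispersion
magnitudes; a proportional (CV) alternative is available. Values are
floored at 1 mm (all reported minima are ≥ 2 mm), and genotype-level
variation can be injected as lognormal multiplicative perturbations of
`cm` and `L1` (off by default — genotype effects are demonstrated but not
quantified in the source material). Noise is independent across leaves,
traits and plants; real repeated measurements on a plant are surely
correlated, so passing recovery tests here says nothing about robustness
to structured measurement error, rater effects, or model misspecification
in real canopies. Every simulation requires an explicit seed and is
exactly reproducible.

For parameter-recovery experiments the TLN panels are chosen so that every
group has at least three integer positions beyond its largest-leaf
position while still straddling the `xs` and `dr` breakpoints (maize
12–25, sorghum 14–40, pearl millet 15–27). This honours the fitting
precondition that observations span both sides of `xs`: with two or fewer
post-peak points, `dr` and `dsl` are jointly unidentifiable — several
(`dr`, `dsl`) pairs interpolate the same observations exactly — which is
also why low-TLN plants produce the erratic decay-rate estimates the
outlier screen targets.

## Problem sizes used by the shipped experiments

The packaged recovery experiments are deliberately desk-scale: noiseless
per-group fits over five TLN groups per species-trait (targets such as the
maize `cm` and sorghum `L1` recoveries), breakpoint regressions over 13–17
TLN points, and end-to-end calibrations over three genotypes × 13–27 TLN
values with one (noiseless) or ten (5 % CV noise) plants per TLN. The
noiseless end-to-end experiment reproduces every generating parameter to
well under 2 %; the noisy one is a genuinely stochastic check in which
most — not all — parameters land inside the published standard-error
bands (weakly identified corners, such as the pearl millet blade-width
expolinear phase and decay-rate intercepts, move out of band first).

## Known limitations

- Per-group fits are independent; no parameter sharing or hierarchical
  (mixed-effects) structure across groups or genotypes, and no bootstrap
  uncertainty — standard errors are local Jacobian-based approximations,
  which are optimistic near degenerate optima.
- The generic parameters describe species-average behaviour;
  genotype-specific calibration is supported by the pipeline but no
  genotype-specific values are packaged.
- Thermal-time leaf appearance, senescence, tillering and canopy-level
  integration (LAI) are out of scope: the package predicts mature
  per-leaf dimensions only.
- The bell-shaped baseline (`bell_leaf_area()`) is provided for
  comparison, not fitted by the pipeline.
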