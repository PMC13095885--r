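# leafprofile

Individual leaf size profiles for maize, sorghum and pearl millet.

Crop growth models need the area of every leaf on the main culm to
simulate light interception, biomass accumulation and transpiration,
especially early in the season when the canopy is still open. `leafprofile`
predicts blade length, blade width and leaf area for each main-culm leaf
position from a single whole-plant covariate — the total leaf number (TLN)
— replacing the classical one-equation bell-shaped leaf-area curve with a
mechanistically richer description of the two blade dimensions. The
package is aimed at crop modellers and phenomics groups who need either
ready-to-use species-generic parameters or a calibration pipeline for
their own genotypes.

## The model

Blade length or width `y` (mm) at leaf position `x` (counted from the
bottom; position 1 is the coleoptile leaf, position TLN the flag leaf)
follows a three-phase expolinear–logistic curve:

- rising phase (`x < xs`):
  `y = L1 + (cm/rm) · ln(1 + exp(rm·(x − tb − 1)))` — exponential growth
  at rate `rm` blending into a straight line of slope `cm`, starting from
  the first-leaf size `L1`;
- maximum: `Ymax = y(xs)` at the (real-valued) largest-leaf position `xs`;
- falling phase (`x ≥ xs`):
  `y = Ymax·Yslevel / (Ymax + (Yslevel − Ymax)·exp(dr·(x − xs)))` with
  `Yslevel = Ymax + dsl`, a logistic decay at rate `dr` toward the flag
  leaf.

Leaf area is `length × width × shape factor`, with factor 0.71 for
ordinary leaves and 0.635 for the flag leaf. Two parameters depend on TLN:
the largest-leaf position `xs` (linearly for maize and pearl millet;
segmented with a breakpoint at TLN 20.5 for sorghum) and the decay rate
`dr` (declining linearly up to a species breakpoint, constant beyond).
The remaining five parameters (`L1, cm, rm, tb, dsl`) are fixed per
species and trait. Packaged species-generic values, with standard errors,
ship in `inst/extdata/species_params.yaml` and load via
`default_species_params()`.

The calibration pipeline mirrors how such generic values are estimated:
observations are grouped by genotype × TLN, each group is fitted by
Levenberg–Marquardt nonlinear least squares, fixed parameters are pooled
across groups, and the per-group `xs` and `dr` estimates are regressed on
TLN (with a robust bivariate outlier screen on the `dr` estimates, which
are unstable for low-TLN plants). A seeded synthetic-data generator
produces measurement panels with the structure of real multi-genotype
campaigns so the whole pipeline can be exercised as a parameter-recovery
experiment.

## Worked example

Predict a full profile for a sorghum plant with 18 leaves:

```r
library(leafprofile)
set  <- default_species_params("sorghum")
prof <- predict_profile(set, tln = 18)
round(prof[c(1, 2, 9, 12, 18), ], 1)
#>    tln position length_mm width_mm area_mm2 is_flag
#> 1   18        1      19.8      5.8     81.1       0
#> 2   18        2      27.2      7.0    135.3       0
#> 9   18        9     446.2     52.3  16555.7       0
#> 12  18       12     657.7     83.8  39142.2       0
#> 18  18       18     246.7     56.1   8786.2       1
```

The blade grows from a 19.8 mm coleoptile leaf to its maximum near
position 13 (`xs = 12.92` for this TLN, `Ymax ≈ 722.6` mm) and decays to a
246.7 mm flag leaf whose area uses the 0.635 flag factor.

Recover parameters from a noisy synthetic campaign (two genotypes, TLN
14–40, five plants per TLN, 5 % multiplicative measurement noise):

```r
sim <- generate_dataset(sim_config("sorghum", genotypes = c("A", "B"),
  tln_values = 14:40, plants_per_tln = 5,
  noise = list(model = "proportional", cv = 0.05), seed = 42))
cal <- calibrate_species(sim$records)
round(cal$params$traits$blade_length$fixed, 2)
#>    L1    cm    rm    tb   dsl
#> 15.97 71.44  1.52  1.99  5.23
round(unlist(cal$params$traits$blade_length$xs_rule), 3)
#>      a      b      c     bp
#>  4.999  0.442  0.261 20.509
```

The generating values were `cm = 70.5`, `rm = 1.56` and an xs rule of
`(4.64, 0.46, 0.26, 20.5)`: the linear-phase slope, exponential rate and
the segmented largest-leaf-position rule (including the free breakpoint)
are recovered closely from 90 observations per group
(`fit_profile` reports, e.g., `rmse 19.4 mm, R2 0.994` for one such
group).

A small CLI wraps the same functions
(`Rscript inst/cli/leafsize.R predict --species sorghum --tln 18 --out profile.csv`;
subcommands `predict`, `fit`, `calibrate`, `simulate`, `evaluate`).

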