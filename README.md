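# leafpigments

Non-destructive monitoring of leaf pigments from paired reflectance and
transmittance spectra.

Destructive pigment assays (ethanol extraction + spectrophotometry) give
accurate chlorophyll and carotenoid contents but consume the leaf. This
package implements the optical alternative for controlled-environment
plant experiments: measure the leaf's reflectance *R(λ)* and
transmittance *T(λ)* with an integrating sphere, then estimate the
pigment contents by constrained inversion of a physical leaf-optics
model. Alongside the estimator it provides the reference wet chemistry,
chlorophyll-fluorescence quenching indices, and the downstream study
analyses (unit conversion, modelled-vs-measured correlation, pigment
ratio time courses, growth summaries), plus a synthetic-data generator
that emulates a two-cultivar lettuce light-quality experiment so the
whole pipeline runs end to end with no instrument data.

## The model and estimator

The leaf is a stack of `N` identical absorbing plates (generalized plate
model, PROSPECT-D-style state). Per-plate absorption is the linear sum of
constituent contents times specific absorption coefficients,

> k(λ) = [C_ab·K_ab + C_car·((1−C_x)·K_V + C_x·K_Z) + C_anth·K_anth +
> C_brown·K_brown + C_w·K_w + C_m·K_m] / N,

where the xanthophyll-cycle de-epoxidation state C_x = (Z+A)/(Z+A+V)
convexly mixes a violaxanthin-like and a red-shifted zeaxanthin-like
carotenoid end-member. Plate R/T combine the beam transmissivity
θ(k) = (1−k)e^(−k) + k²E₁(k) with average Fresnel interface
transmissivities (40° cone above, isotropic inside); the `N`-plate stack
is solved with the analytic Stokes recurrences (non-integer `N`
continuous).

Inversion minimises ‖R_model−R_obs‖² + ‖T_model−T_obs‖² over 400–900 nm
subject to box bounds on all parameters and to the laboratory-observed
ratio band **4.4 < chl/car < 6.4**, imposed exactly by reparameterising
Ccar = Cab/ρ with ρ box-bounded. Optimisation is box-constrained
trust-region least squares from five seeded Latin-hypercube starts;
results are bit-reproducible given the seed.

## Worked example

Simulate a leaf with known pigments, add 1% measurement noise, and
recover it:

```r
library(leafpigments)

lib   <- build_synthetic_library(seed = 1)
truth <- leaf_biophysics(N = 1.6, Cab = 45, Ccar = 45 / 5.2,
                         Canth = 2, Cx = 0.3)
obs <- forward_model(truth, lib)
set.seed(1)
obs$reflectance   <- obs$reflectance   * (1 + rnorm(nrow(obs), 0, 0.01))
obs$transmittance <- obs$transmittance * (1 + rnorm(nrow(obs), 0, 0.01))

fit <- invert_spectrum(obs, lib, inversion_config(seed = 1))
tidy(fit)
#> # A tibble: 8 × 6
#>   term   estimate  lower  upper at_lower at_upper
#>   <chr>     <dbl>  <dbl>  <dbl> <lgl>    <lgl>
#> 1 N       1.60    1        3.5  FALSE    FALSE
#> 2 Cab    45.0     0.1    120    FALSE    FALSE
#> 3 Ccar    8.70    0.02    30    NA       NA
#> 4 Canth   2.01    0       40    FALSE    FALSE
#> 5 Cx      0.293   0        1    FALSE    FALSE
#> 6 Cbrown  0       0        1    TRUE     FALSE
#> 7 Cw      0.0104  0.0001   0.05 FALSE    FALSE
#> 8 Cm      0.00399 0.001    0.02 FALSE    FALSE
glance(fit)$chl_car_ratio
#> [1] 5.175479
```

Despite the noise, the chlorophyll estimate is within ~0.1% of the true
45 µg cm⁻², anthocyanin within 1%, and the estimated chl/car ratio
(5.18) stays inside the admissible band. `autoplot(fit)` overlays the
fitted spectra on the measurements.

The published growth-response table reproduces its stated pooled-PFD
fresh-weight changes:

```r
pfd_effect_summary(growth_table(), traits = "fresh_weight_g")
#> # A tibble: 2 × 5
#>   cultivar trait          pooled_low pooled_high pct_change
#>   <chr>    <chr>               <dbl>       <dbl>      <dbl>
#> 1 CV_g     fresh_weight_g       10.7        24.0         56
#> 2 CV_r     fresh_weight_g       14.1        24.4         42
```

A full synthetic factorial cohort (spectra, assays, fluorescence, stored
ground truth) comes from `generate_cohort(synthetic_design(seed = 1))`;
see the methods vignette (`vignettes/leaf-pigment-monitoring.Rmd`) for
the model, the design choices and what the synthetic tests do and do not
demonstrate.

## Command line

A thin wrapper over the package functions lives at
`inst/cli/leafpigments.R` with subcommands `simulate`, `invert`,
`wetchem`, `fluor` and `analyze`, reading and writing plain CSV.
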