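# condquant

Quantification of liquid–liquid phase separated (LLPS) protein condensates
and the microtubule asters they nucleate, from confocal fluorescence
microscopy. Built for in vitro studies of microtubule crosslinkers of the
MAP65/PRC1/Ase1 family, whose droplets concentrate tubulin, organize
microtubule bundles into asters, and age from liquid-like to gel-like over
hours — but the estimators are generic to condensate imaging.

The package is aimed at biophysicists quantifying condensate experiments:
it turns image stacks and FRAP traces into partition coefficients, size
laws, recovery kinetics, material properties and aster statistics, and it
ships a seeded synthetic-data generator so every estimator can be validated
by parameter recovery without any experimental data.

## What it computes

| Quantity | Model / estimator | Function |
|---|---|---|
| Partition coefficient | p = I_in / I_out (eroded mask / clean annulus) | `partition_coefficient()` |
| Droplet size statistics | empirical CDF fit to a normal CDF | `measure_diameter_cdf()` |
| Size vs concentration | y = a·x^b + c; critical concentration x* = (−c/a)^(1/b) | `fit_shifted_power_law()` |
| Contact angle | circle fit to the free boundary of an X–Z section | `contact_angle()` |
| FRAP kinetics | I(t) = F_m(1 − e^(−t/τ)); τ½ = τ ln 2; D_app = r²/τ½ | `fit_single_exponential()`, `apparent_diffusion()` |
| Biphasic recovery | A(1 − e^(−t/τ₁)) + B(1 − e^(−t/τ₂)), τ₁ < τ₂ | `fit_biphasic()` |
| Aging | F(t) = F∞ + A·e^(−t/τ_age) | `fit_aging()` |
| Internal diffusion | erf-edge width growth σ²(t) = σ0² + 2·D_in·t | `fit_radial_diffusion()` |
| Viscosity | η = k_B·T / (6π·D·R_h) | `stokes_einstein_viscosity()` |
| Volume conservation | V₃ vs V₁+V₂ through-origin slope | `fusion_volume_regression()` |
| Coalescence | AR(t) = 1 + (AR₀−1)·e^(−t/τ_c); τ_c = (η/γ)·ℓ | `coalescence_relaxation()`, `surface_tension()` |
| Aster projections | circular peak-prominence counting on an annulus | `count_projections()` |
| Projection scaling | N = α·d² + β·d + δ | `fit_projection_scaling()` |

Each analysis has a matching generator (`gen_droplet_stack()`,
`gen_frap_trace()`, `simulate_frap_field()`, `gen_fusion_series()`,
`gen_fusion_events()`, `gen_aster_image()`, `gen_diameter_samples()`,
`gen_contact_cap()`) that records full ground truth and is bit-reproducible
under a seed.

## Worked example

Generate a synthetic confocal stack of one condensate with a generating
enrichment ratio of 20.5, segment it, and measure the partition
coefficient; then fit a noiseless FRAP trace:

```r
library(condquant)

stack <- gen_droplet_stack(radii = 1.5, centers = c(3.2, 3.2, 2),
                           partition_ratio = 20.5, seed = 3)
drops <- segment_droplets(stack)
drops
#>   label     x_um     y_um    z_um diameter_um volume_um3 eq_z border
#> 1     1 3.097044 3.098774 2.00036    2.987542      13.87    5  FALSE
partition_coefficient(stack, drops)
#> <partition_result> p = 20.3 +/- NA (SEM), n = 1 droplets

fit_single_exponential(gen_frap_trace(tau_half = 27.16,
                                      mobile_fraction = 0.62, noise_sd = 0))
#> <frap_fit> tau_half = 27.16 s, mobile fraction = 0.62, Dapp = 0.01114 um^2/s

fit_aging(c(1, 2, 3, 4, 4.5), c(0.62, 0.25, 0.16, 0.14, 0.13))
#> <aging_fit> tau_age = 0.714 h, F_inf = 0.13 (F0 = 2.12)
```

The segmented diameter (2.99 µm vs the generating 3.0 µm) and recovered
p (20.3 vs 20.5) illustrate the pipeline's accuracy at realistic noise;
the aging fit shows condensate mobility decaying with a ~0.71 h time
constant toward a ~13% residual mobile fraction.

See the vignette (`vignettes/condensate-quantification.Rmd`) for the full
model descriptions, parameter conventions and numerical choices.

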