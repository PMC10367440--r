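---
title: "Quantifying protein condensates, their aging, and the asters they nucleate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein condensates, their aging, and the asters they nucleate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condquant)
```

## The system and the measurements

Microtubule-crosslinking proteins of the MAP65/PRC1/Ase1 family undergo
liquid–liquid phase separation (LLPS) in vitro: above a critical
concentration the protein demixes into micron-scale droplets. These
condensates concentrate tubulin, nucleate microtubule bundles, and organize
them into asters whose arm number tracks droplet size. Over hours the
droplets *age* from liquid-like to gel-like, which shows up as slowing FRAP
recovery and arrested fusion. `condquant` implements the quantitative
pipeline for all of these readouts:

* droplet segmentation and sizing from confocal z-stacks;
* partition coefficients \(p = I_\mathrm{in}/I_\mathrm{out}\);
* FRAP kinetics — halftimes, mobile fractions, apparent and internal
  diffusion coefficients, aging time constants, biphasic recovery;
* rheology — Stokes–Einstein viscosity, fusion volume conservation,
  coalescence relaxation, surface tension;
* aster projection counting and its quadratic scaling with diameter.

Because raw experimental stacks are large and instrument-specific, the
package pairs every analysis operation with a seeded synthetic generator
that emulates the corresponding experiment and records its ground truth.
Every stage is validated by parameter recovery: generate with known
parameters, analyze, compare.

## Image model and segmentation

A synthetic stack (`gen_droplet_stack()`) renders spherical droplets of
interior:exterior intensity ratio \(p\) on a uniform background, convolves
with a separable anisotropic Gaussian PSF \((\sigma_{xy}, \sigma_z)\), and
applies Poisson shot noise plus Gaussian read noise (sd 2 counts by
default). This is deliberately minimal optics — no diffraction rings or
aberrations — sufficient for testing recovery of ratios and geometry, not
for instrument simulation.

`segment_droplets()` smooths with a 1-pixel Gaussian, thresholds with a
single global Otsu threshold per stack (parameter-free and adequate for
high-contrast droplets), fills holes, splits touching droplets by watershed
on the plane-wise distance map, and links planes into 3-D components. Two
conventions matter downstream:

* **Diameter** is the equivalent-circle diameter of the component's
  maximum-area (equatorial) plane — the 2-D confocal-slice convention —
  while **volume** is the full 3-D voxel volume, used by the fusion
  analysis where volumes are the physical claim.
* **Border-touching components are flagged and excluded** from size
  statistics: censored sizes bias the distribution.

A uniform image must segment to nothing, so a contrast guard requires the
threshold to clear the background noise floor (median + 5 MAD) before any
component is accepted.

For partitioning, the interior mean uses the mask eroded by 2 px and the
exterior mean an annulus 3–6 px beyond the boundary with all droplet masks
excluded; both choices keep the PSF-blurred rim out of both averages.
Intensities enter only as ratios, so the measure is invariant to global
intensity scaling. Coordinates are 0-based at pixel centres and all
user-facing lengths are in micrometres.

## Size distributions and the critical concentration

`measure_diameter_cdf()` fits the empirical CDF of droplet diameters to a
normal CDF by least squares; the fitted mean (= median of the symmetric
fit) is reported with SEM \(\sigma/\sqrt{n}\). The concentration dependence
of the median is fit by `fit_shifted_power_law()` with
\(y = a x^b + c\), weighted by \(1/\mathrm{sem}^2\) and multistarted over
\(b \in \{0.25, 0.5, 1, 2\}\) (with \(a, c\) seeded by linear regression at
each fixed \(b\)); the best converged start wins, so the solution residual
is never worse than any initialization. When \(c < 0\) the fitted law
crosses zero at \(x^* = (-c/a)^{1/b}\), which we take as the critical
concentration for phase separation; how to extract a critical concentration
from such a fit is genuinely open (zero crossing vs. detection-limit
crossing), and the zero crossing is the convention implemented here because
it needs no extra detection-limit parameter.

```{r powerlaw}
x <- c(0.05, 0.1, 0.5, 1, 5, 10, 14)     # uM
fit <- fit_shifted_power_law(x, 1 * x^0.5 - 0.22)
fit$critical_concentration                # 0.0484 uM = 48.4 nM
```

## FRAP: normalization and kinetics

Traces are normalized (`normalize_trace()`) by background subtraction,
optional reference-ROI division (photofade correction), then the affine map
that puts the prebleach mean at 1 and the bleach frame at 0, re-zeroing
time at the bleach. The operation is idempotent and invariant to positive
affine transforms of the raw intensities. The bleach frame, when not given,
is the minimum within 3 frames after the largest single-frame drop.

Recovery is fit (`fit_single_exponential()`) with
\(I(t) = F_m (1 - e^{-t/\tau})\), the standard single-exponential FRAP
form; \(\tau_{1/2} = \tau \ln 2\). The mobile fraction is the plateau of
the *fitted model*, not the last data point, which is robust to truncated
acquisitions. Fits are bounded trust-region least squares
(`minpack.lm::nlsLM`), multistarted over three decades of \(\tau\), ties
broken by residual. The apparent diffusion coefficient is the operational
estimator \(D_\mathrm{app} = r^2/\tau_{1/2}\) with bleach radius
\(r = 0.55\) µm by default — deliberately *not* the Soumpasis
\(0.224\, r^2/\tau_{1/2}\), so that values are comparable with the
condensate literature that uses the simple ratio; the bleach radius itself
can be measured from the first post-bleach image by an inverted-Gaussian
radial fit (`estimate_bleach_radius()`, \(r = \sigma\sqrt{2\ln 2}\)).

```{r frap}
tr <- gen_frap_trace(tau_half = 27.16, mobile_fraction = 0.62, noise_sd = 0)
fit_single_exponential(tr)
```

Aging is quantified by fitting mobile fraction versus maturation time with
\(F(t) = F_\infty + A e^{-t/\tau_\mathrm{age}}\), \(F_\infty \in [0,1]\),
\(A \ge 0\) (`fit_aging()`). The amplitude is left free rather than
bounding \(F_0 = F_\infty + A\) by 1: the first observation typically lies
an hour after mixing, and constraining the back-extrapolated intercept to
the physical range distorts the decay constant (with the bound active,
the five tabulated points fit to \(\tau \approx 1.5\) h instead of the
\(\approx 0.71\) h the data actually decay with).

Two-component recovery (tubulin in condensates: fast boundary exchange plus
slow interior mixing) is fit by `fit_biphasic()` with
\(I(t) = A(1 - e^{-t/\tau_1}) + B(1 - e^{-t/\tau_2})\), \(\tau_1 < \tau_2\)
enforced by reordering, compared to the nested single exponential by AIC,
and flagged "effectively monophasic" when \(\tau_1/\tau_2 > 0.8\) or one
amplitude vanishes.

## The diffusion forward model

`simulate_frap_field()` is the package's ground-truth FRAP physics: explicit
(FTCS) finite-difference diffusion of the mobile pool on a disk, immobile
pool static, bleach applied multiplicatively at \(t = 0\). The masked
no-flux stencil uses antisymmetric pairwise fluxes, so in closed mode total
mass is conserved to floating point (the tests assert 1e-9 per step — in
practice it holds to ~1e-15). The stability bound
\(\Delta t \le h^2/(4D)\) is enforced as an error, never silently clamped.
An exchange mode holds ghost cells at the unbleached exterior concentration
for whole-droplet bleaches, where recovery is influx from solution.

The simulator is cross-checked against an independent random-walk oracle
(Brownian particles with wall rejection) in the test suite: after matched
bleach and elapsed time the two fields agree to within 2% of the dynamic
range (2×10⁵ particles, both fields smoothed identically to suppress
binning shot noise — at 10⁵ particles the shot noise alone would exceed the
comparison tolerance).

Whole-droplet bleach profiles are analyzed by `fit_radial_diffusion()`: each
radially averaged profile is fit with an error-function edge and the
squared edge width regressed on time, \(\sigma^2(t) = \sigma_0^2 + 2 D t\).
On simulated whole-droplet bleaches this recovers the generating \(D\) to a
few percent; the 1-D front model ignores cylindrical curvature, so
agreement within 20% is what the tests require.

## Rheology

Viscosity comes from Stokes–Einstein,
\(\eta = k_B T / (6\pi D R_h)\), with defaults \(R_h = 4.2\) nm (the
measured hydrodynamic radius scale of MAP65) and \(T = 295\) K (22 °C room
temperature; the tabulated viscosities are consistent with 295–298 K, so
the temperature is an explicit argument).

Fusion events supply the surface tension. `coalescence_relaxation()`
segments a two-droplet merge movie, takes pre-fusion volumes from the last
two-component frame, and fits the merged object's equatorial aspect ratio
with \(AR(t) = 1 + (AR_0 - 1)e^{-t/\tau_c}\). The fully relaxed tail, where
mask voxelization quantizes the aspect ratio, is dropped from the fit. For
liquid droplets \(\tau_c = (\eta/\gamma)\,\ell\) with proportionality
constant taken as 1 and characteristic length \(\ell\) the mean pre-fusion
radius — a convention, stated as such and configurable through the
generator; recovery tests are therefore self-consistent rather than
method-exact. The through-origin slope of \(\tau_c\) vs \(\ell\) is the
inverse capillary velocity, and \(\gamma = \eta/\mathrm{slope}\)
(Pa·s per s/µm = µN/m). Gel-like movies whose aspect ratio never relaxes
are flagged, not fitted, and excluded from the tension regression. Volume
conservation across events is checked by `fusion_volume_regression()`, the
zero-intercept regression of \(V_3\) on \(V_1 + V_2\).

The fusion *renderer* (`gen_fusion_series()`) is a geometric morph —
touching spheres to a relaxing prolate spheroid of exactly conserved
volume — not a hydrodynamic solve; only the relaxation law and volume
conservation are physical claims, which is all the analysis consumes.

## Asters

`gen_aster_image()` renders a bright droplet disk with tapered radial
ridges at jittered equal spacing, storing the exact arm angles.
`count_projections()` samples the z-maximum-intensity projection on a
circle at 1.3× the droplet radius in 1° bins, smooths over 3°, and counts
arms as circular local maxima by topographic prominence. Counting on the
maximum projection matters because arms leave any single plane. Two
thresholds make the count robust at both ends of the density range: an
absolute one (prominence ≥ 3× the noise level of the profile, estimated
from arm-free image corners with shot-noise scaling to the annulus
intensity, because the sub-pixel 1° samples are too correlated to estimate
noise from the profile residual) and a relative one (≥ 25% of the largest
prominence, which removes noise peaks without touching the shallowest true
arm). Peaks closer than 5° count as one arm — split bundles — and a profile
whose largest prominence is noise-sized counts zero. On a seeded battery of
100 asters with 0–30 arms and 3° jitter the count is exact in ≥ 95% of
cases, and the generator refuses configurations whose jittered spacing
falls below the 6° resolvability limit, advising fewer arms or a larger
droplet.

The arm number scales with droplet surface area, i.e. diameter squared;
`fit_projection_scaling()` fits the weighted parabola
\(N = \alpha d^2 + \beta d + \delta\) and with exactly three (diameter,
count) medians interpolates them exactly.

```{r asters}
fit_projection_scaling(c(1.04, 2.43, 3.08), c(2, 12, 28))
```

## Contact angles

Droplet wetting is measured from X–Z sections (`contact_angle()`): segment,
fit a circle to the free boundary (excluding the substrate rows) by
algebraic least squares, and take
\(\theta = \arccos((z_0 - z_c)/R)\) at the substrate plane. Synthetic caps
(`gen_contact_cap()`) with generating angles of 50° (bare glass, wetting)
and 130° (polymer brush, dewetting) are recovered within 5°, a hemisphere
within 3°.

## Numerical choices, problem sizes, limitations

* All generators take explicit integer seeds and restore the caller's RNG
  state; identical seed and parameters give bit-identical artifacts, and a
  serialized ground-truth record regenerates its artifact exactly.
* Nonlinear fits are multistarted and bounded; degenerate inputs (flat
  traces, constant medians, rising mobile fractions, unrelaxing fusions)
  return flagged results rather than errors wherever the flag is
  scientifically meaningful.
* Test problem sizes are chosen to exercise the estimators well inside
  their asymptotic regime while keeping the suite quick: 64×64×9 voxel
  partition stacks, 200 noisy FRAP traces, 10⁴-sample diameter CDFs,
  100-aster counting batteries, 2×10⁵-particle diffusion oracles.
* The synthetic data do not emulate photofade during acquisition (the
  correction path is exercised with constructed fades), uneven
  illumination, drift, or realistic optics; passing recovery tests
  demonstrates correctness of the estimators under the stated image model,
  not robustness to every instrument artifact.
* Acquisition noise levels are configurable, not calibrated to any
  instrument: the defaults (Poisson + 2-count read noise) are typical of
  sCMOS confocal imaging.
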