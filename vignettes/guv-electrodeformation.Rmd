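---
title: "Estimating membrane bending stiffness from GUV electrodeformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating membrane bending stiffness from GUV electrodeformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guvkappa)
```

## The model

Giant unilamellar vesicles (GUVs) are micron-scale single-bilayer vesicles
used as minimal models of the cell membrane. In an AC electric field a
quasi-spherical GUV deforms into a prolate spheroid (elongated along the
field). At low membrane tension the visible area gained comes from ironing
out thermally excited wrinkles, and this *bending regime* obeys a
log-linear law:

$$
\frac{\Delta A}{A_0} \;=\; \frac{k_B T}{8\pi\kappa}\,
\ln\!\frac{E_0^{2}}{H_{po}-H_{eq}} \;+\; c ,
$$

where $A_0 = 4\pi R_0^2$ is the area of the unperturbed vesicle,
$\Delta A$ the apparent area increase at field strength $E_0$,
$H_{po}$ and $H_{eq}$ the mean curvatures at the pole and the equator of
the deformed spheroid, $\kappa$ the bending stiffness, and $c$ a
frequency-dependent intercept. Fitting $\Delta A/A_0$ against the
regressor $x = \ln(E_0^2/(H_{po}-H_{eq}))$ over the bending regime gives a
slope $s$, and

$$\kappa = \frac{k_B T}{8\pi s}.$$

Everything in the package exists to produce, measure, and fit that line.

### Geometry and conventions

The deformed vesicle is a spheroid with semi-axis $a$ along the field and
transverse semi-axis $b$. Because the vesicle encloses an osmotically
trapped sucrose solution, deformation conserves volume: $a b^2 = R_0^3$.
`deform_at_fixed_volume()` inverts the area change under that constraint
(unique on each branch since area grows monotonically with aspect ratio
away from the sphere, which is the area minimizer).

Curvatures use the mean convention $H = (c_1+c_2)/2$, giving
$H_{po} = a/b^2$ and $H_{eq} = (b/a^2 + 1/b)/2$; for a prolate shape
$H_{po} > H_{eq}$. The choice of convention is immaterial for $\kappa$:
multiplying $H_{po}-H_{eq}$ by any positive constant shifts $x$ by an
additive constant that the intercept absorbs, leaving the slope unchanged.
The fit computes its slope from the centered regressor, so this invariance
holds at machine precision (`curvature_convention = "sum"` reproduces
$\hat\kappa$ to ~1e-16 relative). The same absorption covers the
dimensional constant left inside the logarithm when $E_0$ is taken in V/m
and curvatures in 1/m.

### The regressor couples to the response

Note that $x$ depends on the deformed shape, hence on $\Delta A/A_0$
itself. The synthetic generator therefore solves a fixed point for each
field strength: $d = s\,\ln(E_0^2/(H_{po}(d)-H_{eq}(d))) + c$. The
right-hand side decreases in $d$ (larger deformation, larger curvature
difference), so the root is unique; it is bracketed on
$d \in [10^{-8}, 0.2]$ and solved to $10^{-12}$.

## Study conditions emulated by the generator

`synthetic_config()` defaults encode the experiment the package emulates:

| parameter | default | meaning |
|---|---|---|
| `kappa_true` | 4.5e-19 J | pure-GUV bending stiffness (~110 $k_BT$) |
| `field_grid` | 20 log-spaced values, 100–20,000 V/m | AC field sweep; $E_0=0$ excluded from regression since $\ln E_0^2$ diverges |
| `frequency` | 100 kHz | AC frequency; physically enters only through $c$ |
| `T` | 298 K | room temperature |
| `R0` | 20.7 µm | mid-range vesicle radius (diameter 41.4 µm) |
| `pixel_size` | 0.145 µm/px | 40x phase-contrast scale; two pixels = 0.29 µm |
| `intercept_c` | calibrated | set so $\Delta A/A_0 = 0.03$ at 20 kV/m (small-deformation regime) |
| `noise_sd_dA` | 0.014 | measurement noise, *relative* (see below) |

The intercept is not physically constrained here — no tension prefactor or
frequency model is implemented — so it is calibrated once to put the
response in the small-deformation range and is never a recovery target.

### The noise model

An axis-length measurement carries a two-pixel deviation, 0.29 µm. To
first order a deviation $\delta$ on a diameter $D$ perturbs a sphere's
area by $2\delta/D$ relative — `propagate_pixel_error()` — which is 1.4%
for the default 41.4 µm vesicle. The generator applies this as a
*relative* Gaussian error on the area change: each point's sd is
`noise_sd_dA` × $\Delta A/A_0$, i.e. area-change values good to ±1.4%.

The alternative reading — an absolute sd of 0.014 on $\Delta A/A_0$
itself — is not usable as a study condition: across the default field
sweep the whole signal spans only $s \times \Delta x \approx 0.004$, so an
absolute 0.014 per-point error exceeds the entire dynamic range and no
estimator could recover $\kappa$ from a single series (the Cramér–Rao
bound puts the per-series spread near 300%). Since measured per-vesicle
stiffnesses of this type are reported with ~30% spread, the relative
reading is the one consistent with practice; the absolute variant remains
available via `noise_model = "absolute"`. Noise is injected into the
deformation and the stored semi-axes are recomputed from the noisy value,
so a noisy record is internally consistent: re-deriving $\Delta A/A_0$
from its own axes reproduces the stored number.

### What the renderer emulates — and what it does not

`render_vesicle_frame()` synthesizes the phase-contrast appearance of a
sucrose-filled vesicle in a glucose bath: a darker interior, a dark
membrane ring just inside the boundary, a bright halo just outside (the
refractive-index-mismatch artifact), and a mid-gray background. Edges are
analytic Gaussian profiles of the exact signed distance to the ellipse
(vectorized Newton on the eccentric angle near the boundary) — equivalent
to blurring the ideal image wherever the boundary curvature radius is
large against the blur sigma — followed by i.i.d. pixel noise. Contrast
levels are placed symmetrically about mid-gray so that a global Otsu
threshold crosses the rendered edge at the ground-truth boundary; the
round trip is therefore unbiased by construction rather than by tuning.

Not emulated: the true phase-contrast optical transfer function, thermal
flickering of the contour, field inhomogeneity, out-of-focus light,
multiple vesicles or debris per frame, and vesicle chains. Passing the
round-trip tests shows the measurement chain is internally consistent at
realistic contrast and noise; it does not certify performance on crowded
or defocused real micrographs.

## The measurement chain

`binarize()` applies a global Otsu threshold (dark side = foreground),
fills interior holes, and drops components below `min_area_px` (default
50 px, which suppresses noise speckle). `extract_contour()` traces the
largest component's boundary by marching squares at level 0.5, giving an
ordered closed sub-pixel polygon; components touching the frame edge are
flagged as truncated. `fit_ellipse()` is the direct algebraic
least-squares conic fit constrained to an ellipse, on centered and scaled
coordinates for conditioning.

A binary mask quantizes the boundary, and the resulting ±0.05 px axis
error is not white: its phase drifts smoothly as the shape grows across a
stack, which can tilt the fitted slope by ±20%. `segment_vesicle()`
therefore refines each contour point along the ellipse normal to the
sub-pixel threshold crossing of the bilinearly interpolated intensity and
refits (`refine = TRUE` by default; it falls back to the mask contour when
the local contrast does not bracket the threshold). With refinement the
imaging route recovers the generating stiffness to ~1–2%.

`measure_axes()` assigns the semi-axis along the field axis as $a$ and
defines $R_0$ from the zero-field frame as the *area-equivalent* radius of
the measured shape, which makes that frame's $\Delta A/A_0$ exactly zero;
the volume-equivalent alternative differs only at second order in the
residual ellipticity. Sizing uses the ImageJ convention: the
area-equivalent circle diameter (`equivalent_diameter()`, with the
geometric-mean-of-axes variant behind `method = "axes"`), histogrammed in
5 µm bins (left-closed, last bin closed).

## Selecting the bending regime

Real sweeps can leave the bending regime at high fields (tension takes
over and the response saturates), so the fit must find the log-linear
stretch. `select_bending_regime()` is deterministic:

1. If the whole series is already linear (R² ≥ 0.98) it is used outright.
2. Otherwise every contiguous window of ≥ 4 regressable records is
   scanned. A window *qualifies* if its R² ≥ 0.9 **and** its slope passes
   a two-sided t-test at level 0.05 Bonferroni-corrected for the number of
   windows scanned. The significance gate is what makes a pure-noise
   series fail cleanly: without it, scanning ~150 windows finds a
   spurious R² ≥ 0.9 stretch about half the time.
3. Among qualifying windows the maximum R² wins, but windows whose misfit
   $1-R^2$ is within twice the best misfit count as statistically tied —
   R² differences on that scale are sampling noise — and ties go to the
   longer, then lower-field window.

The tie rule matters. A strict max-R² scan is ill-posed across window
lengths: under any measurement noise, short windows that happen to look
steep and clean win, biasing $\hat\kappa$ low (a winner's curse; we
measured about −11% median bias without the rule). The multiplicative band
restores near-full windows on linear data while still cutting a saturating
tail exactly — on a noiseless change-point series the best misfit is zero,
so only perfectly linear windows tie and the longest of them is the
pre-saturation stretch.

Two properties of the gate are worth knowing. At the default noise level
the true slope's t-statistic sits almost exactly at the value implied by
the R² ≥ 0.9 qualifying bound, so (i) a substantial fraction of simulated
vesicles (~30%) report `non-deforming` — which mirrors the experimental
observation that some vesicles do not deform usably — and (ii) the
recovered-$\hat\kappa$ distribution is mildly truncated, leaving a few
percent of downward bias in the gated median. The estimator itself is
calibrated: with the regime supplied explicitly the median bias is below
2% (this is exercised in the test suite). A non-positive slope is always
reported as `non-deforming`, never as a negative stiffness.

## Uncertainties

The slope standard error combines the OLS residual estimate with a
pixel-measurement noise floor: the propagated area uncertainty
(× the mean response) mapped onto the slope through the regressor spread,
added in quadrature. $\kappa$'s uncertainty follows by the delta method,
$\sigma_\kappa = \kappa\,\sigma_s/s$. Across vesicles,
`aggregate_kappa()` reports the arithmetic mean and the $n-1$ sample sd of
the defined estimates and counts non-deforming vesicles separately.

## Numerical choices

- Spheroid areas use closed forms with series-guarded eccentricity factors
  ($\mathrm{asin}(e)/e$, $\mathrm{atanh}(e)/e$ expanded for $e^2 < 10^{-4}$),
  continuous and exact through the sphere; they agree with adaptive
  surface-of-revolution quadrature to better than 1e-8 relative over
  $a/b \in [1/5, 5]$.
- `deform_at_fixed_volume()` solves on the log aspect ratio with
  `uniroot` at tolerance 1e-14 and verifies the achieved area change to
  1e-10 relative (with an absolute floor of 1e-12 where the target is at
  roundoff scale).
- Degenerate inputs fail loudly: non-positive axes, constant frames, empty
  segmentations, fewer than 6 contour points, collinear point sets, series
  with fewer than 4 regressable records, and aggregation without a single
  defined estimate are all errors, not silent results.
- All randomness flows from explicit integer seeds through a
  save/restore wrapper, so generation never perturbs the caller's RNG
  stream and identical configurations are bitwise reproducible.

## Problem sizes

The packaged simulations use 50 deformation series for the tabular
recovery study, 5 rendered stacks of 15 frames (vesicle radius 100 px) for
the imaging route, 100 rendered shapes for the segmentation round trip,
and 700 diameters for the sizing study — sizes at which the Monte Carlo
error of the reported means is well below the tolerances being checked.

## Known limitations

- Only ellipsoidal shape modes are modelled; higher-order modes,
  electrohydrodynamic flows, and membrane viscosity are out of scope.
- One vesicle per stack; no multi-vesicle tracking or chain resolution.
- The intercept $c$ is a free parameter, not a frequency model; absolute
  values of $c$ are therefore not comparable across instruments.
- The tension (stretching) regime is only ever *excluded*, never fitted.
- The gated regime search trades a small, documented selection bias for
  robustness against spurious regimes; studies needing strictly unbiased
  per-vesicle estimates should fix the window explicitly.
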