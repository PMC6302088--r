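# guvkappa

Electrodeformation analysis of giant unilamellar vesicles (GUVs): estimate
the membrane bending stiffness κ from the deformation of vesicles in AC
electric fields, with a synthetic-microscopy module that makes every stage
of the pipeline testable against known ground truth.

## The science

A quasi-spherical GUV in an AC field elongates into a prolate spheroid. At
low membrane tension — the *bending regime* — the apparent area gained by
pulling out thermal wrinkles grows logarithmically with the electric
stress:

```
ΔA / A0 = kB T / (8 π κ) · ln( E0² / (Hpo − Heq) ) + c
```

where `A0 = 4π R0²` is the area of the unperturbed vesicle, `ΔA` the
apparent area increase, `E0` the field strength (V/m), `Hpo` and `Heq` the
mean curvatures at the pole and equator of the deformed spheroid (1/m),
`T` the temperature, `kB` the Boltzmann constant, and `c` a
frequency-dependent intercept. The slope `s` of ΔA/A0 against the
log-regressor gives the bending stiffness directly:

```
κ = kB T / (8 π s)
```

A pure-GUV experiment of this kind yields κ ≈ 4.5 × 10⁻¹⁹ J, the value the
package uses as its reference generating stiffness.

The package covers the full measurement chain:

- **geometry** — exact prolate/oblate spheroid areas, volumes, pole and
  equator curvatures, and the fixed-volume deformation map
  (`spheroid_area()`, `mean_curvature_pole()`, `deform_at_fixed_volume()`).
- **synthetic data** — forward-simulated deformation series with
  measurement noise, truncated-lognormal vesicle populations, and
  phase-contrast-like image stacks with ground truth
  (`generate_deformation_series()`, `generate_population()`,
  `render_series()`).
- **imaging** — Otsu binarization, sub-pixel contour extraction, direct
  least-squares ellipse fits, principal-axis series and size distributions
  (`binarize()`, `extract_contour()`, `fit_ellipse()`, `measure_axes()`,
  `size_distribution()`).
- **fitting** — bending-regime selection, the slope-to-κ conversion with
  uncertainties, pixel-error propagation, and per-vesicle aggregation
  (`select_bending_regime()`, `fit_kappa()`, `propagate_pixel_error()`,
  `aggregate_kappa()`).
- **reporting** — the simulate → (render → segment) → fit → summarize
  pipeline with CSV/TIFF/JSON artifacts (`run_pipeline()`).

## Worked example

Simulate one vesicle (radius 20.7 µm, 20 field steps from 100 to
20,000 V/m at 100 kHz, 1.4% measurement noise on the area change) and
recover its stiffness:

```r
library(guvkappa)

ser <- generate_deformation_series(synthetic_config(seed = 11))
head(as.data.frame(ser)[, c("E0_V_per_m", "a_um", "b_um", "dA_over_A0")], 4)
#>   E0_V_per_m     a_um     b_um dA_over_A0
#> 1   100.0000 26.92027 18.15164 0.02595801
#> 2   132.1621 26.98020 18.13147 0.02638566
#> 3   174.6681 26.92796 18.14904 0.02601282
#> 4   230.8450 26.96367 18.13702 0.02626751

fit_kappa(ser)
#> <kappa_estimate> kappa = 4.52e-19 +/- 4.5e-20 J (slope 0.000363, R2 0.928, 20 pts)
```

The fitted slope 3.63 × 10⁻⁴ converts to κ = 4.52 × 10⁻¹⁹ J, within one
standard error of the generating 4.5 × 10⁻¹⁹ J. The same estimate can be
obtained without ever touching tabular data, by rendering the vesicle as a
phase-contrast image stack and measuring it back
(`render_series()` → `measure_axes()` → `fit_kappa()`).

Vesicle sizing works the same way ImageJ-based counting does:

```r
d <- generate_population(700, seed = 1)     # diameters in [10, 60] um
size_distribution(d, bin_width = 5)
#> <size_distribution> n = 700, mean = 26.82 um, sd = 9.79 um, 10 bins
```

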