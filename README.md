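# aortapwv

Aortic stiffness from 4D flow cardiovascular MR: **pulse wave velocity
(PWV)** from time-resolved, three-directionally velocity-encoded velocity
fields, **distensibility coefficients (DC)** from 2D CINE series, and the
cohort statistics that turn per-subject measurements into age- and
sex-specific reference values. It is aimed at researchers processing
(or validating processors of) thoracic-aorta 4D flow data.

The core computation: after phase-unwrap and eddy-current correction, the
aortic lumen is segmented and a centerline is extracted between two seed
points; analysis planes are distributed normal to the centerline every
5 mm; the through-plane flow rate Q(t) is integrated on each plane; the
wave arrival time τᵢ at plane i (arc length sᵢ) is detected by

* time-to-foot (TTF): baseline ∩ regression line through the 20–80%
  upstroke,
* half-peak: first upstroke crossing of ½·(peak − baseline) above baseline,
* cross-correlation (XCor): sub-sample lag maximising the normalised
  cross-correlation against the most proximal plane,

and PWV is the inverse slope of the ordinary least squares fit τ ~ s:

    PWV = 1 / slope,   slope = dτ/ds        [τ in s, s in mm → PWV in m/s]

The local marker is DC = (2·Δd/Dd)/ΔP in 10⁻³/kPa, with the cross-section
tracked through the cardiac cycle by a multi-scale phase-based (quadrature
filter) registration and converted to an equivalent diameter d = 2·√(A/π).
The cohort layer fits the reference regression
`PWV = β₀ + β_age·age + β_male·male`, residual-adjusted correlations,
Bland–Altman limits of agreement, and paired Wilcoxon comparisons of the
three algorithms.

Because raw subject data are rarely shareable, the package includes digital
phantom generators (flow, CINE, cohort) with exact ground truth; the test
suite validates every stage against them.

## Worked example

```r
library(aortapwv)

# a digital aorta: candy-cane tube, true PWV 5 m/s, 20 ms frames
ph <- make_flow_phantom(phantom_spec(true_pwv = 5, seed = 1))
g  <- ph$geometry
est <- estimate_pwv(ph$field,
                    start_mm = candy_cane_point(g, 5)$point[1, ],
                    end_mm   = candy_cane_point(g, g$length - 5)$point[1, ])
for (m in names(est)) print(est[[m]])
#> <pwv_estimate> ttf: 5.03 m/s (R^2 = 0.996, 55 planes)
#> <pwv_estimate> half_peak: 5.03 m/s (R^2 = 1.000, 55 planes)
#> <pwv_estimate> xcor: 5.05 m/s (R^2 = 1.000, 55 planes)

# distensibility from a pulsating CINE phantom (Dd 24 mm, delta-d 2 mm)
cine <- make_cine_phantom(cine_phantom_spec(dd_mm = 24, delta_d_mm = 2, seed = 1))
edf  <- cine$truth$end_diastolic_frame
c0   <- circle_contour(edf, cine$spec$center_px,
                       cine$truth$d_mm[edf] / 2 / cine$spec$spacing_mm)
print(estimate_dc(cine$cine, c0, blood_pressure(120, 80),
                  end_diastolic_frame = edf))
#> <dc_result> ascending aorta: DC = 30.0 x 10^-3/kPa (delta d 1.92 mm, Dd 24.00 mm, dP 40.0 mmHg)

# cohort layer: simulate 126 subjects and refit the reference regression
cohort <- simulate_cohort(cohort_spec(seed = 1))
print(fit_reference_model(cohort))
#> <reference_model> PWV = 1.22 + 0.087*age + 0.43*male (m/s), sigma = 0.73, n = 126
#>   age x sex interaction p = 0.24
```

Reading the output: all three wave-arrival algorithms recover the phantom's
5 m/s within 1% (R² of the transit-time fit ≈ 1 on noise-free data); the
tracked DC of 30.0 × 10⁻³/kPa corresponds to the analytic
(2·2/24)/(40 mmHg → kPa) ≈ 31.3 with the tracked Δd of 1.92 mm vs the true
2 mm; and a single simulated cohort of 126 subjects reproduces the
generating coefficients (1.51, 0.080, 0.53) to within its own sampling
error.

A thin CLI over the same functions lives in `inst/cli/aortapwv.R`
(`estimate-pwv`, `estimate-dc`, `cohort-stats` subcommands, NIfTI + JSON
sidecar inputs).

## Package layout

* `R/synthetic-*.R` — phantom and cohort generators with ground truth
* `R/preprocess.R` — unwrapping, eddy-current correction, segmentation
* `R/centerline.R`, `R/planes.R` — geometry
* `R/flow-pwv.R` — waveforms, arrival detection, transit-time fit
* `R/registration.R`, `R/distensibility.R` — contour tracking and DC
* `R/cohort-stats.R` — reference model, adjusted correlations,
  Bland–Altman, Wilcoxon
* `R/io.R` — NIfTI + JSON sidecar, CSV, JSON result writers
* `vignettes/aortic-stiffness-pipeline.Rmd` — the methods notes (models,
  parameter choices, numerical findings, limitations)
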