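# pcmriflow

Quantitative hemodynamics of the aortic root from 2D cine phase-contrast
(velocity-encoded) cardiac MRI, for imaging scientists evaluating aortic-root
prostheses or native valve function. Given one imaging plane — a magnitude
stack plus three direction-encoded velocity stacks across ~100 cardiac
phases — the package reconstructs the volumetric flow waveform and the
standard flow, orifice and wall-elasticity metrics used to compare a
prosthetic valve-conduit against native controls.

## What it computes

With the through-plane velocity map `v(x, t)` (cm/s) over the segmented
lumen `Ω(t)` and pixel area `a` (cm²):

- **Flow waveform** `Q(t) = Σ_{Ω(t)} v · a` (ml/s), with `Q_max = max_t Q(t)`
  and `Q_mean` the whole-cycle time average;
- **Peak velocity** `V_max`: the maximum signed `v` over the lumen at the
  peak-flow frame;
- **Effective orifice area** `EOA`: the lumen area where `v` strictly
  exceeds the lumen-mean velocity at the peak-flow frame, plus its ratio to
  the lumen (sinus) area;
- **Wall elasticity** from the lumen-area waveform `A(t)` and a central
  pressure pair (Ps, Pd):
  - diameter `D = 2√(A/π)`,
  - compliance `(A_s − A_d)/(P_s − P_d)` (mm²/mmHg),
  - distensibility `((A_s − A_d)/A_d)/(P_s − P_d)` (mmHg⁻¹),
  - stiffness index `β = ln(P_s/P_d)/(D_s − D_d)` (cm⁻¹; the conventional
    `D_d`-normalized β is reported alongside);
- **Cohort comparison**: per-group mean ± SD with Mann–Whitney U
  (asymptotic and exact-enumeration p side by side) and Fisher's exact test
  for categorical variables.

Patient series are read from four NIfTI volumes plus a JSON sidecar (VENC
per axis, frame times, plane basis). Because raw clinical scans are rarely
shareable, the package includes a synthetic phantom generator
(`phantom_spec()` / `generate_phantom()`) producing a pulsating lumen with
plug, parabolic or Womersley velocity profiles, VENC-scaled 12-bit phase
encoding with aliasing, and a complete analytic ground truth for every
metric above.

## Worked example

```r
library(pcmriflow)

# noiseless phantom at acquisition resolution: 96 x 96 px of 1.4 mm,
# 100 phases, half-sine systole peaking at 500 ml/s, lumen 15 -> 16 mm
spec <- phantom_spec(noise_sd = 0)
ph   <- generate_phantom(spec)
res  <- analyze_series(ph$series, pressures = pressure_pair(131, 79))

res$flow
#> flow_waveform: 100 frames, Qmax 499.7 ml/s (frame 17), Qmean 105.0 ml/s
res$orifice
#> orifice_metrics: EOA 4.17 cm^2 of 8.25 cm^2 lumen (ratio 0.51), Vmax 124.3 cm/s
res$elasticity
#> elasticity_indices: As 8.25 / Ad 7.00 cm^2, Ds 3.24 / Dd 2.98 cm
#>   compliance 2412.3 (mm^2 mmHg^-1 1e-3), distensibility 3.45 (mmHg^-1 1e-3)
#>   beta 1.972 cm^-1 (as-printed), 5.885 (Dd-normalized)
```

`Qmax` recovers the prescribed 500 ml/s peak to 0.05 %; the EOA of a
full-lumen parabolic profile is half the lumen area (the `v > v̄` region is
`r < R/√2`), recovered here as a ratio of 0.51 against the analytic 0.50;
`Vmax` is the Poiseuille center velocity `2·Q/A`. The elasticity indices
match the values implied by the prescribed 15→16 mm radius pulsation and the
131/79 mmHg pressure pair.

Two small groups are compared the way clinical proof-of-concept tables are:

```r
mw <- mann_whitney(c(238, 209), c(240, 336, 340, 342))
#> U = 0, z = -1.852, p (asymptotic) = 0.064, p (exact) = 0.133
```

Both p-values are always reported: at n = 2 vs 4 they differ materially even
under full separation.

A six-subject per-case table (two controls, four recipients of a composite
valve-conduit prosthesis, from a published proof-of-concept study) ships
with the package:

```r
summarize_cohort(cohort_cases(), group_levels = c("control", "patient"))
```

## Command line

A thin wrapper over `run_pipeline()` lives at `inst/cli/pcmri.R`:

```sh
Rscript inst/cli/pcmri.R --config run.yaml --seed 1 --out results/
```

with YAML-configured tasks `simulate`, `validate`, `segment`, `analyze`,
`cohort`, `report` (exit codes: 0 ok, 2 validation, 3 computation).

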