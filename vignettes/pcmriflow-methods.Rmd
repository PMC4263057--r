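---
title: "Methods: phase-contrast flow quantification and aortic-root wall mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-contrast flow quantification and aortic-root wall mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmriflow)
```

## The measurement model

A 2D cine phase-contrast acquisition at one plane through the aortic root
yields, per cardiac phase, a magnitude image and three velocity-encoded
images (one per patient axis). Velocity is carried in the signal phase:
a velocity `v` along an encoding axis with encoding limit VENC maps to
`φ = π v / VENC`, so `|v| = VENC` reaches `±π` and anything faster wraps
(aliases). `pcmriflow` models raw storage as 12-bit signed integers,
`stored = floor(2048 φ / π)` in `[-2048, 2047]` with `-2048 ↦ -π`; the
decode `v = VENC · stored / 2048` then recovers any unaliased velocity
within one quantization step `VENC/2048`. Floor (rather than round-to-
nearest) quantization is deliberate: with rounding, velocities in the top
half-step below the VENC would round to `+π`, alias to `-π`, and break the
"lossless below VENC" guarantee. A second dialect, `velocity`, accepts
already-decoded cm/s stacks, since both conventions occur in exported
clinical data; the sidecar flag says which one a series uses.

The three decoded axis stacks form a velocity 3-vector per pixel. Projection
onto the plane basis (two in-plane axes plus the plane normal, orthonormal
in patient coordinates) gives the through-plane map used for flow and the
in-plane residual used for secondary-flow visualization; orthonormality
makes the split energy-preserving, `|v|² = v_⊥² + |v_∥|²`.

## From images to metrics

**Segmentation.** Bright-blood magnitude images separate lumen from
background well, so each frame is segmented independently with a
deterministic, parameter-light chain: Otsu threshold inside a user ROI,
connected component containing the seed point (largest if unseeded), hole
fill. Per-frame re-segmentation (rather than propagating one contour) is
required anyway to obtain the area waveform `A(t)`. Externally drawn masks
can be supplied verbatim. An optional circular 3-frame moving average of
`A(t)` exists for jittery segmentations; it is off by default because it
biases the systolic/diastolic extrema toward each other, which directly
shrinks every elasticity index.

**Flow.** `Q(t) = Σ_mask v_⊥ · a_pixel`, retrograde pixels included with
sign; `Q_max` is the temporal maximum (earliest frame on ties), `Q_mean`
the arithmetic mean over the full cycle including diastole. `V_max` is the
maximum signed through-plane velocity over the lumen at the peak-flow
frame; it keeps its sign, so a frame dominated by retrograde flow reports a
negative peak — surprising but honest.

**Effective orifice area.** EOA is the lumen area whose velocity strictly
exceeds the spatial mean velocity over the lumen at the peak-flow frame.
Two choices were genuinely open and are fixed as follows. The inequality is
strict, so an exactly uniform field has EOA 0 — a measure-zero degeneracy
on real data, documented rather than special-cased. The spatial mean is
taken over the full lumen with signs; retrograde rim pixels therefore lower
the threshold slightly. A `"positive"` averaging mode (antegrade pixels
only) is available for sensitivity analysis. The reported sinus area is the
PC-MRI lumen area at the peak frame, and the output labels it as such: a
sinus area measured on separate anatomic 3D imaging is a different quantity
and ratios built from the two sources are not interchangeable.

**Wall mechanics.** From `A(t)` in cm² and a central pressure pair in mmHg:
`D = 2√(A/π)`; compliance `(A_s − A_d)/(P_s − P_d)` in mm²/mmHg;
distensibility `((A_s − A_d)/A_d)/(P_s − P_d)` in mmHg⁻¹; stiffness
`β = ln(P_s/P_d)/(D_s − D_d)` in cm⁻¹. Two deliberate reporting choices:

- Clinical tables print compliance and distensibility under `·10⁻³` unit
  headers, i.e. the printed number is the raw value × 10³. Both scalings
  are emitted (`compliance` and `compliance_raw`); the package does not
  attempt to reconcile tables whose unit headers are internally
  inconsistent with their own printed magnitudes.
- The β above is the unnormalized form. The conventional stiffness index
  normalizes the diameter excursion by the diastolic diameter,
  `ln(P_s/P_d)/((D_s−D_d)/D_d)`, and typically lands in the 0.2–5 range
  rather than per-cm units. Published aortic-root β values around 0.2–0.5
  are much closer to the normalized convention, so both are always
  reported (`beta`, `beta_normalized`) and neither is silently substituted.

**Cohort statistics.** Mean ± n−1 SD per group (SD reported missing, not
zero, for single-subject groups); Mann–Whitney U with the tie-corrected
normal approximation *without* continuity correction, plus an exact
two-sided p by complete enumeration of the permutation distribution of U
whenever the pooled n is ≤ 12. The enumeration handles ties, where
classical exact tables do not. Both p-values are always shown: for 2-vs-4
groups under complete separation the asymptotic p is 0.064 while the exact
p is 2/15 ≈ 0.133, and which one a given software package prints is often
undocumented. Fisher's exact test uses the standard two-sided rule (sum of
hypergeometric probabilities ≤ the observed table's). Display rounding is
half-away-from-zero; raw doubles are retained.

## The synthetic phantom

Real velocity-encoded patient series are rarely depositable, so validation
rests on a generator whose every output quantity is known analytically.

**What it emulates.** A circular lumen (optionally with a concentric
stenotic jet) on a 96 × 96 grid of 1.4 × 1.4 mm pixels, 100 phases per
cycle — a typical aortic-root reconstruction; a half-sine systolic flow
lobe `Q(t) = Q_peak sin(πt/T_s)` with `Q_peak` 500 ml/s and systole a third
of an 880 ms cycle, giving `Q_max`/`Q_mean` in the physiological range
(and, via the closed form `Q_mean = (2/π)·Q_peak·s`, an exact oracle); wall
pulsation with the radius following the normalized flow waveform between 15
and 16 mm, so `A_s`/`A_d` ground truth is unambiguous and the area maximum
coincides with peak flow; plug, parabolic (Poiseuille) or Womersley
velocity profiles, each normalized so the continuum integral over the flow
cross-section equals `Q(t)` exactly; VENC defaulting to 1.1 × the true peak
velocity per axis (the usual prescription for avoiding aliasing while
preserving dynamic range); additive Gaussian velocity noise (default
5 cm/s) applied before encoding; and an optional plane tilt that moves
`sin(tilt)` of the velocity onto a known in-plane axis, to exercise the
decomposition.

**Womersley details.** The oscillatory profile uses the classical rigid-tube
solution per harmonic, with `J₀`, `J₁` of complex argument evaluated by
power series (no installed R package provides complex Bessel functions;
the series is numerically benign here because the argument lies on the
`e^{3πi/4}` ray where `|J₀|` grows exponentially and cancellation never
dominates — accurate to ~1e-10 for the physiological α range, α ≈ 10–25 at
the fundamental). Each harmonic's profile integrates to exactly that
harmonic of `Q`, and the Fourier coefficients are phase-shifted by half a
frame because samples sit at frame midpoints; together these make the
continuum flow reconstruction exact at every frame, so the pixel sum is the
only discretization error. As α → 0 the profile converges to Poiseuille,
which the tests verify pointwise at α ≈ 0.1.

**What it does not emulate.** Rician magnitude noise, eddy-current and
Maxwell-term phase offsets, partial-volume averaging at the wall (pixels
are classified by center), intra-voxel dephasing in jets, non-circular or
translating lumens, and 3D geometry. Passing recovery tests therefore
demonstrates the correctness of the *analysis chain* — decoding,
segmentation, integration, thresholding, index arithmetic — not robustness
to every artifact of clinical acquisitions.

## Numerical choices and problem sizes

- Pixel indexing is 1-based `(row, col)`, the native R convention, used
  consistently across masks, ROI boxes and seed points.
- Peak-flow frame and area extrema take the earliest frame on exact ties.
- Phantom recovery tolerances follow from discretization, not tuning: with
  the lumen radius ≥ 8 pixels, per-frame flow errs by well under 2 % of
  `Q_peak` for the parabolic and Womersley profiles (their wall velocity
  → 0, so boundary-pixel misclassification carries almost no flow). The
  plug profile carries full velocity at the wall, making its error the raw
  disc-area quantization (~3 % at 1.4 mm); its conservation test therefore
  runs at 0.7 mm pixels, where the same radius spans ~21 pixels.
- Wall-mechanics recovery is validated on a 0.7 mm reconstruction for the
  same structural reason: the observable is the *difference* `A_s − A_d`
  (~12 % of the area), and at 1.4 mm the one-pixel-ring granularity of two
  independently pixelized discs is of the same order as that difference.
  At 0.7 mm compliance, distensibility and β recover within 5 %, dominated
  by residual pixelization, as the acceptance checks compute.
- Test and acceptance problem sizes: 96 × 96 × 100 series (the default
  grid), smaller 64 × 64 × 40 variants for unit tests; these keep the whole
  suite in the tens of seconds while leaving every radius ≥ 8 pixels.
- The Otsu threshold is computed per frame on the ROI normalized to [0, 1],
  making segmentation invariant under positive affine intensity rescaling.

## Limitations

Single-plane 2D analysis only: no 3D reconstruction, no wall shear stress,
no pressure-gradient estimation, no regurgitant-fraction reporting. Central
pressures are inputs, not estimated from cuff oscillometry. The bundled
six-subject per-case table is provided for the cohort-summary machinery and
as a worked example; at n = 2 vs 4 its p-values are descriptive, not
confirmatory — the same caveat its source study attached to them.
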