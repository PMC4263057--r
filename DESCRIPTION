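Package: pcmriflow
Title: Phase-Contrast MRI Hemodynamics of the Aortic Root
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative hemodynamic analysis of velocity-encoded
    (phase-contrast) cine cardiac MRI at the aortic root: reading and
    writing velocity-encoded image series (NIfTI volumes with a JSON
    sidecar), VENC-based phase-to-velocity conversion, per-frame lumen
    segmentation of magnitude images, through-plane/in-plane velocity
    decomposition, volumetric flow waveform reconstruction, peak and mean
    flow, peak velocity, effective orifice area, and aortic-wall
    elasticity indices (compliance, distensibility, stiffness index
    beta). Includes a synthetic pulsatile-flow phantom generator with
    plug, parabolic and Womersley velocity profiles and known ground
    truth, and small-cohort group summaries with Mann-Whitney U and
    Fisher exact comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    stats,
    graphics,
    tools,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
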