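Package: vortrial
Title: Trial-by-Trial Climbing-Fiber Plasticity and VOR Gain Learning Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cerebellar motor-learning electrophysiology:
    trial-by-trial statistics linking climbing-fiber (complex-spike) activity to
    next-trial changes in Purkinje cell simple-spike output, with a
    matched-count bootstrap null; reciprocal-interval firing-rate estimation,
    moving-baseline subtraction, complex-spike probability histograms, pause and
    waveform (spikelet) metrics; eye-movement kinematics (zero-phase Butterworth
    filtering and differentiation, velocity-threshold saccade detection,
    excision and interpolation, retinal slip); sinusoid-fit vestibulo-ocular
    reflex (VOR) gain and percent-change learning with normality-gated group
    comparisons; and a synthetic Purkinje-cell / eye-movement session generator
    with implantable plasticity so that every stage is verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    emmeans,
    multcomp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
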