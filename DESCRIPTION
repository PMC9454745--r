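Package: gazelab
Title: Oculomotor and Spike-Train Quantification for Murine Gaze-Stabilization Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sinusoidal vestibulo-ocular reflex (VOR) and
    optokinetic reflex (OKR) experiments in mice: least-squares estimation of
    slow-phase gain and phase from desaccaded eye-velocity traces, iterative
    quick-phase (nystagmus fast phase) detection, saccadic main-sequence
    regression with the extra sum-of-squares F test, quantification of VOR
    gain-down motor learning, and inter-spike-interval regularity metrics
    (firing rate, CV, CV2) for Purkinje-cell recordings. Includes a synthetic
    cohort generator (sinusoidal stimulation, raised-cosine quick phases,
    gamma-renewal and burst-pause spike trains) with ground-truth logging, a
    mixed-design ANOVA and Mann-Whitney statistics layer, and report assembly.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
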