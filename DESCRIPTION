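Package: laminarGamma
Title: Laminar Gamma-Oscillation Analysis of Cortical Column Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for trial-structured laminar-probe recordings
    from visual cortex: current source density estimation by the spline
    inverse CSD (iCSD) method with a disc volume-conductor forward model,
    layer-III/IV border identification from the evoked sink/source polarity
    inversion and baseline CSD correlations, per-domain gamma-power hotspot
    detection with a gradient hidden-peak rule, dominant gamma-frequency
    estimation from trough-to-trough cycle periods of above-median-amplitude
    episodes, and bias-corrected phase-locking (PLV) profiles between hotspot
    CSD signals and entire spiking activity (ESA) or CSD signals across
    depth, together with the accompanying nonparametric statistics battery.
    Includes a synthetic cortical-column generator (three laminar gamma
    oscillators, evoked onset response, phase-locked spiking, correlated
    baseline activity, 1/f noise) providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, signal, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'session-io.R'
    'preprocess.R'
    'icsd.R'
    'laminar.R'
    'spectral.R'
    'hotspot.R'
    'gamma-frequency.R'
    'coherence.R'
    'synthetic-column.R'
    'stats-tests.R'
    'pipeline.R'
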