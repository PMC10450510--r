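Package: epicortex
Title: Spontaneous Population Activity, Single-Unit and Synapse Morphometry
    Analysis for Human Neocortical Slice Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis stack for in-vitro human neocortical slice experiments
    combining laminar multielectrode electrophysiology with anatomy.
    Characterizes spontaneous population activity (SPA) events across
    pharmacological epochs (recurrence frequency, baseline-corrected
    event-triggered LFP-gradient and multiunit-activity amplitudes),
    classifies sorted single units into principal-cell and interneuron types
    from waveform halfmax width and autocorrelogram shape, quantifies firing
    rate, burstiness and interspike-interval variability, classifies
    SPA-locked firing modulation with a Granger-causality screen, infers
    putative mono- and polysynaptic connections from crosscorrelogram peaks,
    counts immunostained cell bodies in brightfield micrographs, and runs the
    contingency and group statistics used for electron-microscopic synapse
    morphometry. A ground-truthed synthetic-data generator reproduces the
    statistical structure each stage assumes, so every detector and estimator
    is validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, EBImage
Suggests: testthat (>= 3.0.0), lmtest, jsonlite, png, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'core_io.R'
    'synthetic_units.R'
    'synthetic_spa.R'
    'synthetic_image.R'
    'synthetic_synapses.R'
    'spa_metrics.R'
    'classify.R'
    'firing.R'
    'modulation.R'
    'connectivity.R'
    'cell_counting.R'
    'normality.R'
    'synapse_stats.R'
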