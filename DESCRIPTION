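Package: sfcoupling
Title: Structure-Function Coupling of Intracranial LFP and Sensor-Array Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates electrophysiological functional connectivity with
    tractography-derived structural connectivity. Provides multitaper
    cross-spectral density and coherence estimation, DICS (Dynamic Imaging of
    Coherent Sources) beamformer coherence imaging against an intracranial
    reference channel, streamline tract-density imaging, a voxel-wise general
    linear model with voxel-specific design matrices and cluster-based
    permutation family-wise error inference, and nonparametric spectral
    Granger causality (Wilson spectral matrix factorization) with
    time-reversal surrogate testing of directionality. A synthetic-cohort
    generator with known ground-truth structure-function coupling makes every
    stage testable without access to patient recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    RNifti,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
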