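Package: eegnorm
Title: Normative Mapping and Abnormality Lateralisation for Scalp EEG Band Power
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building normative maps of regional scalp EEG relative
    band power and scoring patient abnormality against them. Implements the
    full sensor-to-map pipeline: resampling, zero-phase band-pass filtering,
    common average referencing, ECG-guided signal-space projection of cardiac
    artifact, sLORETA source localisation with sign-flip ROI averaging, Welch
    spectral estimation, relative band power in the five classical bands, and
    cohort-level z-score lateralisation of temporal-lobe abnormality. Includes
    a fully synthetic data generator (leadfields, parcellations, healthy and
    temporal-lobe-epilepsy cohorts with known planted band-power profiles) so
    that every stage is testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    jsonlite,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
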