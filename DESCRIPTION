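Package: pulsedi
Title: Similarity of Intracranial Pressure and Cerebral Arterial Blood
    Volume Pulse Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for quantifying the similarity between intracranial
    pressure (ICP) pulse waveforms and cerebral arterial blood volume
    (CaBV) pulse waveforms estimated from transcranial Doppler cerebral
    blood flow velocity (CBFV) via the constant flow forward model.
    Includes a ground-truth-annotated synthetic neuromonitoring signal
    generator, signal preprocessing (linear upsampling, zero-phase
    low-pass filtering, moving means), multiscale pulse-onset detection,
    automated pulse quality control, per-pulse difference-index scoring,
    ICP plateau-wave detection with baseline/plateau period selection,
    and paired nonparametric comparison of periods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
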