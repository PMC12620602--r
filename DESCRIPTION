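Package: dims2
Title: Chimeric Spectrum Deconvolution for Stepped-Isolation Direct-Infusion Tandem MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deconvoluting chimeric MS2 spectra acquired by direct
    infusion with a stepwise-moving isolation window. Co-isolated isobaric
    precursors are separated by exploiting the intensity modulation that the
    imperfect band-pass isolation filter imposes as its centre steps across
    the precursor region: fragments are assigned to precursors by Pearson
    correlation of their per-scan intensity profiles. Includes acquisition
    plan construction, mzML/MGF/MSP input and output, a synthetic scan-series
    simulator with known ground truth, and evaluation metrics (cosine
    similarity, intensity-weighted precision and recall, NCE50, modulation
    profile distance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    mzR,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
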