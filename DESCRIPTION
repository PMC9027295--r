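Package: mrmdeiso
Title: Chromatogram-Level Deisotoping for LC-MRM-MS Data
Version: 0.1.0
Authors@R:
    person("MRM", "Tools", email = "mrmtools@example.org", role = c("aut", "cre"))
Description: Processing of liquid chromatography multiple-reaction-monitoring
    mass spectrometry (LC-MRM-MS) chromatograms with transition-level
    (MS2-level) isotopic interference correction. Computes aggregated
    isotopologue distributions for precursor/product ion formulae, discovers
    source-to-affected interference relations among MRM channels, and removes
    interfering isotopic signals by cascaded chromatogram subtraction.
    Includes mzML and tabular chromatogram input, compound-library channel
    annotation, anchor-based retention-time alignment, background-subtracted
    area-under-curve integration, and a scheduled-MRM simulator with a
    forward interference model for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
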