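Package: earspan
Title: Life-Course Biophysics and Transcriptomics of the Drosophila Antennal Ear
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for age-related hearing loss in the Drosophila
    antennal ear. Simulates and fits free-fluctuation recordings of the antennal
    sound receiver (damped harmonic oscillator spectra; best frequency, quality
    factor and active energy gain in kBT units), fits two-population gating-spring
    models to dynamic stiffness curves and sigmoidal compound-action-potential
    response curves, screens gene-by-age count matrices for age-variable
    expression with a negative-binomial pairwise test and fold-change/FDR
    filtering, computes gene-ontology enrichment scores and ortholog-panel
    overlap tables, performs delta-delta-Ct relative quantification of qPCR
    plates, and analyses sound-evoked locomotor activity and cohort survival.
    Seed-deterministic synthetic-data generators emulate every input so the whole
    pipeline is testable without instrument recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
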