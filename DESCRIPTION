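Package: phenora
Title: Rule-Based Rheumatoid Arthritis Phenotyping for Primary-Care EHR Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies highly probable rheumatoid arthritis (RA) cases in
    CPRD-style coded primary-care records using a two-criterion diagnostic
    algorithm: an RA diagnosis code plus a disease-modifying antirheumatic
    drug (DMARD) prescription with no alternative indication, or repeated RA
    codes with a strong-severity code and no superseding alternative
    diagnosis. Provides code-dictionary loading and validation, incident
    cohort selection by first-RA-code window, per-patient classification with
    auditable evidence, a constructive synthetic cohort generator with exact
    ground-truth labels, and stratified fulfilment reporting with
    homogeneity tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
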