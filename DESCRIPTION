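Package: rtqa
Title: Radiotherapy Quality Surveillance Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for radiotherapy quality surveillance:
    reading and writing the DICOM-RT triplet (structure set, dose, plan),
    TG-263 structure nomenclature standardization, dose-volume histogram
    computation with standard metrics (Dx%, Dx cc, Vx Gy, Dmean, Dmax, Dmin),
    dose-constraint grading (pass / acceptable variation / fail), discrete
    clinical templates with validation, auto-population and narrative
    round-tripping, decision-tree clinical quality measures, de-identification
    with consistent pseudonymization and integrity sealing, and practice-level
    benchmarking with exact binomial outlier flagging. Includes a synthetic
    data module that generates geometric phantoms, analytic dose fields and
    template-conformant patient records so every component is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    jsonlite,
    digest,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
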