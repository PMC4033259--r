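Package: niarch
Title: Neuroimaging Data Sharing Toolkit: DICOM De-Identification,
    Archiving and Quality Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained toolkit for preparing and sharing
    neuroimaging data. Discovers classic DICOM files on disk, groups
    them into subjects, sessions and scans, removes a fixed profile of
    protected (potentially identifying) header fields, annotates data
    with sharing identifiers, and ingests it into a local
    project/subject/session/scan archive that validates anonymization
    and labels on arrival. Archived scans are converted to NIfTI-1 and
    passed through native quality-assessment procedures: region
    intensity statistics and signal-to-noise ratio for structural
    scans, per-timepoint summary traces and temporal SNR/SFNR for
    functional time series, and gradient-table sanity checks for
    diffusion series. A seeded phantom generator produces synthetic
    DICOM trees with ground truth for testing and reference
    distributions for report histograms.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    digest,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
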