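Package: aarcmr
Title: Multi-Parametric Cardiac MR Quantification of Infarct Size and
    Area-at-Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for multi-parametric cardiac
    magnetic resonance quantification of myocardial infarct size (IS) and
    area-at-risk (AAR) in small-animal ischemia-reperfusion studies.
    Provides a seeded digital short-axis phantom cohort generator
    (multi-echo spin-echo, Look-Locker inversion-recovery under
    slice-selective and global inversion, late gadolinium enhancement, and
    simulated histology labels), pixel-wise T2 and Look-Locker T1
    relaxometry, FAIR arterial-spin-labeling perfusion quantification with
    a blood-pool input function, normal-ROI standard-deviation threshold
    segmentation into putative AAR and infarct, planimetry, and the
    agreement statistics (Bland-Altman, paired and unpaired t-tests,
    one-way ANOVA with Bonferroni correction) used to compare imaging
    modalities against histology.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
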