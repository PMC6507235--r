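Package: trscore
Title: Tumor Roughness Scoring for Renal Mass CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the boundary irregularity ("roughness") of renal
    masses on contrast-enhanced CT. A three-stage pipeline enhances each
    slice (guided filtering, unsharp edge enhancement, image fusion),
    partitions the tumor region by alpha-trimmed multilevel thresholding
    that maximizes between-class variance, and estimates a box-counting
    fractal dimension from the edge points of every intensity level; the
    per-level slopes are averaged into a Tumor Roughness Score (TRS).
    Includes synthetic tumor phantoms with controllable boundary roughness,
    classical fractal fixtures with known box dimension for validation, and
    a cohort-statistics layer (one-way ANOVA with LSD post hoc tests,
    Pearson correlation, multivariable linear regression, demographic
    summary tables).
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
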