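Package: ccfpet
Title: CT-Based Spatial Normalization and Regional Quantification for Mouse Brain PET-CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolbox for quantitative analysis of mouse brain PET-CT studies
    in the Allen Common Coordinate Framework (CCFv3). Provides NIfTI/NRRD volume
    handling on physical grids, construction of volume-of-interest (VOI) label
    atlases from the hierarchical Allen ontology with bilateral splitting and
    morphological erosion, deterministic rigid and low-frequency elastic (cosine
    basis) registration engines, two-stage MR/CT/PET template construction, a
    root-mean-squared displacement metric for comparing CT-based against
    MR-based normalization pipelines, and regional uptake statistics (SUV
    conversion, cerebral global-mean scaling, paired t tests with
    Benjamini-Hochberg false-discovery-rate control). A seeded synthetic
    mouse-head phantom supplies CT/MR/PET triplets with known ground-truth
    deformations and paired cohorts so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
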