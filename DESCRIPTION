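Package: surfqc
Title: Quality Control for Cortical Surface Reconstructions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for visual and automated quality control of
    FreeSurfer-style cortical surface reconstructions. Generates multi-view
    snapshot images of a T1 volume with white and pial surface contours
    overlaid, runs anonymized rating sessions and aggregates categorical
    ratings into a continuous per-participant quality score, computes
    inter-rater reliability (Spearman, two-way agreement ICC), derives
    Euler-characteristic topology metrics from surface meshes, and provides
    a mixed-model analysis battery quantifying the impact of image quality
    on regional cortical morphometry and on case-control comparisons under
    several quality-handling strategies. A synthetic module generates
    phantom subjects and simulated cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    digest,
    png,
    RNifti,
    lme4,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
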