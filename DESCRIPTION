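Package: neglectVLSM
Title: Voxel-Lesion Symptom Mapping of Lateralised Visuospatial Neglect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for mass-univariate lesion-behaviour
    mapping of egocentric and allocentric visuospatial neglect. Scores
    Hearts-type cancellation sheets into continuous severities (centre of
    cancellation, lateralised false-positive proportion) and categorical
    impairment labels; runs voxelwise one-tailed pooled-variance t-tests on
    binary lesion masks with a minimum-overlap filter, lesion-volume
    residualization and Bonferroni family-wise control; and post-processes
    statistic maps (hemispheric mirror-homologue comparison, thresholded-map
    overlap, atlas-based cluster description). Includes a synthetic-cohort
    simulator with implanted ground truth so every stage is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
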