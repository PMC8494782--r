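Package: emphyCT
Title: Quantitative Emphysema Assessment from Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies pulmonary emphysema from volumetric chest CT.
    Reads NIfTI and NRRD volumes, segments the lungs by attenuation
    thresholding and connected components, divides each lung into three
    cranio-caudal thirds, classifies parenchymal patterns (emphysema,
    normal, ground-glass opacity, crazy-paving/linear opacities,
    consolidation) with a percentile-feature feed-forward neural network,
    and computes emphysema indices adjusted to the measured CT lung volume
    or to the predicted total lung volume of a healthy supine subject,
    alongside low-attenuation-area (-950 HU) densitometry. Includes
    regional (lung-thirds) distribution analysis, agreement and
    association statistics (Bland-Altman, Spearman, paired t, one-way
    ANOVA with Bonferroni post-hoc), and a seeded synthetic CT phantom
    generator with voxel-level ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0),
    nnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'emphyCT-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'roi-dataset.R'
    'ann-classifier.R'
    'cohort-stats.R'
    'lung-regions.R'
    'quantification.R'
    'volume-io.R'
    'phantom.R'
    'regional-analysis.R'
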