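Package: cki
Title: Central Kinase Inference from Paired Transcriptomic and Phosphoproteomic Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ranks protein kinases that are potentially central to a biological
    transition by integrating three evidence channels across all pairwise sample
    comparisons: differential mRNA expression of the kinases themselves,
    Yates-corrected chi-squared tests on per-kinase total substrate intensity
    (square-root-transformed phosphosite reporter intensities), and
    chi-squared tests on per-kinase up- versus down-regulated substrate
    sub-networks weighted by relative intensity ratios. Site-specific
    kinase-substrate relations are consumed as a predicted network table.
    Includes hit-count integration and ranking, ROC/AUC benchmarking against
    known-regulator truth sets, hypergeometric term enrichment, Spearman
    correlation diagnostics, TMT reporter-ion labeling-efficiency QC from MGF
    spectra, phosphosite summary statistics, and a synthetic-data generator
    with planted kinase activity effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: Proteomics, Phosphoproteomics, Transcriptomics, NetworkInference,
    Software
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'stats.R'
    'io.R'
    'mgf.R'
    'psite_summary.R'
    'evidence_mrna.R'
    'evidence_intensity.R'
    'evidence_network.R'
    'integrate.R'
    'design_io.R'
    'evaluate.R'
    'simulate.R'
    'cli.R'
    'cki-package.R'
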