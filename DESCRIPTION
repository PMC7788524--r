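Package: apmsTimeCourse
Title: Interactor Discovery from Affinity-Purification Mass Spectrometry
    Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end workflow for discovering bait-protein interactors
    from affinity-purification mass spectrometry (AP-MS) time-course
    experiments. Merges BioGRID- and STRING-style interaction exports into a
    literature interactome re-scored with an evidence-based confidence
    scheme, ingests label-free MS1 quantification tables with identification
    and quantification acceptance filters, categorises proteins against a
    contaminant repository of negative-control AP-MS runs, clusters temporal
    abundance profiles with uncentred Pearson correlation and complete
    linkage anchored on known binders, applies fold-change and significance
    filters to shortlist candidates, expands the network one hop from known
    interactors, and ships a fully synthetic data generator with ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Proteomics, MassSpectrometry, NetworkInference, TimeCourse
Collate: 
    'AllClasses.R'
    'clustering.R'
    'contaminants.R'
    'filtering.R'
    'interactome.R'
    'msdata-io.R'
    'onehop.R'
    'pipeline.R'
    'simulate.R'
    'utils.R'
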