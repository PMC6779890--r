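Package: exoSig
Title: Small Noncoding RNA Biomarker Signatures from Exosomal RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and validation of small noncoding RNA (miRNA/piRNA)
    biomarker signatures from cerebrospinal-fluid exosome small RNA
    sequencing. Provides variance-stabilizing normalization with removal of
    unwanted variation, a three-iteration feature-selection procedure
    (permutation-calibrated relevance scoring with bootstrap stability
    selection, mutual-information ranking, and covariate-adjusted confound
    filtering), random-forest classification with stratified-bootstrap AUROC
    evaluation including combined models with CSF protein biomarkers (pTau,
    Abeta42/40 ratio), descriptive sncRNAome analytics (genomic-context
    annotation of piRNA loci, miRNA arm dominance, cell-versus-exosome
    correlation), and a negative-binomial cohort simulator for end-to-end
    validation with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2), SummarizedExperiment
Imports: methods, stats, utils, tools, S4Vectors, IRanges, GenomicRanges,
    rtracklayer, randomForest, jsonlite, yaml
Suggests: testthat (>= 3.0.0), pROC
Config/testthat/edition: 3
biocViews: Transcriptomics, Normalization, FeatureExtraction, Classification,
    Sequencing
RoxygenNote: 7.3.3
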