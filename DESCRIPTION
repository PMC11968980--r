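Package: grexcontact
Title: Genetically Regulated Expression of Enhancer RNAs and Chromatin Contact Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking genetically regulated expression (GReX) of
    enhancer RNAs and canonical genes to 3D chromatin contact frequency.
    Provides elastic-net cis models of transcript expression with
    cross-validated imputability calls, cis-eQTL mapping, ingestion and
    iterative-correction (ICE) normalization of binned Hi-C contact
    matrices, assembly of enhancer-gene pair training sets, fully-connected
    neural networks and classical regression baselines for contact-frequency
    prediction, exact two-feature Shapley attribution, cross-tissue transfer
    evaluation, and the downstream association bookkeeping used in
    transcriptome-wide association studies (Bonferroni thresholds, GWAS
    locus classification, Mendelian-randomization tallies, peak overlap,
    eQTL set comparison, and colocalization accounting). A synthetic-data
    module generates genotypes, annotations, expression, and contact
    matrices with the statistical structure the analysis assumes, so the
    full pipeline is testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    glmnet,
    Matrix,
    IRanges,
    S4Vectors,
    e1071,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
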