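Package: topicprs
Title: Comorbidity Topic Modelling and Polygenic Risk Score Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for subgrouping clinical comorbidity profiles and testing their
    polygenic basis. Converts a subject-by-clinical-feature table into pseudo
    electronic-medical-record documents, fits a latent Dirichlet allocation topic
    model of comorbid conditions by collapsed Gibbs sampling, builds p-value
    tranche polygenic risk scores from genotypes and external GWAS summary
    statistics (with array-style QC, allele harmonization and LD clumping), tests
    topic-score associations with rank-based inverse-normal transformed outcomes,
    nested-model ANOVA and semi-partial variance decomposition, and tests
    candidate-gene-list overlap with the hypergeometric distribution. Includes a
    synthetic-data generator with known ground truth so the full pipeline can be
    exercised and validated without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
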