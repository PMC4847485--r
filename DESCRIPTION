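Package: curex
Title: Weakly Supervised Information Extraction from Curated Biomedical Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns curated database records into noisy training examples for
    biomedical information extraction. A committee of weak classifiers votes
    on candidate passages, an expectation-maximization label estimator turns
    the votes into per-example reliabilities and per-classifier error rates,
    importance reweighting converts reliabilities into misclassification
    costs, and a cost-sensitive linear support vector machine learns the
    final extractor. Ships dictionary-based mention extraction, sparse
    feature creation, end-to-end pipelines for two genome-wide association
    study tasks (target-phenotype ranking and stage-ethnicity tuple
    extraction), evaluation metrics (precision-at-k, micro and macro tuple
    F1), article-based cross-validation, a synthetic corpus and committee
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    xml2,
    jsonlite,
    optparse,
    withr,
    tools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
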