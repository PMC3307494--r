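Package: litrank
Title: Two-Set Literature Ranking with Dictionary Tagging and a Tuned
    Linear Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks biomedical abstracts by relevance to an "interesting"
    document set against a background set.  Gene identifiers (Entrez or
    Ensembl) are expanded to linked PubMed abstracts, abstracts are tagged
    against a typed keyword dictionary into occurrence-count profiles, a
    bag-of-keywords feature space is built from the two training sets, and
    an L2-regularized logistic regression is tuned by a two-stage penalty
    grid search under five-fold cross-validation.  Query abstracts receive
    a probability-of-relevance score and a ranked assignment.  Includes an
    evaluation toolkit (confusion counts, precision/recall/FPR sweeps,
    Matthews correlation, majority-vote curation) and a synthetic-corpus
    generator with controllable topic separability for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
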