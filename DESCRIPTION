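Package: mddaid
Title: Antidepressant Response Knowledgebase and Decision-Aid Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a per-drug antidepressant-response knowledgebase from
    claims-like dispensing and medical-history event data, using medication
    persistence as a surrogate outcome for remission in major depressive
    disorder. Treatment episodes are constructed from dispensing records and
    classified into continued, switched, discontinued, and augmented
    dispositions; per-drug response models are fit by L1-penalized logistic
    regression with association screening and stability selection over random
    subsamples. The toolkit audits subgroup-specific algorithmic bias via
    McFadden pseudo-R-squared comparisons, runs an information-gain adaptive
    intake over prototype tables, aggregates suicide-risk-factor counts into
    referral pathways, manages dialogue topics over a directed acyclic topic
    network, and emits rule-based, counterfactually explained treatment
    recommendations. A synthetic-cohort generator with known ground-truth
    response models makes every stage testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
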