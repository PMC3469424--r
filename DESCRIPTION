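Package: fnnmets
Title: Fuzzy Neural Network Discovery of Combinational Metabolic Syndrome Risk Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering combinational risk factors of
    metabolic syndrome (MetS) from longitudinal health-check data. Implements
    JASSO-based MetS classification and case / healthy-control cohort labeling
    with medication exclusion; a fuzzy neural network (FNN) classifier with
    sigmoid low/high membership functions, product rule units and a weighted-sum
    output, trained by gradient descent; five-fold cross-validated forward
    feature selection over candidate health-check characteristics with a
    null-method baseline and linear/logistic comparators; fuzzy-rule extraction
    (low/high thresholds, 2x2 cell counts, rule weights); and statistical
    verification via adjusted logistic odds ratios, signed correlation ratios
    with lifestyle habits, and baseline group comparisons. A seeded synthetic
    cohort generator emulates the marginal distributions, habit-biomarker
    correlations and gamma-GTP x WBC interaction structure of employee
    health-check cohorts, so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    glmnet
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
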