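Package: riverfce
Title: Fuzzy Comprehensive Evaluation of Multifunctional Rivers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for grading the functional status of river segments on a
    hierarchical indicator system (target, criterion, sub-criterion and
    indicator layers) with five quality grades.  Subjective indicator weights
    are derived with the analytic hierarchy process (principal-eigenvector
    priorities with Saaty consistency testing), objective weights with the
    entropy method, and the two are fused by a weighted average.  Segment
    values are converted to grade memberships with Cauchy-shaped membership
    functions and composed into criterion- and target-layer evaluation
    vectors, graded by the principle of maximum affiliation.  Includes a
    seeded synthetic-scenario generator with planted grades for end-to-end
    validation, and a packaged 22-indicator river configuration.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
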