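Package: linkbias
Title: Simulating the Impact of Record-Linkage Error on Epidemiological Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how record-linkage errors distort health-services
    research results. Generates paired cancer-registry and insurance-claims cohorts
    with known ground truth, links them deterministically at a direct-identifier
    level (unique personal number) and an indirect-identifier level (name, date of
    birth, sex) with configurable missed-match and false-match error processes,
    runs a standard epidemiological analysis battery (descriptive statistics,
    group comparisons with rule-based test selection, person-years incidence with
    exact Poisson intervals, simple and adjusted Cox proportional-hazards models,
    subgroup analyses) at both levels, and scores the concordance of the two sets
    of results with arcsine (Cohen's h) and regression (Cohen's f) effect sizes
    and a three-tier good/poor/insufficient classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
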