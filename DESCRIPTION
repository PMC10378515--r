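Package: edsqual
Title: Graded Clinical Qualification of DNA Variants in Ehlers-Danlos
    Syndrome with Cohort and Gene-Set Comparison Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a stepwise molecular and clinical qualification
    protocol that grades DNA variants found by exome sequencing on a
    diagnostic-utility scale (evidenced, strong, moderate, uncertain, or
    no diagnostic utility, with synergistic and other-diagnosis
    qualifiers) and aggregates them into a 0-4+ per-patient medical DNA
    utility score. Accompanying tools summarize patient cohorts with
    findings checklists (Welch t tests from summary moments, N-1
    chi-squared tests on proportions), classify gene catalogs by product
    function and tissue element or process, compare gene sets between
    conditions including identical and family-similar symbol matching,
    export tripartite gene-mechanism-symptom ("entome") graphs, and
    simulate seeded synthetic patient cohorts with configurable findings
    and testing-outcome structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
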