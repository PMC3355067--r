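Package: initgem
Title: Tissue-Specific Metabolic Network Extraction by Integer Programming
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores the reactions of a genome-scale metabolic model with
    per-tissue proteomic and transcriptomic evidence, extracts a maximally
    supported, flux-consistent subnetwork by mixed-integer linear
    programming with a relaxed steady state that permits net metabolite
    accumulation, and compares sets of extracted networks through
    hypergeometric enrichment, Reporter Metabolite scoring, and
    bootstrapped hierarchical clustering. Includes a preprocessing
    pipeline that turns a raw merged reconstruction into a connected,
    flux-consistent template, and a synthetic-data generator producing
    random stoichiometric networks with planted active subnetworks so the
    whole pipeline can be exercised without external data. Linear and
    integer programs are solved with the HiGHS solver through a bundled
    Python helper (SciPy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    jsonlite,
    xml2,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: python (>= 3.8) with scipy (>= 1.9) on the PATH
Config/testthat/edition: 3
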