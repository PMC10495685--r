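Package: cardopt
Title: Cardinality Optimization for Quality Control of Genome-Scale
    Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Audits and repairs constraint-based metabolic models by
    casting the standard quality-control questions as cardinality
    (zero-norm) optimization problems solved with a difference-of-convex
    algorithm (DCA) over a sequence of linear programs. Implements
    stoichiometric consistency testing by minimal relaxation of mass
    conservation with sequential omission of suspect reactions,
    leak/siphon detection, flux consistency testing, thermodynamic flux
    consistency testing with chemical-potential certificates, sparse flux
    balance analysis, and relaxed flux balance analysis, together with
    capped-l1 and five other step-function approximations, seeded
    synthetic network generators with known ground truth, readers and
    writers for SBML Level 3 FBC, JSON and TSV models, broom-style
    tidiers, and a command-line audit tool.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    processx,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
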