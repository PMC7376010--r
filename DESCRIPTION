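Package: aneusim
Title: Stochastic Simulation of Aneuploid Cell Dynamics During
    Hematopoietic Reconstitution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based Monte Carlo model of aneuploid hematopoietic
    stem cell dynamics during post-transplantation bone marrow
    reconstitution.  Cells divide on stochastic timers, acquire
    aneuploidy at a per-division rate, and compete for a logistic,
    niche-limited capacity through fitness-weighted binomial culling;
    a radiation-damaged niche adds a fitness-independent efflux that
    relaxes as the niche heals.  Includes a deterministic mean-field
    oracle, time-resolved Kruskal-Wallis comparison of simulated
    conditions with an area-under-p-curve summary, declarative
    parameter-sweep experiments, and CSV/YAML input-output with a
    small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
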