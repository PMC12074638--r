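Package: persistlab
Title: Quantitative Analysis of Bacterial Antibiotic Persistence Assays
Version: 0.1.0
Authors@R: person("persistlab", "maintainers", email = "persistlab@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative pipeline of single-cell antibiotic
    persistence studies: most-probable-number (limiting dilution) viable-count
    estimation from 96-well plates, assembly of killing curves with log-scale
    replicate summaries, multi-exponential decay fitting in log space with AIC
    phase-number selection, single-cell lineage statistics (division rates,
    growing/non-growing classification, cell-shape circularity, rank-sum
    comparisons), and the two-mode subpopulation survival model f = s * Pn
    with propagated errors. Includes a synthetic-data simulator (Poisson well
    allocation, lognormal killing-curve noise, two-state switching lineage
    trees) so the full pipeline is testable without experimental data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
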