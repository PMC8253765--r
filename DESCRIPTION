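Package: dynadder
Title: Cell Size Homeostasis Simulation and Slope Diagnostics for the
    Dynamic Adder Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates single-cell lineages of total cell surface area over
    the cell cycle of an amoeboid cell under sizer, timer, adder, or
    dynamic-adder division control, with explicit exocytosis/endocytosis
    membrane-flux bookkeeping driven by Poisson phagocytosis.  Extracts
    per-cycle records from area trajectories, fits the classical
    slope diagnostics (added area vs birth area, pre-cytokinesis area vs
    birth area, log generation time vs log birth area) with bootstrap
    confidence intervals, classifies the homeostasis regime, and computes
    membrane-turnover budgets (refresh counts and uptake fractions).
    Includes a reproducible command-line pipeline over CSV/JSON files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
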