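Package: dnarom
Title: Decoherent Charge Transport and Crossbar Read-Out Simulation for
    DNA Memory Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates electrically readable DNA read-only memory. A
    non-equilibrium Green's function engine with Buettiker-probe
    decoherence turns orthogonalized molecular Hamiltonians of
    double-stranded DNA into current-voltage lookup tables, and a
    nonlinear crossbar-array solver (full Kirchhoff nodal analysis plus a
    fast sneak-path-parameter model) turns those tables into read-out
    current maps, bit error rates, and power figures under interconnect
    resistance and Fermi-energy variability, including Monte Carlo and
    image-storage benchmarks.
License: MIT + file LICENSE
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
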