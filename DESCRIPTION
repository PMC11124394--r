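Package: bindweight
Title: Expression-Weighted Tubulin Binding Energies and Censored-Potency QSAR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines per-isotype ligand binding energies for beta-tubulin with
    cell-line-specific isotype expression profiles into expression-weighted
    binding energies (BE_w), and correlates BE_w and standard physicochemical
    descriptors with log IC50 across cell-line panels using censoring-aware
    linear models. Includes simplex-constrained least-squares recovery of the
    implied isotype weights, convex-hull feasibility diagnostics for
    energy/weighted-energy table pairs, typed readers and writers for the
    delimited-text table formats, and a seeded synthetic-data generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
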