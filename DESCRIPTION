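Package: nucleocensus
Title: Molecular Census and Demixing-Mechanism Scoring for Membraneless
    Nuclear Organelles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts absolute proteomics abundances (iBAQ), imaging-based
    enrichment factors, and organelle geometry into a molecular census of
    membraneless nuclear organelles (copy numbers, concentrations, mass
    densities of candidate scaffold proteins, RNAs and nucleosomes).
    Computes molecular sizes under explicit conformational models
    (predicted, relaxed random-walk, and expanded arrangements of
    ordered/disordered domains; folded and worm-like-chain RNA), derives
    mean nearest-neighbor distances for randomly distributed hard spheres,
    and scores each organelle against the Debye length to distinguish
    compositions compatible with phase separation coupled to percolation
    (PSCP/LLPS) from demixing by interaction with clustered chromatin
    binding sites (ICBS). Includes a synthetic-cell generator and
    Monte-Carlo nearest-neighbor oracles for validation, plus a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
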