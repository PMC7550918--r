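Package: resclust
Title: Residue-Cluster Correlation Analysis of Per-Residue Binding-Energy
    Decompositions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies clusters of active-site residues whose cumulative
    per-residue binding-energy contribution tracks inhibitory activity
    (pIC50). Takes compound-by-residue energy decomposition tables (e.g.
    frame-averaged MM-PBSA per-residue contributions in kJ/mol) and
    activity tables, computes residue-wise and energy-component Pearson
    correlation profiles, applies sign-based residue selection with
    optional structure-activity-relationship site constraints, sums
    cluster energies per compound, and scores clusters by correlation
    with activity. Adds the significance and validation machinery such
    analyses need: exhaustive and greedy cluster search, permutation
    tests, bootstrap confidence intervals, and leave-one-out
    cross-validation, plus a synthetic-data generator with known
    population correlation structure for calibration studies. Ships the
    published COX-2 diarylheterocyclic inhibitor dataset (8 compounds by
    12 active-site residues) as a worked fixture.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
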