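Package: cpgroups
Title: Atom-Group Additivity Prediction of Liquid and Solid Heat Capacities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts isobaric heat capacities of the liquid and solid phase
    of organic molecules and ionic liquids at 298.15 K by atom-group
    additivity.  Backbone atoms are typed by element, hybridization,
    aromaticity and formal charge together with an encoded neighbourhood
    string; hydroxy oxygens are refined into primary, secondary and tertiary
    alcohol classes; special groups correct for endocyclic single bonds,
    small-ring angle strain, polyols and intramolecular hydrogen bridges.
    Ships the two published phase-specific contribution tables and the full
    fitting machinery to re-derive contributions from any training set:
    occurrence-matrix assembly, Gauss-Seidel solution of the normal
    equations, 10-fold cross-validation and iterative outlier elimination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    tibble,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
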