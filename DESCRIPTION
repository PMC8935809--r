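Package: nitrenium
Title: Nitrenium-Ion Stability QSAR for Primary Aromatic Amine Mutagenicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the bacterial (Ames) mutagenicity of primary aromatic
    amines from the thermodynamic stability of their nitrenium ions. The
    relative stabilization energy ddE (kcal/mol) of the ArNH+ cation versus
    the aniline reference pair is computed from AM1 semi-empirical heats
    of formation of force-field-selected conformers; a negative ddE flags a
    stabilized, mutagenicity-prone cation. Includes the dataset eligibility
    filters used for local QSAR curation, a bundled AM1 engine, seeded
    distance-geometry conformer enumeration, classification metrics with
    coverage bookkeeping, and a decision-cutoff sweep, supporting ICH M7
    expert review of potentially mutagenic impurities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Open Babel (obabel on the PATH); Python 3 with RDKit (conformer embedding)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
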