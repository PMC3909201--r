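Package: frustfold
Title: Frustrated Coarse-Grained Go-Model Folding Simulations and
    Transition-State Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds C-alpha Go-like models from PDB structures, optionally
    augmented with non-native hydrophobic attractions that act as energetic
    frustrations, and folds them by Langevin dynamics.  Implements an
    adaptive variable-temperature protocol that locks the simulation onto
    the folding transition temperature by equalising the folded and
    unfolded peaks of the native-contact histogram, and provides
    transition-state-ensemble analytics: apparent free-energy profiles
    -ln P(Q), phi-values, phi-increment statistics, and representative
    native-contact counts resolved by secondary-structure element pair.
    Includes deterministic synthetic fixtures (an ideal helical hairpin,
    a double-well toy sampler) so the whole pipeline runs and is testable
    without external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
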