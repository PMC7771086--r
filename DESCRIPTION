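Package: subsites
Title: Annotation, Modelling and Monte Carlo Analysis of Protease-Peptide
    Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates protease crystal structures bound to peptide-like
    ligands with the S4-S4' binding-pocket nomenclature, models full
    natural-amino-acid 8-mer substrates spanning P4-P4' (non-natural
    amino-acid replacement, side-chain mutation, missing-position
    reconstruction), samples complex conformations with a Metropolis
    Monte Carlo sampler using backrub-style backbone moves, and computes
    per-position structural observables (relative accessible surface
    area, hydrogen bonds, non-bonded contacts, interface energies) that
    are compared against per-position cleavage entropies derived from
    protease specificity matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
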