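Package: dnaface
Title: Dissection of Protein-DNA Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterises the binding region of a protein-DNA complex from
    its atomic coordinates. Computes solvent accessible surface areas
    (Shrake-Rupley), identifies interface atoms and residues by buried
    surface area, dissects the interface into core and rim, analyses
    interface hydration and water-mediated hydrogen bonding, scores the
    interface by amino-acid propensity (Rp), solvent-accessible hydrogen-bond
    donor capacity (Dp) and evolutionary conservation (Ncons) from a
    user-supplied multiple sequence alignment, and ranks candidate or decoy
    interfaces by those features. Includes deterministic generators of toy
    protein-DNA complexes, synthetic alignments and docking-decoy sets for
    testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    bio3d,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
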