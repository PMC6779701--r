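Package: swishmc
Title: Solvent-Scaled Hamiltonian Replica Exchange Sampling and Helicity
    Analysis for Coarse-Grained Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo implementation of the SWISH (Sampling Water
    Interfaces through Scaled Hamiltonians) replica exchange protocol on a
    coarse-grained peptide model, together with the trajectory observables
    used to characterise intrinsically disordered helical peptides:
    Kabsch-Sander hydrogen-bond energies and DSSP-style alpha/3-10 helicity,
    geometric hydrogen-bond and salt-bridge statistics, radius of gyration,
    Ramachandran histograms, and Aurora-Rose helix N-capping motif
    classification. Peptide sequences carry post-translational modifications
    (phosphorylation, side-chain and N-terminal acetylation) that modulate
    side-chain charges, the mechanism by which phosphorylation of the
    huntingtin N-terminus stabilises helical conformations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    bio3d,
    seqinr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
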