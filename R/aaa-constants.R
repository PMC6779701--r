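# Shared amino-acid tables. One-letter codes only; no Gly/Pro special-casing is
# needed for the huntingtin N-terminal peptides but the tables cover all 20.

AA_CODES <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              E = "Glu", Q = "Gln", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

AA_ONE <- stats::setNames(names(AA_THREE), unname(AA_THREE))

# Side-chain formal charges of unmodified residues at physiological pH.
AA_SC_CHARGE <- c(D = -1, E = -1, K = +1, R = +1)

# Hydrophobic (h) and polar (p) classes of the Aurora-Rose capping alphabet.
# Lys and Arg belong to both: their alkyl side chains count as hydrophobic,
# the charged head groups as polar.
AA_H_CLASS <- c("A", "V", "L", "I", "M", "F", "W", "Y", "C", "K", "R")
AA_P_CLASS <- c("S", "T", "N", "Q", "D", "E", "H", "K", "R")

# Side-chain masses in Da (residue mass minus the 56 Da backbone unit).
AA_SC_MASS <- c(A = 15.0, R = 100.1, N = 58.1, D = 59.0, C = 47.1,
                E = 73.1, Q = 72.1, G = 1.0, H = 81.1, I = 57.1,
                L = 57.1, K = 72.1, M = 75.1, F = 91.1, P = 41.1,
                S = 31.0, T = 45.1, W = 130.2, Y = 107.1, V = 43.1)

# CA -> side-chain-bead distance (Angstrom) by side-chain size class.
AA_SC_DIST <- c(A = 1.5, C = 1.9, S = 1.9, T = 1.9, V = 1.9,
                D = 2.4, I = 2.4, L = 2.4, M = 2.4, N = 2.4, P = 2.4,
                E = 2.9, K = 2.9, Q = 2.9,
                F = 3.2, H = 3.2, R = 3.2, Y = 3.2,
                W = 3.6, G = 0.0)

PHOSPHATE_MASS <- 80.0   # HPO3 added by phosphorylation
ACETYL_MASS    <- 42.0   # C2H2O added by acetylation
PHOSPHO_SC_EXTRA_DIST <- 1.0  # phosphate centroid sits beyond the hydroxyl
ACETYL_SC_EXTRA_DIST  <- 0.5

# Boltzmann constant in kcal/(mol K); k_B * 300 K = 0.5961 kcal/mol.
KB_KCAL <- 0.0019872041

# Atom masses for backbone atoms of the coarse-grained representation.
ATOM_MASS <- c(N = 14.01, H = 1.008, CA = 13.02, C = 12.01, O = 16.0)
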