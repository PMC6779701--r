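#' Build a conformation from backbone dihedrals
#'
#' Constructs Cartesian coordinates for the coarse-grained representation
#' (backbone N, H, CA, C, O plus one side-chain bead per residue, written as
#' CB) from phi/psi internal coordinates with ideal bond lengths and angles
#' and omega fixed at 180 degrees. The first residue is placed in a canonical
#' frame (N at the origin, CA on the x axis, C in the xy plane), so the build
#' is deterministic. `phi[1]` has no geometric effect (no preceding carbonyl)
#' but is retained as a coordinate; `psi[L]` orients the terminal carbonyl.
#' Amide hydrogens are placed 1 Angstrom from N opposing the preceding
#' carbonyl; residue 1 carries no amide hydrogen.
#'
#' @param seq A `mod_sequence`.
#' @param dihedrals Numeric matrix or data frame with columns `phi`, `psi`
#'   (degrees, in (-180, 180]), one row per residue; or a length-2 vector
#'   recycled to all residues.
#' @return A `conformation`: list with `coords` (n_atoms x 3 matrix,
#'   Angstrom), `atoms` (tibble: `residue`, `atom`, `element`, `mass`),
#'   `phi`, `psi`, and the originating `seq`.
#' @examples
#' wt <- parse_modified_sequence("MATLEKLMKAFESLKSFQQ")
#' helix <- build_conformation(wt, c(-57, -47))
#' @export
build_conformation <- function(seq, dihedrals) {
  stopifnot(inherits(seq, "mod_sequence"))
  L <- length(seq)
  d <- normalize_dihedrals(dihedrals, L)
  coords <- cpp_build_coords(d$phi, d$psi, seq$residues$sc_dist)
  structure(list(coords = coords, atoms = atom_table(seq),
                 phi = d$phi, psi = d$psi, seq = seq),
            class = "conformation")
}

normalize_dihedrals <- function(dihedrals, L) {
  if (is.numeric(dihedrals) && length(dihedrals) == 2) {
    dihedrals <- matrix(rep(dihedrals, each = L), ncol = 2)
  }
  d <- as.matrix(as.data.frame(dihedrals))
  if (nrow(d) != L || ncol(d) != 2) {
    rlang::abort(paste0("expected ", L, " (phi, psi) pairs, got ",
                        nrow(d), " x ", ncol(d)),
                 class = "swishmc_error_dihedrals")
  }
  if (any(!is.finite(d)) || any(d <= -180) || any(d > 180)) {
    rlang::abort("dihedral angles must be finite and in (-180, 180]",
                 class = "swishmc_error_dihedrals")
  }
  list(phi = as.numeric(d[, 1]), psi = as.numeric(d[, 2]))
}

#' Atom table of the coarse-grained representation
#' @param seq A `mod_sequence`.
#' @return Tibble with one row per atom in build order: `residue`, `atom`
#'   (N, H, CA, C, O, SC), `element`, `mass` (Da).
#' @export
atom_table <- function(seq) {
  stopifnot(inherits(seq, "mod_sequence"))
  L <- length(seq)
  rows <- lapply(seq_len(L), function(i) {
    atoms <- if (i == 1) c("N", "CA", "C", "O", "SC")
             else c("N", "H", "CA", "C", "O", "SC")
    tibble::tibble(
      residue = i, atom = atoms,
      element = c(N = "N", H = "H", CA = "C", C = "C", O = "O",
                  SC = "C")[atoms],
      mass = ifelse(atoms == "SC", seq$residues$sc_mass[i],
                    ATOM_MASS[atoms]))
  })
  dplyr::bind_rows(rows)
}

atom_row <- function(conf, residue, atom) {
  which(conf$atoms$residue == residue & conf$atoms$atom == atom)
}

#' Coordinates of one named atom across residues
#' @param conf A `conformation`.
#' @param atom Atom name (N, H, CA, C, O, SC).
#' @return Matrix L x 3 (rows of residues lacking the atom are NA).
#' @export
atom_coords <- function(conf, atom) {
  L <- length(conf$seq)
  out <- matrix(NA_real_, L, 3)
  sel <- conf$atoms$atom == atom
  out[conf$atoms$residue[sel], ] <- conf$coords[sel, , drop = FALSE]
  out
}

#' Measure backbone dihedrals from coordinates
#'
#' `phi[1]` is not measurable (no preceding carbonyl) and is returned as NA;
#' `psi` is recovered for every residue from the carbonyl orientation
#' (torsion N-CA-C-O minus 180 degrees).
#'
#' @param conf A `conformation` (or any object with `coords` and `atoms`).
#' @return Tibble with `residue`, `phi`, `psi` in degrees.
#' @export
measure_dihedrals <- function(conf) {
  L <- length(conf$seq)
  N <- atom_coords(conf, "N"); CA <- atom_coords(conf, "CA")
  C <- atom_coords(conf, "C"); O <- atom_coords(conf, "O")
  phi <- rep(NA_real_, L); psi <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    if (i > 1) phi[i] <- dihedral_angle(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    psi[i] <- wrap_angle(dihedral_angle(N[i, ], CA[i, ], C[i, ], O[i, ]) - 180)
  }
  tibble::tibble(residue = seq_len(L), phi = phi, psi = psi)
}

wrap_angle <- function(a) {
  w <- (a + 180) %% 360 - 180
  ifelse(w <= -180, 180, w)
}

#' Torsion angle defined by four points
#' @param p1,p2,p3,p4 Numeric xyz vectors.
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  wrap_angle(-atan2(y, x) * 180 / pi)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation> ", x$seq$name, ": ", length(x$seq), " residues, ",
      nrow(x$coords), " atoms\n", sep = "")
  invisible(x)
}
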