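#' Default coarse-grained energy parameters
#'
#' Loads the versioned parameter file shipped with the package. The model
#' has four terms: (i) a torsion potential with a helical basin at
#' (-57, -47) and an extended basin at (-135, 135), each a 2-D Gaussian
#' well; (ii) Lennard-Jones interactions between CA and side-chain beads of
#' residues at least two apart; (iii) Debye-Hueckel screened Coulomb
#' interactions between formal charges (side chains and termini), with the
#' default Debye length of 9.6 Angstrom corresponding to 100 mM monovalent
#' salt at 300 K and dielectric 78.5; (iv) the lambda-coupled
#' solvent-dispersion term W. W is the analogue of the attractive
#' water-apolar Lennard-Jones energy: each apolar bead (CA and C of every
#' residue, side-chain beads of hydrophobic-class residues) contributes
#' `-s_apolar * max(0, n_max - neighbours)` where neighbours counts heavy
#' atoms of other residues within `cutoff_exposure`. W is therefore more
#' negative the more solvent-exposed the chain is, so scaling it by
#' lambda > 1 favours exposed/extended states and lambda < 1 favours
#' hydrophobic collapse.
#'
#' @param path Optional path to a parameter file (two-column
#'   tab-separated key/value, `#` comments allowed); defaults to the shipped
#'   `cg_default_v1.tsv`.
#' @return An `energy_params` list.
#' @export
default_energy_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("params", "cg_default_v1.tsv", package = "swishmc")
  }
  read_energy_params(path)
}

#' Read energy parameters from a key-value file
#' @param path Parameter file path.
#' @return An `energy_params` list.
#' @export
read_energy_params <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", header = FALSE,
                           col.names = c("key", "value"))
  p <- as.list(stats::setNames(as.numeric(tab$value), tab$key))
  validate_energy_params(p)
  structure(p, class = "energy_params")
}

#' Write energy parameters to a key-value file
#' @param params An `energy_params` list.
#' @param path Output path.
#' @export
write_energy_params <- function(params, path) {
  writeLines(c("# swishmc coarse-grained model parameters",
               paste(names(params), vapply(params, format, ""), sep = "\t")),
             path)
  invisible(path)
}

validate_energy_params <- function(p) {
  needed <- c("temperature", "dielectric", "debye_length", "s_apolar",
              "cutoff_exposure", "n_max", "hardcore", "eps_ca", "sigma_ca",
              "eps_sc_h", "eps_sc_p", "sigma_sc", "helix_phi", "helix_psi",
              "helix_width", "helix_depth", "ext_phi", "ext_psi",
              "ext_width", "ext_depth")
  missing <- setdiff(needed, names(p))
  if (length(missing) > 0) {
    rlang::abort(paste("missing parameter(s):", paste(missing, collapse = ", ")),
                 class = "swishmc_error_params")
  }
  positive <- c("temperature", "dielectric", "debye_length", "cutoff_exposure",
                "sigma_ca", "sigma_sc", "helix_width", "ext_width")
  bad <- positive[vapply(positive, function(k) p[[k]] <= 0, TRUE)]
  if (length(bad) > 0) {
    rlang::abort(paste("parameter(s) must be positive:",
                       paste(bad, collapse = ", ")),
                 class = "swishmc_error_params")
  }
  invisible(p)
}

# Pack sequence + parameters into the flat per-atom arrays consumed by the
# compiled energy/sampling kernels.
pack_system <- function(seq, params) {
  stopifnot(inherits(seq, "mod_sequence"))
  at <- atom_table(seq)
  L <- length(seq)
  kind_code <- c(N = 0L, H = 1L, CA = 2L, C = 3L, O = 4L, SC = 5L)
  kind <- unname(kind_code[at$atom])
  res0 <- at$residue - 1L
  q <- numeric(nrow(at))
  sc_rows <- which(at$atom == "SC")
  q[sc_rows] <- seq$residues$sc_charge[at$residue[sc_rows]]
  q[which(at$atom == "N" & at$residue == 1)] <- seq$nterm_charge
  q[which(at$atom == "C" & at$residue == L)] <- seq$cterm_charge
  eps <- numeric(nrow(at)); sigma <- numeric(nrow(at))
  eps[at$atom == "CA"] <- params$eps_ca
  sigma[at$atom == "CA"] <- params$sigma_ca
  sc_h <- seq$residues$in_h[at$residue[sc_rows]]
  eps[sc_rows] <- ifelse(sc_h, params$eps_sc_h, params$eps_sc_p)
  sigma[sc_rows] <- params$sigma_sc
  # lambda-coupled apolar set: CA and C beads of all residues, SC beads of
  # hydrophobic-class residues (the CG mirror of "all C and S atoms").
  apolar <- as.integer(at$atom %in% c("CA", "C"))
  apolar[sc_rows] <- as.integer(sc_h)
  depth <- cbind(rep(params$helix_depth, L), rep(params$ext_depth, L))
  list(kind = kind, res = res0, q = q, eps = eps, sigma = sigma,
       apolar = apolar, sc_dist = seq$residues$sc_dist,
       basin_phi = c(params$helix_phi, params$ext_phi),
       basin_psi = c(params$helix_psi, params$ext_psi),
       basin_width = c(params$helix_width, params$ext_width),
       basin_depth = depth,
       dielectric = params$dielectric, debye_length = params$debye_length,
       s_apolar = params$s_apolar, cutoff_exposure = params$cutoff_exposure,
       hardcore = params$hardcore, n_max = as.integer(params$n_max))
}

#' Decompose the energy into lambda-independent and lambda-coupled parts
#'
#' The total energy at solvent-scaling coefficient lambda is exactly
#' `U(lambda) = U0 + lambda * W`, where `U0` collects the torsion,
#' Lennard-Jones and screened-Coulomb terms and `W` is the
#' solvent-dispersion energy of the apolar beads. Overlapping beads closer
#' than the hard-core distance yield `U0 = Inf` (no exception).
#'
#' @param conf A `conformation`.
#' @param seq A `mod_sequence` consistent with `conf` (defaults to the one
#'   stored in `conf`).
#' @param params An `energy_params` list.
#' @return An `energy_decomposition`: list with `U0`, `W` (kcal/mol) and a
#'   `terms` breakdown (torsion, lj, elec).
#' @export
energy_decomposition <- function(conf, seq = conf$seq,
                                 params = default_energy_params()) {
  stopifnot(inherits(conf, "conformation"))
  if (length(seq) != length(conf$seq)) {
    rlang::abort("sequence and conformation lengths differ",
                 class = "swishmc_error_dihedrals")
  }
  sys <- pack_system(seq, params)
  t <- cpp_energy_terms(conf$phi, conf$psi, sys)
  structure(list(U0 = unname(t["U0"]), W = unname(t["W"]),
                 terms = c(torsion = unname(t["torsion"]),
                           lj = unname(t["lj"]), elec = unname(t["elec"])),
                 clash = t["clash"] > 0),
            class = "energy_decomposition")
}

#' Total energy at a given solvent-scaling coefficient
#' @inheritParams energy_decomposition
#' @param lambda Solvent-scaling coefficient (> 0).
#' @return Energy in kcal/mol (`Inf` on hard-core overlap).
#' @export
total_energy <- function(conf, seq = conf$seq,
                         params = default_energy_params(), lambda = 1) {
  stopifnot(lambda > 0)
  d <- energy_decomposition(conf, seq, params)
  d$U0 + lambda * d$W
}

#' Solvent exposure of the apolar beads
#'
#' @inheritParams energy_decomposition
#' @return Tibble of apolar beads with `residue`, `atom` and `exposure`
#'   (`max(0, n_max - neighbour count)`); the lambda-coupled energy is
#'   `W = -s_apolar * sum(exposure)`.
#' @export
solvent_exposure <- function(conf, seq = conf$seq,
                             params = default_energy_params()) {
  sys <- pack_system(seq, params)
  e <- cpp_exposure(conf$phi, conf$psi, sys)
  out <- conf$atoms
  out$exposure <- as.numeric(e)
  dplyr::filter(out, !is.na(.data$exposure))[, c("residue", "atom", "exposure")]
}

#' Screened Coulomb energy between the charged groups of two residues
#'
#' Debye-Hueckel pair energy between all charged atoms belonging to residue
#' `res_i` and those of `res_j` (side-chain beads; terminal charges ride on
#' the first N and last C). Useful for inspecting e.g. the
#' phosphothreonine-lysine salt-bridge term.
#'
#' @inheritParams energy_decomposition
#' @param res_i,res_j 1-based residue indices.
#' @return Energy in kcal/mol.
#' @export
electrostatic_pair_energy <- function(conf, res_i, res_j, seq = conf$seq,
                                      params = default_energy_params()) {
  sys <- pack_system(seq, params)
  sel_i <- which(sys$res + 1L == res_i & sys$q != 0)
  sel_j <- which(sys$res + 1L == res_j & sys$q != 0)
  e <- 0
  for (a in sel_i) for (b in sel_j) {
    r <- sqrt(sum((conf$coords[a, ] - conf$coords[b, ])^2))
    e <- e + 332.0637 * sys$q[a] * sys$q[b] /
      (params$dielectric * r) * exp(-r / params$debye_length)
  }
  e
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat(sprintf("<energy_decomposition> U0 = %.4f, W = %.4f kcal/mol\n",
              x$U0, x$W))
  cat(sprintf("  torsion %.4f | LJ %.4f | elec %.4f\n",
              x$terms["torsion"], x$terms["lj"], x$terms["elec"]))
  invisible(x)
}
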