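# Kabsch-Sander backbone hydrogen-bond energies and DSSP-style assignment
# restricted to the helical classes (H = alpha, G = 3-10); everything else
# collapses to turn (T) or coil (C), since the observable of record counts
# only alpha or 3-10 helicity.

KS_Q1Q2_F <- 0.084 * 332  # 27.888 kcal/mol * Angstrom
KS_CUTOFF <- -0.5         # bond iff E < -0.5 kcal/mol

#' Place amide hydrogens on backbone coordinates
#'
#' For residues i >= 2 the amide hydrogen is placed 1 Angstrom from N(i)
#' along the unit vector C(i-1) - O(i-1) (opposing the preceding carbonyl,
#' the standard DSSP reconstruction). Residue 1 receives no amide hydrogen
#' and can never act as a Kabsch-Sander donor. Frames that already contain
#' amide hydrogens are returned unchanged.
#'
#' @param x A `trajectory` or `conformation`.
#' @return Object of the same class with H atoms present.
#' @export
place_amide_hydrogens <- function(x) {
  if (inherits(x, "conformation")) {
    traj <- place_amide_hydrogens(as_trajectory(x))
    out <- x
    out$coords <- traj$coords[, , 1]
    out$atoms <- traj$atoms
    return(out)
  }
  stopifnot(inherits(x, "trajectory"))
  L <- max(x$atoms$residue)
  has_h <- vapply(2:L, function(r)
    any(x$atoms$residue == r & x$atoms$atom == "H"), TRUE)
  if (all(has_h)) return(x)
  for (r in seq_len(L)) {
    missing <- setdiff(c("N", "CA", "C", "O"),
                       x$atoms$atom[x$atoms$residue == r])
    if (length(missing) > 0) {
      rlang::abort(paste0("residue ", r, " is missing backbone atom(s) ",
                          paste(missing, collapse = ", ")),
                   class = "swishmc_error_io")
    }
  }
  nf <- n_frames(x)
  rowN <- match_atom_rows(x$atoms, "N")
  rowC <- match_atom_rows(x$atoms, "C")
  rowO <- match_atom_rows(x$atoms, "O")
  new_atoms <- list(); new_coords <- list()
  for (r in seq_len(L)) {
    blk <- which(x$atoms$residue == r & x$atoms$atom != "H")
    a <- x$atoms[blk, , drop = FALSE]
    cc <- x$coords[blk, , , drop = FALSE]
    if (r >= 2) {
      h <- array(NA_real_, c(1, 3, nf))
      for (f in seq_len(nf)) {
        d <- x$coords[rowC[r - 1], , f] - x$coords[rowO[r - 1], , f]
        h[1, , f] <- x$coords[rowN[r], , f] + d / sqrt(sum(d^2))
      }
      ins <- which(a$atom == "N")
      a <- dplyr::bind_rows(a[seq_len(ins), ],
                            tibble::tibble(residue = r, atom = "H",
                                           element = "H", mass = ATOM_MASS[["H"]]),
                            a[-seq_len(ins), ])
      cc <- abind3(cc[seq_len(ins), , , drop = FALSE], h,
                   cc[-seq_len(ins), , , drop = FALSE])
    }
    new_atoms[[r]] <- a; new_coords[[r]] <- cc
  }
  new_trajectory(do.call(abind3, new_coords), dplyr::bind_rows(new_atoms),
                 x$meta, x$seq, x$phi, x$psi)
}

abind3 <- function(...) {
  parts <- Filter(function(p) !is.null(p) && dim(p)[1] > 0, list(...))
  n <- sum(vapply(parts, function(p) dim(p)[1], 1L))
  out <- array(NA_real_, c(n, 3, dim(parts[[1]])[3]))
  at <- 0
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

match_atom_rows <- function(atoms, name) {
  L <- max(atoms$residue)
  vapply(seq_len(L), function(r) {
    i <- which(atoms$residue == r & atoms$atom == name)
    if (length(i) == 0) NA_integer_ else i[1]
  }, 1L)
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol for a
#' backbone donor (N-H) / acceptor (C=O) pair; a hydrogen bond is assigned
#' iff `E < -0.5` kcal/mol.
#'
#' @param donor List or matrix with rows/elements `N` and `H` (xyz).
#' @param acceptor List or matrix with rows/elements `C` and `O` (xyz).
#' @return Energy in kcal/mol.
#' @export
ks_hbond_energy <- function(donor, acceptor) {
  N <- donor$N; H <- donor$H; C <- acceptor$C; O <- acceptor$O
  d <- c(ON = dist3(O, N), CH = dist3(C, H), OH = dist3(O, H),
         CN = dist3(C, N))
  if (any(d < 0.5)) {
    rlang::abort("malformed geometry: inter-atom distance below 0.5 Angstrom",
                 class = "swishmc_error_geometry")
  }
  KS_Q1Q2_F * (1 / d["ON"] + 1 / d["CH"] - 1 / d["OH"] - 1 / d["CN"]) |>
    unname()
}

dist3 <- function(a, b) sqrt(sum((a - b)^2))

#' Kabsch-Sander bond matrix of one frame
#'
#' @param frame A `conformation` (amide hydrogens placed if absent).
#' @return L x L logical matrix: entry (i, j) is TRUE iff the carbonyl of
#'   residue i donates to the amide of residue j (CO(i) -> NH(j)) with
#'   Kabsch-Sander energy below -0.5 kcal/mol. Column 1 is all FALSE
#'   (residue 1 has no amide hydrogen).
#' @export
ks_bond_matrix <- function(frame) {
  frame <- place_amide_hydrogens(frame)
  N <- atom_coords(frame, "N"); H <- atom_coords(frame, "H")
  C <- atom_coords(frame, "C"); O <- atom_coords(frame, "O")
  L <- nrow(N)
  rON <- cross_dist(O, N); rCH <- cross_dist(C, H)
  rOH <- cross_dist(O, H); rCN <- cross_dist(C, N)
  E <- KS_Q1Q2_F * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  bond <- !is.na(E) & E < KS_CUTOFF
  diag(bond) <- FALSE
  bond
}

cross_dist <- function(A, B) {
  # rows of A vs rows of B
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Assign helical secondary structure to one frame
#'
#' DSSP turn logic restricted to helices: an n-turn at i (n in 3, 4) is a
#' Kabsch-Sander bond CO(i) -> NH(i+n). Two consecutive 4-turns at i-1 and
#' i make residues i..i+3 alpha-helical (H); two consecutive 3-turns make
#' residues i..i+2 3-10-helical (G) unless already H (alpha priority).
#' Residues inside a single turn are T, everything else C.
#'
#' @param frame A `conformation` with at least 3 complete-backbone residues.
#' @return Character vector of per-residue labels (H, G, T, C).
#' @export
assign_ss <- function(frame) {
  bond <- ks_bond_matrix(frame)
  L <- nrow(bond)
  if (L < 3) {
    rlang::abort("at least 3 residues required", class = "swishmc_error_input")
  }
  turn <- function(n) {
    v <- rep(FALSE, L)
    idx <- seq_len(max(0, L - n))
    v[idx] <- bond[cbind(idx, idx + n)]
    v
  }
  t3 <- turn(3); t4 <- turn(4)
  lab <- rep("C", L)
  for (i in seq_len(L)) {   # single turns -> T on the spanned interior
    for (n in c(3, 4)) {
      tn <- if (n == 3) t3 else t4
      if (i <= L - n && tn[i]) {
        span <- (i + 1):(i + n - 1)
        lab[span][lab[span] == "C"] <- "T"
      }
    }
  }
  for (i in 2:L) {
    if (i <= L - 4 && t4[i - 1] && t4[i]) lab[i:(i + 3)] <- "H"
  }
  for (i in 2:L) {
    if (i <= L - 3 && t3[i - 1] && t3[i]) {
      span <- i:(i + 2)
      lab[span][lab[span] != "H"] <- "G"
    }
  }
  lab
}

#' Assign secondary structure to every frame of a trajectory
#' @param traj A `trajectory`.
#' @return Character matrix, frames x residues.
#' @export
assign_ss_trajectory <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  traj <- place_amide_hydrogens(traj)
  t(vapply(seq_len(n_frames(traj)),
           function(f) assign_ss(get_frame(traj, f)),
           character(max(traj$atoms$residue))))
}

#' Helicity profile of a trajectory
#'
#' The helicity of record: per residue, the fraction of frames assigned
#' alpha (H) or 3-10 (G) helix; the overall helicity is the fraction of
#' residue-frames assigned helical, i.e. the mean over residues of
#' (H-fraction + G-fraction), identically equal to the mean over frames of
#' the per-frame helical fraction.
#'
#' @param x A `swish_run` (uses the lambda = 1 reporting stream), a
#'   `trajectory`, or a character label matrix (frames x residues).
#' @param equilibration_fraction Initial fraction of frames discarded
#'   before averaging (default 0.1).
#' @param ... Unused.
#' @return A `helicity_profile` tibble: `residue`, `code`, `f_alpha`,
#'   `f_three_ten`, `f_helical`, with attributes `overall` (scalar fraction)
#'   and `n_frames`.
#' @export
helicity <- function(x, equilibration_fraction = 0.1, ...) {
  UseMethod("helicity")
}

#' @export
helicity.matrix <- function(x, equilibration_fraction = 0.1, codes = NULL, ...) {
  n <- nrow(x)
  first <- floor(n * equilibration_fraction) + 1
  if (n == 0 || first > n) {
    rlang::abort("no frames left after equilibration discard",
                 class = "swishmc_error_empty")
  }
  x <- x[first:n, , drop = FALSE]
  L <- ncol(x)
  f_a <- colMeans(x == "H")
  f_g <- colMeans(x == "G")
  out <- tibble::tibble(
    residue = seq_len(L),
    code = if (is.null(codes)) NA_character_ else codes,
    f_alpha = f_a, f_three_ten = f_g, f_helical = f_a + f_g)
  structure(out, overall = mean(out$f_helical), n_frames = nrow(x),
            class = c("helicity_profile", class(out)))
}

#' @export
helicity.trajectory <- function(x, equilibration_fraction = 0.1, ...) {
  x <- discard_equilibration(x, equilibration_fraction)
  labs <- assign_ss_trajectory(x)
  helicity.matrix(labs, equilibration_fraction = 0,
                  codes = if (!is.null(x$seq)) x$seq$residues$code)
}

#' @export
helicity.swish_run <- function(x, equilibration_fraction = 0.1, lambda = 1, ...) {
  traj <- state_trajectory(x, lambda = lambda,
                           equilibration_fraction = equilibration_fraction)
  helicity.trajectory(traj, equilibration_fraction = 0)
}

#' Overall helicity of a profile
#' @param profile A `helicity_profile`.
#' @return Scalar fraction in [0, 1].
#' @export
overall_helicity <- function(profile) attr(profile, "overall")

#' Per-frame helical fraction series
#'
#' Fraction of residues labelled H or G in each frame; block-average this
#' series to put error bars on the overall helicity.
#'
#' @param x A `trajectory`, `swish_run`, or label matrix.
#' @param equilibration_fraction Initial fraction of frames discarded.
#' @param ... Passed to methods.
#' @return Numeric vector, one value per retained frame.
#' @export
helicity_series <- function(x, equilibration_fraction = 0, ...) {
  labs <- if (is.matrix(x)) x
    else if (inherits(x, "trajectory"))
      assign_ss_trajectory(discard_equilibration(x, equilibration_fraction))
    else if (inherits(x, "swish_run"))
      assign_ss_trajectory(state_trajectory(x, lambda = 1,
                             equilibration_fraction = equilibration_fraction))
    else rlang::abort("unsupported input", class = "swishmc_error_input")
  rowMeans(labs == "H" | labs == "G")
}

#' @export
print.helicity_profile <- function(x, ...) {
  cat(sprintf("<helicity_profile> overall helicity %.1f%% over %d frame(s)\n",
              100 * attr(x, "overall"), attr(x, "n_frames")))
  NextMethod()
}

#' Helicity profile as a percent table
#'
#' Per-residue percentages (one decimal), matching the layout used for
#' reporting simulation-derived helicity.
#'
#' @param profile A `helicity_profile`.
#' @return Tibble with `residue`, `code`, `pct_alpha`, `pct_three_ten`,
#'   `pct_helical`.
#' @export
helicity_percent_table <- function(profile) {
  tibble::tibble(residue = profile$residue, code = profile$code,
                 pct_alpha = round(100 * profile$f_alpha, 1),
                 pct_three_ten = round(100 * profile$f_three_ten, 1),
                 pct_helical = round(100 * profile$f_helical, 1))
}
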