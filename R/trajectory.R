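#' Trajectory container
#'
#' Ordered frames of coarse-grained coordinates with provenance metadata.
#' Created by [state_trajectory()] (from a SWISH run), [read_multimodel_pdb()]
#' (external origin) or [as_trajectory()] (single conformation).
#'
#' @param coords Numeric array `n_atoms x 3 x n_frames`.
#' @param atoms Atom tibble (`residue`, `atom`, `element`, `mass`).
#' @param meta Frame metadata tibble; a `frame` column is added if missing.
#' @param seq Optional `mod_sequence`.
#' @param phi,psi Optional `n_frames x L` dihedral matrices.
#' @return A `trajectory`.
#' @export
new_trajectory <- function(coords, atoms, meta = NULL, seq = NULL,
                           phi = NULL, psi = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3,
            dim(coords)[1] == nrow(atoms))
  n <- dim(coords)[3]
  if (is.null(meta)) meta <- tibble::tibble(frame = seq_len(n))
  if (!"frame" %in% names(meta)) meta$frame <- seq_len(n)
  structure(list(coords = coords, atoms = atoms, meta = meta, seq = seq,
                 phi = phi, psi = psi),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", n_frames(x), " frame(s), ",
      max(x$atoms$residue), " residues, ", nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @return Integer.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Subset trajectory frames
#' @param traj A `trajectory`.
#' @param idx Frame indices (logical or integer).
#' @return A `trajectory`.
#' @export
subset_frames <- function(traj, idx) {
  new_trajectory(traj$coords[, , idx, drop = FALSE], traj$atoms,
                 traj$meta[idx, , drop = FALSE], traj$seq,
                 if (!is.null(traj$phi)) traj$phi[idx, , drop = FALSE],
                 if (!is.null(traj$psi)) traj$psi[idx, , drop = FALSE])
}

#' Drop the equilibration portion of a trajectory
#' @param traj A `trajectory`.
#' @param equilibration_fraction Fraction of initial frames to discard.
#' @return A `trajectory`.
#' @export
discard_equilibration <- function(traj, equilibration_fraction = 0.1) {
  stopifnot(equilibration_fraction >= 0, equilibration_fraction < 1)
  n <- n_frames(traj)
  first <- floor(n * equilibration_fraction) + 1
  if (first > n) {
    rlang::abort("no frames left after equilibration discard",
                 class = "swishmc_error_empty")
  }
  subset_frames(traj, first:n)
}

#' Extract a single frame as a conformation-like object
#' @param traj A `trajectory`.
#' @param i Frame index.
#' @return A `conformation` (phi/psi present only if stored).
#' @export
get_frame <- function(traj, i) {
  structure(list(coords = traj$coords[, , i], atoms = traj$atoms,
                 phi = if (!is.null(traj$phi)) traj$phi[i, ],
                 psi = if (!is.null(traj$psi)) traj$psi[i, ],
                 seq = traj$seq),
            class = "conformation")
}

#' Convert a conformation to a single-frame trajectory
#' @param conf A `conformation`.
#' @return A `trajectory`.
#' @export
as_trajectory <- function(conf) {
  stopifnot(inherits(conf, "conformation"))
  coords <- array(conf$coords, dim = c(nrow(conf$coords), 3, 1))
  new_trajectory(coords, conf$atoms, seq = conf$seq,
                 phi = if (!is.null(conf$phi)) matrix(conf$phi, 1),
                 psi = if (!is.null(conf$psi)) matrix(conf$psi, 1))
}

#' Materialise the frames recorded at one ladder rung
#'
#' Rebuilds Cartesian coordinates for every frame recorded at the rung with
#' the requested lambda (default 1: the unscaled, physical reporting
#' ensemble).
#'
#' @param run A `swish_run` on a `peptide_system`.
#' @param lambda Rung to extract.
#' @param equilibration_fraction Initial fraction of frames to discard.
#' @return A `trajectory` with `lambda`, `sweep` and `replica` metadata.
#' @export
state_trajectory <- function(run, lambda = 1, equilibration_fraction = 0) {
  stopifnot(inherits(run, "swish_run"),
            inherits(run$system, "peptide_system"))
  rung <- which(abs(as.numeric(run$ladder) - lambda) < 1e-9)
  if (length(rung) == 0) {
    rlang::abort(paste0("no ladder rung at lambda = ", lambda),
                 class = "swishmc_error_no_rung")
  }
  fr <- run$frames[[rung[1]]]
  if (is.null(fr) || length(fr$sweep) == 0) {
    rlang::abort("no frames recorded at the requested rung",
                 class = "swishmc_error_empty")
  }
  seq <- run$system$seq
  sc <- seq$residues$sc_dist
  n <- length(fr$sweep)
  first <- floor(n * equilibration_fraction) + 1
  keep <- first:n
  coords <- array(NA_real_, c(6 * length(seq) - 1, 3, length(keep)))
  for (j in seq_along(keep)) {
    coords[, , j] <- cpp_build_coords(fr$phi[keep[j], ], fr$psi[keep[j], ], sc)
  }
  new_trajectory(coords, atom_table(seq),
                 meta = tibble::tibble(frame = seq_along(keep),
                                       sweep = fr$sweep[keep],
                                       replica = fr$replica[keep],
                                       lambda = as.numeric(run$ladder)[rung[1]]),
                 seq = seq,
                 phi = fr$phi[keep, , drop = FALSE],
                 psi = fr$psi[keep, , drop = FALSE])
}
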