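# Geometric hydrogen bonds, salt bridges, radius of gyration, Ramachandran
# histograms and Aurora-Rose N-capping motif classification.

HB_DIST_CUTOFF <- 3.5   # heavy-heavy, inclusive
HB_ANGLE_CUTOFF <- 120  # heavy-H-heavy, exclusive

# Side chains able to donate / accept hydrogen bonds in the CG model.
SC_DONOR_CODES <- c("K", "R", "S", "T", "N", "Q", "Y", "W", "H")
SC_ACCEPTOR_CODES <- c("D", "E", "N", "Q", "S", "T", "Y", "H")

#' Does a donor/acceptor geometry qualify as a hydrogen bond?
#'
#' The geometric rule of record: heavy-atom distance of at most 3.5
#' Angstrom (inclusive) and heavy-H-heavy angle strictly greater than 120
#' degrees.
#'
#' @param distance Heavy-heavy distance, Angstrom.
#' @param angle Heavy-H-heavy angle, degrees.
#' @return Logical.
#' @export
hbond_geometry_ok <- function(distance, angle) {
  distance <= HB_DIST_CUTOFF & angle > HB_ANGLE_CUTOFF
}

resolve_donors <- function(frame, donors = NULL) {
  seq <- frame$seq
  L <- max(frame$atoms$residue)
  rowN <- match_atom_rows(frame$atoms, "N")
  rowH <- match_atom_rows(frame$atoms, "H")
  rowCA <- match_atom_rows(frame$atoms, "CA")
  rowSC <- match_atom_rows(frame$atoms, "SC")
  out <- list()
  # backbone amides (residue 1 has no amide hydrogen)
  for (r in 2:L) {
    if (!is.na(rowH[r])) {
      out[[length(out) + 1]] <- list(residue = r, site = "backbone_nh",
                                     heavy = rowN[r], h = rowH[r])
    }
  }
  if (!is.null(seq)) {
    for (r in seq_len(L)) {
      code <- seq$residues$code[r]
      ptm <- seq$residues$ptm[r]
      donor_ok <- code %in% SC_DONOR_CODES &&
        !(code %in% c("S", "T") && !is.na(ptm) && ptm == "phospho") &&
        !(code == "K" && !is.na(ptm) && ptm == "acetyl")
      if (donor_ok && !is.na(rowSC[r])) {
        out[[length(out) + 1]] <- list(residue = r, site = "sidechain",
                                       heavy = rowSC[r],
                                       h = -rowSC[r],  # virtual H marker
                                       ca = rowCA[r])
      }
    }
  }
  if (!is.null(donors)) out <- Filter(function(d) d$residue %in% donors, out)
  out
}

resolve_acceptors <- function(frame, acceptors = NULL) {
  seq <- frame$seq
  L <- max(frame$atoms$residue)
  rowO <- match_atom_rows(frame$atoms, "O")
  rowSC <- match_atom_rows(frame$atoms, "SC")
  out <- list()
  for (r in seq_len(L)) {
    out[[length(out) + 1]] <- list(residue = r, site = "backbone_co",
                                   heavy = rowO[r])
  }
  if (!is.null(seq)) {
    for (r in seq_len(L)) {
      code <- seq$residues$code[r]
      ptm <- seq$residues$ptm[r]
      acc_ok <- code %in% SC_ACCEPTOR_CODES ||
        (!is.na(ptm) && ptm %in% c("phospho", "acetyl"))
      if (acc_ok && !is.na(rowSC[r])) {
        out[[length(out) + 1]] <- list(residue = r, site = "sidechain",
                                       heavy = rowSC[r])
      }
    }
  }
  if (!is.null(acceptors)) out <- Filter(function(a) a$residue %in% acceptors, out)
  out
}

virtual_h <- function(frame, d) {
  # side-chain donor: place the hydrogen 1 Angstrom beyond the bead along
  # the CA -> SC direction
  sc <- frame$coords[d$heavy, ]
  v <- sc - frame$coords[d$ca, ]
  sc + v / sqrt(sum(v^2))
}

#' Geometric hydrogen bonds of one frame
#'
#' All donor-acceptor pairs meeting the geometric rule (distance <= 3.5
#' Angstrom inclusive, heavy-H-heavy angle > 120 degrees exclusive). Donors
#' are backbone amides (residues >= 2) and donor-capable side-chain beads
#' (with a virtual hydrogen along the CA->SC direction); acceptors are
#' backbone carbonyl oxygens and acceptor-capable side-chain beads
#' (phosphate, carboxylate, amide, hydroxyl groups). Same-residue pairs are
#' excluded.
#'
#' @param frame A `conformation`.
#' @param donors,acceptors Optional residue-index filters.
#' @return Tibble: `donor_res`, `donor_site`, `acceptor_res`,
#'   `acceptor_site`, `heavy_distance`, `angle`.
#' @export
geometric_hbonds <- function(frame, donors = NULL, acceptors = NULL) {
  frame <- place_amide_hydrogens(frame)
  dn <- resolve_donors(frame, donors)
  ac <- resolve_acceptors(frame, acceptors)
  rows <- list()
  for (d in dn) {
    h <- if (d$h > 0) frame$coords[d$h, ] else virtual_h(frame, d)
    dh <- frame$coords[d$heavy, ]
    for (a in ac) {
      if (a$residue == d$residue) next
      ah <- frame$coords[a$heavy, ]
      r <- dist3(dh, ah)
      if (r > HB_DIST_CUTOFF) next
      ang <- angle_deg(dh - h, ah - h)
      if (hbond_geometry_ok(r, ang)) {
        rows[[length(rows) + 1]] <-
          tibble::tibble(donor_res = d$residue, donor_site = d$site,
                         acceptor_res = a$residue, acceptor_site = a$site,
                         heavy_distance = r, angle = ang)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(donor_res = integer(), donor_site = character(),
                          acceptor_res = integer(), acceptor_site = character(),
                          heavy_distance = numeric(), angle = numeric()))
  }
  dplyr::bind_rows(rows)
}

angle_deg <- function(v1, v2) {
  ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

#' Backbone CO(i) -> NH(i+k) hydrogen-bond frequency matrix
#'
#' For each carbonyl residue i and offset k in 1..4, the fraction of frames
#' in which the backbone carbonyl of residue i hydrogen-bonds (geometric
#' rule) to the backbone amide of residue i+k.
#'
#' @param traj A `trajectory`.
#' @param offsets Integer offsets (default 1:4).
#' @return An `hbond_matrix` tibble: `residue`, `offset`, `frequency`
#'   (NA where `residue + offset` exceeds the chain).
#' @export
hbond_frequency_matrix <- function(traj, offsets = 1:4) {
  stopifnot(inherits(traj, "trajectory"), n_frames(traj) >= 1)
  traj <- place_amide_hydrogens(traj)
  L <- max(traj$atoms$residue)
  rowN <- match_atom_rows(traj$atoms, "N")
  rowH <- match_atom_rows(traj$atoms, "H")
  rowO <- match_atom_rows(traj$atoms, "O")
  nf <- n_frames(traj)
  counts <- matrix(0, L, length(offsets))
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f]
    for (ki in seq_along(offsets)) {
      k <- offsets[ki]
      for (i in seq_len(L - k)) {
        j <- i + k
        if (is.na(rowH[j])) next
        O <- xyz[rowO[i], ]; N <- xyz[rowN[j], ]; H <- xyz[rowH[j], ]
        r <- dist3(O, N)
        if (r <= HB_DIST_CUTOFF &&
            angle_deg(N - H, O - H) > HB_ANGLE_CUTOFF) {
          counts[i, ki] <- counts[i, ki] + 1
        }
      }
    }
  }
  out <- tidyr::expand_grid(residue = seq_len(L), offset = offsets)
  out$frequency <- NA_real_
  for (ki in seq_along(offsets)) {
    k <- offsets[ki]
    ok <- out$offset == k & out$residue + k <= L
    out$frequency[ok] <- counts[out$residue[ok], ki] / nf
  }
  structure(out, n_frames = nf,
            class = c("hbond_matrix", class(out)))
}

#' Hydrogen-bond frequency between two atom groups
#'
#' Fraction of frames in which ANY donor-acceptor pair drawn from the two
#' groups satisfies the geometric rule (any-pair union semantics: a frame
#' counts once however many pairs qualify). Same-residue self pairs are
#' excluded.
#'
#' @param traj A `trajectory`.
#' @param donor,acceptor Group specifications from [hb_group()].
#' @return Scalar fraction in [0, 1].
#' @export
pair_hbond_frequency <- function(traj, donor, acceptor) {
  stopifnot(inherits(traj, "trajectory"), n_frames(traj) >= 1)
  traj <- place_amide_hydrogens(traj)
  dn <- resolve_group(traj, donor, role = "donor")
  ac <- resolve_group(traj, acceptor, role = "acceptor")
  nf <- n_frames(traj)
  hits <- 0
  for (f in seq_len(nf)) {
    frame <- get_frame(traj, f)
    found <- FALSE
    for (d in dn) {
      h <- if (d$h > 0) frame$coords[d$h, ] else virtual_h(frame, d)
      dh <- frame$coords[d$heavy, ]
      for (a in ac) {
        if (a$residue == d$residue && a$site == d$site) next
        ah <- frame$coords[a$heavy, ]
        r <- dist3(dh, ah)
        if (r <= HB_DIST_CUTOFF &&
            angle_deg(dh - h, ah - h) > HB_ANGLE_CUTOFF) {
          found <- TRUE; break
        }
      }
      if (found) break
    }
    hits <- hits + found
  }
  hits / nf
}

#' Specify a hydrogen-bond atom group
#'
#' @param residue Residue index (or vector of indices pooled into one
#'   group).
#' @param site `"backbone_nh"`, `"backbone_co"` or `"sidechain"`.
#' @return An `hb_group` specification.
#' @export
hb_group <- function(residue, site = c("backbone_nh", "backbone_co",
                                       "sidechain")) {
  site <- match.arg(site)
  structure(list(residue = as.integer(residue), site = site),
            class = "hb_group")
}

resolve_group <- function(traj, spec, role) {
  stopifnot(inherits(spec, "hb_group"))
  L <- max(traj$atoms$residue)
  if (any(spec$residue < 1 | spec$residue > L)) {
    rlang::abort("group residue index out of range",
                 class = "swishmc_error_group")
  }
  pool <- if (role == "donor") resolve_donors(traj) else resolve_acceptors(traj)
  out <- Filter(function(g) g$residue %in% spec$residue && g$site == spec$site,
                pool)
  if (length(out) == 0) {
    rlang::abort(paste0("cannot resolve ", role, " group: residue(s) ",
                        paste(spec$residue, collapse = ","), " have no ",
                        spec$site, " ", role,
                        if (spec$site == "backbone_nh" && 1 %in% spec$residue)
                          " (residue 1 carries no amide hydrogen)" else ""),
                 class = "swishmc_error_group")
  }
  out
}

#' Salt bridges of one frame
#'
#' Pairs of opposite-sign charged groups (side-chain beads and termini)
#' whose bead distance is at most `cutoff` (default 4 Angstrom, the
#' conventional heavy-atom criterion).
#'
#' @param frame A `conformation`.
#' @param seq A `mod_sequence` (defaults to the one in `frame`).
#' @param cutoff Distance cutoff, Angstrom.
#' @return Tibble: `res_i`, `group_i`, `res_j`, `group_j`, `distance`.
#' @export
salt_bridges <- function(frame, seq = frame$seq, cutoff = 4.0) {
  stopifnot(inherits(frame, "conformation"), !is.null(seq))
  L <- length(seq)
  rowN <- match_atom_rows(frame$atoms, "N")
  rowC <- match_atom_rows(frame$atoms, "C")
  rowSC <- match_atom_rows(frame$atoms, "SC")
  groups <- list()
  if (seq$nterm_charge != 0) {
    groups[[length(groups) + 1]] <- list(res = 1L, group = "nterm",
                                         row = rowN[1], q = seq$nterm_charge)
  }
  for (r in seq_len(L)) {
    q <- seq$residues$sc_charge[r]
    if (q != 0) {
      groups[[length(groups) + 1]] <- list(res = r, group = "sidechain",
                                           row = rowSC[r], q = q)
    }
  }
  if (seq$cterm_charge != 0) {
    groups[[length(groups) + 1]] <- list(res = L, group = "cterm",
                                         row = rowC[L], q = seq$cterm_charge)
  }
  rows <- list()
  if (length(groups) >= 2) {
    for (i in seq_len(length(groups) - 1)) for (j in (i + 1):length(groups)) {
      gi <- groups[[i]]; gj <- groups[[j]]
      if (gi$q * gj$q >= 0) next
      d <- dist3(frame$coords[gi$row, ], frame$coords[gj$row, ])
      if (d <= cutoff) {
        rows[[length(rows) + 1]] <-
          tibble::tibble(res_i = gi$res, group_i = gi$group,
                         res_j = gj$res, group_j = gj$group, distance = d)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(res_i = integer(), group_i = character(),
                          res_j = integer(), group_j = character(),
                          distance = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Radius of gyration
#'
#' Mass-weighted (default) root-mean-square distance of the atoms from
#' their weighted centroid.
#'
#' @param x A `conformation` or `trajectory`.
#' @param mass_weighting Use atom masses (default) or plain average.
#' @return Scalar (conformation) or per-frame numeric vector (trajectory),
#'   Angstrom.
#' @export
radius_of_gyration <- function(x, mass_weighting = TRUE) {
  if (inherits(x, "trajectory")) {
    return(vapply(seq_len(n_frames(x)),
                  function(f) radius_of_gyration(get_frame(x, f),
                                                 mass_weighting),
                  1.0))
  }
  stopifnot(inherits(x, "conformation"))
  w <- if (mass_weighting) x$atoms$mass else rep(1, nrow(x$coords))
  w <- w / sum(w)
  ctr <- colSums(x$coords * w)
  sqrt(sum(w * rowSums(sweep(x$coords, 2, ctr)^2)))
}

#' Two-dimensional phi/psi histogram for one residue
#'
#' @param traj A `trajectory` with stored dihedrals (internal origin) or
#'   measurable backbone.
#' @param residue Residue index; residue 1 has no phi and raises an error.
#' @param bin_width Bin width in degrees (must divide 360).
#' @return Matrix of counts over `[-180, 180)^2` (phi rows, psi columns);
#'   total count equals the number of frames.
#' @export
dihedral_histogram <- function(traj, residue, bin_width = 10) {
  stopifnot(inherits(traj, "trajectory"))
  if (360 %% bin_width != 0) {
    rlang::abort("bin_width must divide 360", class = "swishmc_error_input")
  }
  if (residue == 1) {
    rlang::abort("residue 1 has no defined phi angle (no preceding carbonyl)",
                 class = "swishmc_error_input")
  }
  if (is.null(traj$phi)) {
    dih <- lapply(seq_len(n_frames(traj)),
                  function(f) measure_dihedrals(get_frame(traj, f)))
    phi <- vapply(dih, function(d) d$phi[residue], 1.0)
    psi <- vapply(dih, function(d) d$psi[residue], 1.0)
  } else {
    phi <- traj$phi[, residue]; psi <- traj$psi[, residue]
  }
  if (any(is.na(phi)) || any(is.na(psi))) {
    rlang::abort(paste0("residue ", residue,
                        " lacks a defined phi or psi angle"),
                 class = "swishmc_error_input")
  }
  nb <- as.integer(360 / bin_width)
  brk <- seq(-180, 180, by = bin_width)
  to_bin <- function(a) {
    a <- ifelse(a >= 180, a - 360, a)     # [-180, 180)
    pmin(nb, floor((a + 180) / bin_width) + 1)
  }
  counts <- matrix(0L, nb, nb,
                   dimnames = list(phi = utils::head(brk, -1),
                                   psi = utils::head(brk, -1)))
  for (f in seq_along(phi)) {
    counts[to_bin(phi[f]), to_bin(psi[f])] <-
      counts[to_bin(phi[f]), to_bin(psi[f])] + 1L
  }
  counts
}

# ---------------------------------------------------------------------------
# Aurora-Rose N-capping motifs.

#' The Aurora-Rose capping motif patterns used for helix N-termini
#'
#' Patterns over the alphabet h (hydrophobic, including the alkyl side
#' chains of Lys/Arg), p (polar), x (indifferent) and `-` (the helix
#' boundary). Characters before `-` describe residues immediately
#' preceding the N-cap; the first character after `-` is the N-cap itself.
#'
#' @return Named character vector of patterns (Ia, Ib, IIa).
#' @export
capping_motifs <- function() {
  c(Ia = "h-xpxhx", Ib = "h-xpxph", IIa = "hp-xpxhx")
}

#' Match an N-capping motif pattern at a position
#'
#' @param seq A `mod_sequence`.
#' @param ncap_position 1-based index of the N-cap residue (first residue
#'   after the helix boundary).
#' @param pattern Motif pattern containing exactly one `-`.
#' @param motif Optional motif label carried into the result.
#' @return One-row tibble: `ncap`, `motif`, `pattern`, `matched`, `window`
#'   (residue codes covered, `|` at the boundary), `reason` (NA when
#'   matched; out-of-range windows are reported as unmatched, not errors).
#' @export
match_capping_motif <- function(seq, ncap_position, pattern, motif = NA) {
  stopifnot(inherits(seq, "mod_sequence"))
  chars <- strsplit(pattern, "")[[1]]
  if (sum(chars == "-") != 1 ||
      !all(chars %in% c("h", "p", "x", "-"))) {
    rlang::abort("pattern must be over {h, p, x} with exactly one '-'",
                 class = "swishmc_error_motif")
  }
  dash <- which(chars == "-")
  n_pre <- dash - 1
  n_post <- length(chars) - dash
  L <- length(seq)
  first <- ncap_position - n_pre
  last <- ncap_position + n_post - 1
  mk <- function(matched, reason) {
    window <- if (first >= 1 && last <= L) {
      paste0(paste(seq$residues$code[first:(ncap_position - 1)], collapse = ""),
             "|",
             paste(seq$residues$code[ncap_position:last], collapse = ""))
    } else NA_character_
    tibble::tibble(ncap = ncap_position, motif = motif, pattern = pattern,
                   matched = matched, window = window,
                   reason = reason)
  }
  if (first < 1 || last > L) {
    return(mk(FALSE, "window out of range"))
  }
  template <- chars[chars != "-"]
  idx <- first:last
  for (k in seq_along(idx)) {
    cls <- template[k]
    if (cls == "x") next
    r <- seq$residues[idx[k], ]
    ok <- if (cls == "h") r$in_h else r$in_p
    if (!ok) {
      return(mk(FALSE, paste0("residue ", idx[k], " (", r$code,
                              ") is not in class ", cls)))
    }
  }
  mk(TRUE, NA_character_)
}

#' Scan a sequence for N-capping motif matches
#'
#' @param seq A `mod_sequence`.
#' @param motifs Named pattern vector (default [capping_motifs()]).
#' @param positions Candidate N-cap positions (default all residues).
#' @return Tibble of [match_capping_motif()] rows for every
#'   (position, motif) combination.
#' @export
capping_motif_report <- function(seq, motifs = capping_motifs(),
                                 positions = seq_len(length(seq))) {
  purrr::map_dfr(positions, function(p) {
    purrr::imap_dfr(motifs, function(pat, id) {
      match_capping_motif(seq, p, pat, motif = id)
    })
  })
}
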