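# Shared fixtures and independent oracles. The oracles deliberately
# re-derive quantities from first principles (plain double loops over the
# published formulas) so they share no code with the implementation paths
# they check.

WT_SEQ <- "MATLEKLMKAFESLKSFQQ"

wt_sequence <- function(...) parse_modified_sequence(WT_SEQ, ...)

KB <- 0.0019872041

# --- independent Kabsch-Sander oracle ------------------------------------

oracle_ks_energy <- function(N, H, C, O) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  0.084 * 332 * (1 / d(O, N) + 1 / d(C, H) - 1 / d(O, H) - 1 / d(C, N))
}

# all CO(i) -> NH(j) bond decisions for a frame, by plain loops
oracle_bond_matrix <- function(frame) {
  frame <- place_amide_hydrogens(frame)
  N <- atom_coords(frame, "N"); H <- atom_coords(frame, "H")
  C <- atom_coords(frame, "C"); O <- atom_coords(frame, "O")
  L <- nrow(N)
  out <- matrix(FALSE, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j || is.na(H[j, 1])) next
    out[i, j] <- oracle_ks_energy(N[j, ], H[j, ], C[i, ], O[i, ]) < -0.5
  }
  out
}

# --- brute-force energy oracle -------------------------------------------

# Naive re-derivation of the coarse-grained energy: every term written as an
# explicit double loop from the model definition.
oracle_energy <- function(conf, seq, params) {
  at <- atom_table(seq)
  L <- length(seq)
  xyz <- conf$coords
  # torsion
  tor <- 0
  basins <- list(list(c = c(params$helix_phi, params$helix_psi),
                      w = params$helix_width, d = params$helix_depth),
                 list(c = c(params$ext_phi, params$ext_psi),
                      w = params$ext_width, d = params$ext_depth))
  wrap <- function(a) { w <- (a + 180) %% 360 - 180; ifelse(w <= -180, 180, w) }
  for (r in seq_len(L)) for (b in basins) {
    dphi <- wrap(conf$phi[r] - b$c[1]); dpsi <- wrap(conf$psi[r] - b$c[2])
    tor <- tor - b$d * exp(-(dphi^2 + dpsi^2) / (2 * b$w^2))
  }
  # per-atom attributes
  q <- numeric(nrow(at)); eps <- numeric(nrow(at)); sig <- numeric(nrow(at))
  sc <- which(at$atom == "SC")
  q[sc] <- seq$residues$sc_charge[at$residue[sc]]
  q[at$atom == "N" & at$residue == 1] <- seq$nterm_charge
  q[at$atom == "C" & at$residue == L] <- seq$cterm_charge
  eps[at$atom == "CA"] <- params$eps_ca
  sig[at$atom == "CA"] <- params$sigma_ca
  hres <- seq$residues$in_h[at$residue[sc]]
  eps[sc] <- ifelse(hres, params$eps_sc_h, params$eps_sc_p)
  sig[sc] <- params$sigma_sc
  apolar <- at$atom %in% c("CA", "C") |
    (at$atom == "SC" & seq$residues$in_h[at$residue])
  heavy <- at$atom != "H"
  n <- nrow(at)
  lj <- 0; elec <- 0; nc <- integer(n); clash <- FALSE
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a >= b || !heavy[a] || !heavy[b]) next
    dr <- abs(at$residue[a] - at$residue[b])
    if (dr == 0) next
    rr <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
    if (dr >= 2) {
      if (rr < params$cutoff_exposure) { nc[a] <- nc[a] + 1; nc[b] <- nc[b] + 1 }
      if (rr < params$hardcore) clash <- TRUE
      if (eps[a] > 0 && eps[b] > 0) {
        e <- sqrt(eps[a] * eps[b]); s <- (sig[a] + sig[b]) / 2
        lj <- lj + 4 * e * ((s / rr)^12 - (s / rr)^6)
      }
    }
    if (q[a] != 0 && q[b] != 0) {
      elec <- elec + 332.0637 * q[a] * q[b] /
        (params$dielectric * rr) * exp(-rr / params$debye_length)
    }
  }
  W <- -params$s_apolar * sum(pmax(0, params$n_max - nc[apolar & heavy]))
  list(U0 = if (clash) Inf else tor + lj + elec, W = W,
       torsion = tor, lj = lj, elec = elec)
}

# --- geometry helpers -----------------------------------------------------

random_rotation <- function(seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3)
  qr.Q(qr(m)) * sign(det(qr.Q(qr(m))))
}

rigid_transform <- function(conf, seed = 1, shift = c(5, -3, 11)) {
  R <- random_rotation(seed)
  out <- conf
  out$coords <- sweep(conf$coords %*% t(R), 2, shift, "+")
  out
}

random_conformation <- function(seq, seed) {
  set.seed(seed)
  L <- length(seq)
  build_conformation(seq, cbind(runif(L, -179, 180), runif(L, -179, 180)))
}

# place an explicit donor/acceptor geometry: donor heavy at origin, H on the
# x axis, acceptor heavy at the requested heavy-heavy distance and
# heavy-H-heavy angle
hb_test_geometry <- function(distance, angle) {
  Dh <- c(0, 0, 0)
  H <- c(1, 0, 0)
  th <- angle * pi / 180
  # acceptor positioned so that angle(Dh, H, A) = angle and |Dh - A| = distance
  # solve on the xy plane: A = H + t * (cos(pi - th'), ...) -- parameterise by
  # direction from H making angle `angle` with H->Dh
  dirHD <- (Dh - H)
  base <- atan2(0, -1)  # pi
  phi2 <- base - th
  f <- function(t) {
    A <- H + t * c(cos(phi2), sin(phi2), 0)
    sqrt(sum((A - Dh)^2)) - distance
  }
  t <- stats::uniroot(f, c(1e-6, distance + 2), tol = 1e-12)$root
  A <- H + t * c(cos(phi2), sin(phi2), 0)
  list(donor_heavy = Dh, H = H, acceptor_heavy = A)
}

dist3 <- function(a, b) sqrt(sum((a - b)^2))

# chi-square goodness of fit with low-expectation bins merged
chi2_pvalue <- function(counts, probs, min_expected = 5) {
  stopifnot(length(counts) == length(probs))
  n <- sum(counts)
  ord <- order(probs)
  counts <- counts[ord]; probs <- probs[ord]
  while (length(probs) > 2 && n * probs[1] < min_expected) {
    probs <- c(probs[1] + probs[2], probs[-(1:2)])
    counts <- c(counts[1] + counts[2], counts[-(1:2)])
    ord2 <- order(probs); probs <- probs[ord2]; counts <- counts[ord2]
  }
  suppressWarnings(stats::chisq.test(counts, p = probs / sum(probs))$p.value)
}

# Hand-placed conformation: coordinates given as a named list "res:atom",
# everything unspecified parked far away on the x axis so it cannot
# participate in any contact.
synthetic_conformation <- function(seq, placed = list()) {
  at <- atom_table(seq)
  xyz <- cbind(1000 + 50 * at$residue + 5 * seq_len(nrow(at)), 0, 0)
  for (key in names(placed)) {
    parts <- strsplit(key, ":")[[1]]
    row <- which(at$residue == as.integer(parts[1]) & at$atom == parts[2])
    stopifnot(length(row) == 1)
    xyz[row, ] <- placed[[key]]
  }
  structure(list(coords = xyz, atoms = at, phi = NULL, psi = NULL, seq = seq),
            class = "conformation")
}

# stack hand-placed frames into a trajectory
synthetic_trajectory <- function(seq, frames) {
  confs <- lapply(frames, function(p) synthetic_conformation(seq, p))
  coords <- array(NA_real_, c(nrow(confs[[1]]$coords), 3, length(confs)))
  for (i in seq_along(confs)) coords[, , i] <- confs[[i]]$coords
  new_trajectory(coords, confs[[1]]$atoms, seq = seq)
}
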