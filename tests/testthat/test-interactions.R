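test_that("the hydrogen-bond rule has inclusive distance, exclusive angle bounds", {
  expect_true(hbond_geometry_ok(3.4, 150))
  expect_false(hbond_geometry_ok(3.6, 170))
  expect_false(hbond_geometry_ok(3.5, 120.0))
  expect_true(hbond_geometry_ok(3.5, 120.1))
  expect_true(hbond_geometry_ok(3.5, 180))
  expect_false(hbond_geometry_ok(3.500001, 179))
  # boundary behaviour over a geometry grid
  for (d in c(2.5, 3.0, 3.4, 3.5, 3.6, 4.0)) {
    for (a in c(90, 119.9, 120, 120.1, 150, 179)) {
      g <- hb_test_geometry(d, a)
      dd <- dist3(g$donor_heavy, g$acceptor_heavy)
      aa <- 180 / pi * acos(sum((g$donor_heavy - g$H) * (g$acceptor_heavy - g$H)) /
                              (dist3(g$donor_heavy, g$H) *
                                 dist3(g$acceptor_heavy, g$H)))
      expect_equal(dd, d, tolerance = 1e-6)
      expect_equal(aa, a, tolerance = 1e-6)
      expect_equal(hbond_geometry_ok(d, a), d <= 3.5 && a > 120)
    }
  }
})

test_that("geometric bonds on hand-placed frames follow the rule end-to-end", {
  seq2 <- parse_modified_sequence("AAAA")
  mk <- function(distance, angle) {
    g <- hb_test_geometry(distance, angle)
    synthetic_conformation(seq2, list(`2:N` = g$donor_heavy, `2:H` = g$H,
                                      `4:O` = g$acceptor_heavy))
  }
  hb <- geometric_hbonds(mk(3.4, 150))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor_res, 2)
  expect_equal(hb$acceptor_res, 4)
  expect_equal(hb$heavy_distance, 3.4, tolerance = 1e-6)
  expect_equal(hb$angle, 150, tolerance = 1e-4)
  expect_equal(nrow(geometric_hbonds(mk(3.6, 170))), 0)
  expect_equal(nrow(geometric_hbonds(mk(3.5, 120))), 0)
  expect_equal(nrow(geometric_hbonds(mk(3.5, 120.1))), 1)
})

test_that("geometric bonds are invariant under rigid-body motion", {
  wt <- wt_sequence("pThr3")
  conf <- make_ideal_structure(wt, "alpha")
  hb1 <- geometric_hbonds(conf)
  hb2 <- geometric_hbonds(rigid_transform(conf, seed = 4))
  expect_equal(hb1$donor_res, hb2$donor_res)
  expect_equal(hb1$acceptor_res, hb2$acceptor_res)
  expect_equal(hb1$heavy_distance, hb2$heavy_distance, tolerance = 1e-8)
})

test_that("the frequency matrix counts per-frame indicators", {
  seq4 <- parse_modified_sequence("AAAAA")
  g <- hb_test_geometry(3.0, 160)
  # place the carbonyl O of residue 2 at the acceptor position relative to
  # the amide of residue 5: CO(2) -> NH(5) is offset k = 3
  bonded <- list(`5:N` = g$donor_heavy, `5:H` = g$H, `2:O` = g$acceptor_heavy)
  traj <- synthetic_trajectory(seq4, list(bonded, list(), bonded, list()))
  m <- hbond_frequency_matrix(traj)
  expect_s3_class(m, "hbond_matrix")
  expect_equal(m$frequency[m$residue == 2 & m$offset == 3], 0.5)
  expect_equal(sum(m$frequency > 0, na.rm = TRUE), 1)
  # masked cells: i + k beyond the chain end
  expect_true(all(is.na(m$frequency[m$residue + m$offset > 5])))
  expect_true(all(m$frequency >= 0 & m$frequency <= 1, na.rm = TRUE))
})

test_that("an ideal alpha-helix trajectory has its bonds at offset 4 only", {
  wt <- wt_sequence()
  traj <- as_trajectory(make_ideal_structure(wt, "alpha"))
  m <- hbond_frequency_matrix(traj)
  k4 <- m$frequency[m$offset == 4 & m$residue >= 2 & m$residue <= 14]
  expect_true(all(k4 == 1))
  expect_true(all(m$frequency[m$offset %in% 1:2] == 0, na.rm = TRUE))
  # empty bond set: extended chain gives an all-zero matrix
  me <- hbond_frequency_matrix(as_trajectory(make_ideal_structure(wt, "extended")))
  expect_true(all(me$frequency == 0, na.rm = TRUE))
})

test_that("group frequencies use any-pair union semantics", {
  seq4 <- parse_modified_sequence("AAAAA")
  g <- hb_test_geometry(3.0, 160)
  bond_to <- function(acceptor_key) {
    l <- list(g$donor_heavy, g$H, g$acceptor_heavy)
    names(l) <- c("5:N", "5:H", acceptor_key)
    l
  }
  # two acceptor oxygens bond in disjoint halves of the frames
  traj <- synthetic_trajectory(seq4, list(bond_to("2:O"), bond_to("2:O"),
                                          bond_to("3:O"), bond_to("3:O")))
  f_union <- pair_hbond_frequency(traj, hb_group(5, "backbone_nh"),
                                  hb_group(c(2, 3), "backbone_co"))
  expect_equal(f_union, 1.0)
  expect_equal(pair_hbond_frequency(traj, hb_group(5, "backbone_nh"),
                                    hb_group(2, "backbone_co")), 0.5)
  # single bond present in 1 of 4 frames
  traj2 <- synthetic_trajectory(seq4, list(bond_to("2:O"), list(),
                                           list(), list()))
  expect_equal(pair_hbond_frequency(traj2, hb_group(5, "backbone_nh"),
                                    hb_group(2, "backbone_co")), 0.25)
  # unresolvable specs error: residue 1 has no amide donor
  expect_error(pair_hbond_frequency(traj2, hb_group(1, "backbone_nh"),
                                    hb_group(2, "backbone_co")),
               class = "swishmc_error_group")
  expect_error(pair_hbond_frequency(traj2, hb_group(99, "backbone_nh"),
                                    hb_group(2, "backbone_co")),
               class = "swishmc_error_group")
})

test_that("matrix cells equal the mean of per-frame indicators", {
  wt <- wt_sequence()
  set.seed(402)
  confs <- lapply(1:3, function(s) random_conformation(wt, 400 + s))
  coords <- array(NA_real_, c(nrow(confs[[1]]$coords), 3, 3))
  for (i in 1:3) coords[, , i] <- confs[[i]]$coords
  traj <- new_trajectory(coords, confs[[1]]$atoms, seq = wt)
  m <- hbond_frequency_matrix(traj)
  for (row in which(!is.na(m$frequency) & m$frequency > 0)) {
    i <- m$residue[row]; k <- m$offset[row]
    f <- pair_hbond_frequency(traj, hb_group(i + k, "backbone_nh"),
                              hb_group(i, "backbone_co"))
    expect_gte(f, m$frequency[row])  # union over >= the single pair
  }
})

test_that("salt bridges require opposite charges within the cutoff", {
  pt3 <- wt_sequence("pThr3")
  near <- synthetic_conformation(pt3, list(`3:SC` = c(0, 0, 0),
                                           `6:SC` = c(3.5, 0, 0)))
  sb <- salt_bridges(near)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$res_i, 3); expect_equal(sb$res_j, 6)
  expect_equal(sb$distance, 3.5, tolerance = 1e-9)
  # acetylating the lysine removes the charge and the bridge
  both <- wt_sequence(c("pThr3", "acLys6"))
  near2 <- synthetic_conformation(both, list(`3:SC` = c(0, 0, 0),
                                             `6:SC` = c(3.5, 0, 0)))
  expect_equal(nrow(salt_bridges(near2)), 0)
  # like charges never bridge
  wt <- wt_sequence()
  acid <- synthetic_conformation(wt, list(`5:SC` = c(0, 0, 0),
                                          `12:SC` = c(3.0, 0, 0)))
  expect_equal(nrow(salt_bridges(acid)), 0)
  # beyond the cutoff
  far <- synthetic_conformation(pt3, list(`3:SC` = c(0, 0, 0),
                                          `6:SC` = c(4.5, 0, 0)))
  expect_equal(nrow(salt_bridges(far)), 0)
})

test_that("radius of gyration matches closed-form cases", {
  one <- parse_modified_sequence("A")
  single <- synthetic_conformation(one, list(`1:CA` = c(1, 2, 3)))
  single$coords <- single$coords[single$atoms$atom == "CA", , drop = FALSE]
  single$atoms <- single$atoms[single$atoms$atom == "CA", ]
  expect_equal(radius_of_gyration(single), 0)
  # two equal-mass points 2 Angstrom apart
  two <- single
  two$coords <- rbind(c(0, 0, 0), c(2, 0, 0))
  two$atoms <- tibble::tibble(residue = c(1L, 1L), atom = c("CA", "CA"),
                              element = "C", mass = c(12, 12))
  expect_equal(radius_of_gyration(two), 1)
  # four equal-mass points on a square of side a
  a <- 3.2
  sq <- two
  sq$coords <- rbind(c(0, 0, 0), c(a, 0, 0), c(a, a, 0), c(0, a, 0))
  sq$atoms <- tibble::tibble(residue = 1L, atom = "CA", element = "C",
                             mass = 12)[rep(1, 4), ]
  expect_equal(radius_of_gyration(sq), a / sqrt(2))
  # mass weighting: doubling one mass shifts the centroid
  uneq <- two
  uneq$atoms$mass <- c(24, 12)
  expect_lt(radius_of_gyration(uneq), 1)
  expect_equal(radius_of_gyration(uneq, mass_weighting = FALSE), 1)
})

test_that("dihedral histograms cover the frames exactly", {
  wt <- wt_sequence()
  sys <- peptide_system(wt)
  r <- run_mc(sys, 1, n_sweeps = 50, seed = 6, record_every = 1)
  traj <- state_trajectory(r)
  h <- dihedral_histogram(traj, 5, bin_width = 10)
  expect_equal(sum(h), n_frames(traj))
  expect_equal(dim(h), c(36, 36))
  # static trajectory: a single occupied bin
  st <- as_trajectory(make_ideal_structure(wt, "alpha"))
  h1 <- dihedral_histogram(st, 5, bin_width = 10)
  expect_equal(sum(h1 > 0), 1)
  expect_equal(unname(h1["-60", "-50"]), 1)
  # a single 360-degree bin holds everything
  h360 <- dihedral_histogram(traj, 5, bin_width = 360)
  expect_equal(dim(h360), c(1, 1))
  expect_equal(sum(h360), n_frames(traj))
  # residue 1 has no phi angle
  expect_error(dihedral_histogram(traj, 1), class = "swishmc_error_input")
})

test_that("uniform random dihedrals give a flat histogram", {
  wt <- parse_modified_sequence("AAA")
  set.seed(77)
  n <- 4000
  phi <- matrix(runif(3 * n, -180, 180), n, 3)
  psi <- matrix(runif(3 * n, -180, 180), n, 3)
  coords <- array(0, c(17, 3, 1))
  traj <- new_trajectory(coords[, , 1, drop = FALSE][, , rep(1, n), drop = FALSE],
                         atom_table(wt), seq = wt, phi = phi, psi = psi)
  h <- dihedral_histogram(traj, 2, bin_width = 60)
  expect_gt(chi2_pvalue(as.vector(h), rep(1 / 36, 36)), 0.01)
})

test_that("the three capping-motif claims hold on the printed sequence", {
  wt <- wt_sequence()
  pats <- capping_motifs()
  ib <- match_capping_motif(wt, 2, pats[["Ib"]], motif = "Ib")
  expect_true(ib$matched)
  iia <- match_capping_motif(wt, 4, pats[["IIa"]], motif = "IIa")
  expect_true(iia$matched)
  ia <- match_capping_motif(wt, 11, pats[["Ia"]], motif = "Ia")
  expect_true(ia$matched)
  # character-by-character verification of the Ib alignment at Ala2:
  # M1 = h | A2 = x, T3 = p, L4 = x, E5 = p, K6 = h
  cls <- residue_class(wt)
  expect_true(cls$in_h[1]); expect_true(cls$in_p[3])
  expect_true(cls$in_p[5]); expect_true(cls$in_h[6])
  # the trivial pattern matches anywhere the window fits
  expect_true(match_capping_motif(wt, 10, "x-x")$matched)
  expect_false(match_capping_motif(wt, 1, "x-x")$matched)  # out of range
  expect_equal(match_capping_motif(wt, 1, "x-x")$reason, "window out of range")
})

test_that("motif matching is a pure function of the class alphabet", {
  wt <- wt_sequence()
  report <- capping_motif_report(wt)
  claimed <- report[report$matched &
                      paste(report$ncap, report$motif) %in%
                        c("2 Ib", "4 IIa", "11 Ia"), ]
  expect_equal(nrow(claimed), 3)
  # Ib matches at N-cap 2 only, anywhere on the chain
  ib_hits <- report$ncap[report$motif == "Ib" & report$matched]
  expect_equal(ib_hits, 2)
  # malformed patterns are rejected
  expect_error(match_capping_motif(wt, 3, "hxp"), class = "swishmc_error_motif")
  expect_error(match_capping_motif(wt, 3, "h-x-p"), class = "swishmc_error_motif")
  expect_error(match_capping_motif(wt, 3, "h-zp"), class = "swishmc_error_motif")
})
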