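test_that("Kabsch-Sander energy obeys its closed form and limits", {
  # C and O on the perpendicular bisector plane of N-H, equidistant from
  # both: all four cross distances equal, the reciprocal terms cancel
  don <- list(N = c(0, 0, 0), H = c(2, 0, 0))
  ac2 <- list(C = c(1, 0, 2), O = c(1, 2, 0))
  expect_equal(ks_hbond_energy(don, ac2), 0, tolerance = 1e-12)
  don <- list(N = c(0, 0, 0), H = c(1, 0, 0))
  # 1/r decay: far pair is negligibly bound
  far <- list(C = c(50, 0, 0), O = c(51, 0, 0))
  expect_lt(abs(ks_hbond_energy(don, far)), 0.01)
  # ideal alpha helix i -> i+4 pair is strongly bound
  h <- place_amide_hydrogens(make_ideal_structure(wt_sequence(), "alpha"))
  N <- atom_coords(h, "N"); H <- atom_coords(h, "H")
  C <- atom_coords(h, "C"); O <- atom_coords(h, "O")
  e <- ks_hbond_energy(list(N = N[9, ], H = H[9, ]),
                       list(C = C[5, ], O = O[5, ]))
  expect_lt(e, -0.5)
  expect_equal(e, oracle_ks_energy(N[9, ], H[9, ], C[5, ], O[5, ]),
               tolerance = 1e-12)
  # coincident atoms are malformed geometry
  expect_error(ks_hbond_energy(don, list(C = c(0.1, 0, 0), O = c(5, 0, 0))),
               class = "swishmc_error_geometry")
})

test_that("amide hydrogen placement follows the carbonyl-opposition rule", {
  wt <- wt_sequence()
  conf <- random_conformation(wt, 5)
  traj <- as_trajectory(conf)
  stripped <- new_trajectory(
    traj$coords[traj$atoms$atom != "H", , , drop = FALSE],
    traj$atoms[traj$atoms$atom != "H", ], seq = wt)
  placed <- place_amide_hydrogens(stripped)
  N <- atom_coords(get_frame(placed, 1), "N")
  H <- atom_coords(get_frame(placed, 1), "H")
  C <- atom_coords(get_frame(placed, 1), "C")
  O <- atom_coords(get_frame(placed, 1), "O")
  expect_true(all(is.na(H[1, ])))
  for (i in 2:19) {
    expect_equal(dist3(N[i, ], H[i, ]), 1.0, tolerance = 1e-6)
    u <- (C[i - 1, ] - O[i - 1, ])
    u <- u / sqrt(sum(u^2))
    expect_equal(H[i, ], N[i, ] + u, tolerance = 1e-6)
  }
  # placement agrees with the builder's own hydrogens
  expect_equal(H[-1, ], atom_coords(conf, "H")[-1, ], tolerance = 1e-6)
  # idempotence: frames that already contain H are returned unchanged
  again <- place_amide_hydrogens(placed)
  expect_identical(again$coords, placed$coords)
})

test_that("ideal structures are assigned their textbook helical classes", {
  wt <- wt_sequence()
  alpha <- assign_ss(make_ideal_structure(wt, "alpha"))
  expect_true(all(alpha[2:18] == "H"))
  expect_true(all(alpha[c(1, 19)] != "H"))
  g <- assign_ss(make_ideal_structure(wt, "three_ten"))
  expect_true(all(g[2:18] == "G"))
  expect_false(any(g == "H"))
  ext <- assign_ss(make_ideal_structure(wt, "extended"))
  expect_false(any(ext %in% c("H", "G")))
})

test_that("bond decisions agree with the independent Kabsch-Sander oracle", {
  wt <- wt_sequence()
  frames <- c(lapply(c("alpha", "three_ten", "extended"),
                     function(k) make_ideal_structure(wt, k)),
              list(make_ideal_structure(wt, "mixed",
                     segments = list(list(start = 2, end = 7, kind = "alpha"),
                                     list(start = 11, end = 16, kind = "alpha")))),
              lapply(1:4, function(s) random_conformation(wt, 300 + s)))
  for (f in frames) {
    expect_identical(ks_bond_matrix(f), unname(oracle_bond_matrix(f)),
                     ignore_attr = TRUE)
  }
})

test_that("assignment is invariant under rigid-body motion", {
  wt <- wt_sequence()
  conf <- make_ideal_structure(wt, "mixed",
            segments = list(list(start = 2, end = 7, kind = "alpha"),
                            list(start = 11, end = 16, kind = "three_ten")))
  moved <- rigid_transform(conf, seed = 9)
  expect_identical(assign_ss(conf), assign_ss(moved))
})

test_that("a pure 3-10 bond pattern yields G labels only", {
  wt <- wt_sequence()
  conf <- make_ideal_structure(wt, "mixed",
            segments = list(list(start = 4, end = 9, kind = "three_ten")))
  bonds <- ks_bond_matrix(conf)
  # verify the constructed geometry has consecutive i->i+3 bonds and no
  # i->i+4 bonds in the helical stretch
  expect_true(any(bonds[cbind(4:6, 7:9)]))
  expect_false(any(bonds[cbind(1:15, 5:19)]))
  lab <- assign_ss(conf)
  expect_true(any(lab == "G"))
  expect_false(any(lab == "H"))
})

test_that("helicity arithmetic matches hand-computed fractions", {
  # 1 frame, 2 of 19 residues helical
  one <- make_label_trajectory(paste0("CH", strrep("C", 15), "GC"))
  p1 <- helicity(one, equilibration_fraction = 0)
  expect_equal(attr(p1, "overall"), 2 / 19)
  # all-coil
  p0 <- helicity(make_label_trajectory(rep(strrep("C", 19), 3)),
                 equilibration_fraction = 0)
  expect_equal(attr(p0, "overall"), 0)
  # 4 frames with helical counts 0, 2, 2, 4
  labs <- make_label_trajectory(c(strrep("C", 19),
                                  paste0("HH", strrep("C", 17)),
                                  paste0("GG", strrep("C", 17)),
                                  paste0("HHHH", strrep("C", 15))))
  p <- helicity(labs, equilibration_fraction = 0)
  expect_equal(attr(p, "overall"), (0 + 2 + 2 + 4) / (4 * 19))
  # averaging order equivalence: residue-mean of fractions == frame-mean
  expect_equal(mean(p$f_helical), mean(helicity_series(labs)))
  expect_true(all(p$f_alpha + p$f_three_ten <= 1))
  # empty after discard
  expect_error(helicity(labs[integer(), , drop = FALSE]),
               class = "swishmc_error_empty")
})

test_that("the mixed two-helix fixture localises helicity to its segments", {
  wt <- wt_sequence()
  conf <- make_ideal_structure(wt, "mixed",
            segments = list(list(start = 2, end = 7, kind = "alpha"),
                            list(start = 11, end = 16, kind = "alpha")))
  prof <- helicity(as_trajectory(conf), equilibration_fraction = 0)
  helical <- which(prof$f_helical > 0)
  expect_true(all(helical %in% 2:16))
  expect_true(any(prof$f_helical[3:6] > 0))
  expect_true(any(prof$f_helical[12:15] > 0))
  expect_equal(prof$f_helical[c(1, 9, 19)], c(0, 0, 0))
})
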