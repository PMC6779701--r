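toy4 <- function() make_enumerable_system(2, 4, seed = 5)

# 4-rung ladder without the unscaled rung: fine for these structural tests,
# the missing-reporting-stream warning is expected
run4 <- function(sys, ...) {
  suppressWarnings(run_swish(sys, build_ladder(0.7, 1.3, 0.2), ...))
}

test_that("a single-rung ladder reduces to plain Metropolis MC", {
  sys <- toy4()
  r1 <- suppressWarnings(
    run_swish(sys, build_ladder(0.9, 0.9, 0.1), n_sweeps = 500,
              swap_interval = 50, seed = 3, record_every = 1))
  r2 <- run_mc(sys, 0.9, n_sweeps = 500, seed = 3, record_every = 1)
  expect_equal(r1$frames[[1]]$micro, r2$frames[[1]]$micro)
  expect_equal(nrow(r1$exchange_log), 0)
})

test_that("swap_interval beyond the sweep count yields no exchange attempts", {
  sys <- toy4()
  r <- run_swish(sys, build_ladder(0.8, 1.2, 0.2), n_sweeps = 40,
                 swap_interval = 100, seed = 1)
  expect_equal(nrow(r$exchange_log), 0)
})

test_that("runs are exactly reproducible from (seed, config)", {
  wt <- wt_sequence()
  sys <- peptide_system(wt)
  lad <- build_ladder(0.9, 1.1, 0.1)
  r1 <- run_swish(sys, lad, n_sweeps = 60, swap_interval = 10, seed = 42)
  r2 <- run_swish(sys, lad, n_sweeps = 60, swap_interval = 10, seed = 42)
  expect_identical(r1$frames, r2$frames)
  expect_identical(r1$exchange_log, r2$exchange_log)
  r3 <- run_swish(sys, lad, n_sweeps = 60, swap_interval = 10, seed = 43)
  expect_false(identical(r1$frames, r3$frames))
  # byte-identical trajectory and log files
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(state_trajectory(r1, 1), f1)
  write_multimodel_pdb(state_trajectory(r2, 1), f2)
  expect_identical(readLines(f1), readLines(f2))
  l1 <- withr::local_tempfile(); l2 <- withr::local_tempfile()
  write_exchange_log(r1, l1); write_exchange_log(r2, l2)
  expect_identical(readLines(l1), readLines(l2))
})

test_that("exchanges only touch adjacent rungs on the alternating schedule", {
  sys <- toy4()
  r <- run4(sys, n_sweeps = 400,
                 swap_interval = 10, seed = 7)
  log <- r$exchange_log
  expect_true(all(log$pair_high == log$pair_low + 1))
  expect_true(all(log$step %% 10 == 0))
  phase_parity <- (log$step / 10) %% 2
  expect_true(all(log$pair_low[phase_parity == 1] %% 2 == 1))
  expect_true(all(log$pair_low[phase_parity == 0] %% 2 == 0))
  # the replica<->rung map stays a bijection throughout (replay check)
  s <- summarize_exchanges(r)
  expect_true(all(rowSums(s$occupancy) == s$n_intervals))
  expect_true(all(colSums(s$occupancy) == s$n_intervals))
})

test_that("demux inverts the replica/rung assignment and round-trips", {
  sys <- toy4()
  r <- run4(sys, n_sweeps = 400,
                 swap_interval = 10, seed = 11)
  expect_gt(sum(r$exchange_log$accepted), 0)
  dm <- demux(r)
  # every frame carries the replica that generated it: demux must agree
  for (rep_id in seq_along(dm)) {
    expect_true(all(dm[[rep_id]]$replica == rep_id))
  }
  # re-multiplexing restores the original per-rung frames bit-exactly
  rm_ <- remux(dm, length(r$ladder))
  for (s in seq_along(rm_)) {
    expect_identical(rm_[[s]]$micro, r$frames[[s]]$micro)
    expect_identical(rm_[[s]]$sweep, r$frames[[s]]$sweep)
    expect_identical(rm_[[s]]$replica, r$frames[[s]]$replica)
  }
})

test_that("with no accepted swaps, replica- and state-continuous agree", {
  sys <- toy4()
  r <- run4(sys, n_sweeps = 100,
                 swap_interval = 10, seed = 2)
  log <- r$exchange_log
  log$accepted <- FALSE
  dm <- demux(log, r$frames, r$config)
  for (s in seq_along(dm)) {
    expect_equal(dm[[s]]$micro, r$frames[[s]]$micro)
    expect_equal(unique(dm[[s]]$state), s)
  }
})

test_that("a gapped or inconsistent exchange log is rejected by step", {
  sys <- toy4()
  r <- run4(sys, n_sweeps = 100,
                 swap_interval = 10, seed = 2)
  gap <- r$exchange_log[r$exchange_log$step != 30, ]
  expect_error(demux(gap, r$frames, r$config), "step 30",
               class = "swishmc_error_demux")
  bad <- r$exchange_log
  bad$pair_high[1] <- bad$pair_low[1] + 2L
  expect_error(demux(bad, r$frames, r$config),
               class = "swishmc_error_demux")
})

test_that("a ladder without the unscaled rung warns and has no reporting stream", {
  sys <- toy4()
  expect_warning(
    r <- run_swish(sys, c(0.7, 0.8), n_sweeps = 20, swap_interval = 5,
                   seed = 1),
    class = "swishmc_warn_no_unscaled")
  expect_length(r$frames, 2)
})

test_that("every rung of a SWISH run samples its own Boltzmann distribution", {
  # scaled-down version of the exhaustive-enumeration check
  sys <- make_enumerable_system(2, 4, seed = 21)
  lad <- build_ladder(0.5, 1.5, 0.5)
  r <- run_swish(sys, lad, n_sweeps = 20000, swap_interval = 5, seed = 31,
                 record_every = 10)
  for (k in seq_along(lad)) {
    counts <- tabulate(r$frames[[k]]$micro, nbins = 16)
    probs <- exact_distribution(sys, lambda = lad[k])
    expect_gt(chi2_pvalue(counts, probs), 0.01)
  }
})

test_that("replicas traverse the ladder on a symmetric toy system", {
  # equal W everywhere: all swaps accepted, occupancy spreads over rungs
  sys <- make_enumerable_system(2, 3, U0 = rep(0, 9), W = rep(1, 9))
  r <- run4(sys, n_sweeps = 2000,
                 swap_interval = 10, seed = 13)
  s <- summarize_exchanges(r)
  expect_equal(s$mean_acceptance, 1)
  expect_gt(min(s$round_trips), 0)
  occ <- s$occupancy / rowSums(s$occupancy)
  expect_true(all(abs(occ - 0.25) < 0.1))
})

test_that("the full-energy exponent path gives the same trajectory", {
  sys <- toy4()
  r1 <- run4(sys, n_sweeps = 200, swap_interval = 10, seed = 5)
  r2 <- run4(sys, n_sweeps = 200, swap_interval = 10, seed = 5,
             exponent_method = "full")
  expect_equal(r1$exchange_log$delta, r2$exchange_log$delta, tolerance = 1e-10)
  expect_identical(r1$frames, r2$frames)
})
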