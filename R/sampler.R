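#' Build a lambda ladder
#'
#' The SWISH scaling schedule: a uniformly spaced, strictly increasing set
#' of solvent-scaling coefficients. The production ladder of the huntingtin
#' study runs from 0.85 to 1.10 in steps of 0.05 (6 replicas); the pilot
#' ladder from 0.6 to 1.3 in steps of 0.1 (8 replicas). Non-commensurate
#' bounds raise an error rather than silently truncating.
#'
#' @param lambda_min,lambda_max Ladder bounds (`lambda_min <= lambda_max`).
#' @param step Positive rung spacing.
#' @return A `lambda_ladder`: numeric vector of rung values.
#' @examples
#' build_ladder(0.85, 1.10, 0.05)  # 6 rungs
#' build_ladder(0.6, 1.3, 0.1)     # 8 rungs
#' @export
build_ladder <- function(lambda_min, lambda_max, step) {
  if (lambda_min > lambda_max) {
    rlang::abort("lambda_min must not exceed lambda_max",
                 class = "swishmc_error_ladder")
  }
  if (step <= 0) {
    rlang::abort("step must be positive", class = "swishmc_error_ladder")
  }
  k <- (lambda_max - lambda_min) / step
  if (abs(k - round(k)) > 1e-9) {
    rlang::abort("(lambda_max - lambda_min) is not an integer multiple of step",
                 class = "swishmc_error_ladder")
  }
  values <- lambda_min + step * seq(0, round(k))
  values[length(values)] <- lambda_max
  structure(values, class = "lambda_ladder")
}

#' @export
print.lambda_ladder <- function(x, ...) {
  cat("<lambda_ladder>", paste(format(unclass(x)), collapse = ", "), "\n")
  invisible(x)
}

ladder_unscaled_index <- function(ladder) {
  i <- which(abs(unclass(ladder) - 1) < 1e-12)
  if (length(i) == 0) NA_integer_ else i[1]
}

#' Exchange exponent for a SWISH swap
#'
#' For two replicas at the same temperature whose Hamiltonians differ only
#' in the lambda-scaled solvent term (`U = U0 + lambda * W`), the general
#' Hamiltonian-exchange exponent
#' `beta * [(U_m(x_n) + U_n(x_m)) - (U_m(x_m) + U_n(x_n))]`
#' reduces algebraically to
#' `delta = (lambda_m - lambda_n) * (W_n - W_m) / (kB T)`.
#' The swap is accepted with probability `min(1, exp(-delta))`, which
#' preserves the Boltzmann distribution of every rung.
#'
#' @param lambda_m,lambda_n Scaling coefficients of the two rungs.
#' @param W_m,W_n Solvent-dispersion energies (kcal/mol) of the
#'   configurations currently at those rungs.
#' @param temperature Kelvin.
#' @return Dimensionless exponent `delta`.
#' @export
swap_exponent <- function(lambda_m, lambda_n, W_m, W_n, temperature = 300) {
  stopifnot(temperature > 0)
  (lambda_m - lambda_n) * (W_n - W_m) / (KB_KCAL * temperature)
}

#' Exchange exponent via the full four-energy formula
#'
#' Verification path: evaluates the four total energies from scratch rather
#' than using cached `W` values and the linear shortcut.
#'
#' @param system A sampling system (see [peptide_system()]).
#' @param state_m,state_n Replica states.
#' @param lambda_m,lambda_n Rung coefficients.
#' @param temperature Kelvin.
#' @return Dimensionless exponent.
#' @export
swap_exponent_full <- function(system, state_m, state_n,
                               lambda_m, lambda_n, temperature = 300) {
  kT <- KB_KCAL * temperature
  Umm <- fresh_energy(system, state_m, lambda_m)
  Unn <- fresh_energy(system, state_n, lambda_n)
  Umn <- fresh_energy(system, state_n, lambda_m)
  Unm <- fresh_energy(system, state_m, lambda_n)
  ((Umn + Unm) - (Umm + Unn)) / kT
}

# ---------------------------------------------------------------------------
# Sampling systems. A system provides initial states, Metropolis sweeps at a
# given lambda, and fresh (non-cached) energy evaluations.

#' Coarse-grained peptide sampling system
#'
#' Bundles a modified sequence with energy parameters into the object the
#' SWISH sampler propagates. Moves are single-dihedral perturbations
#' (uniform, symmetric, maximum displacement `delta_max` degrees) applied in
#' a systematic pass over all phi/psi angles.
#'
#' @param seq A `mod_sequence`.
#' @param params An `energy_params` list.
#' @param start Initial conformation: `"extended"` (default, all
#'   (-135, 135)), `"helix"` (all (-57, -47)), or a matrix of dihedrals.
#' @return A `peptide_system`.
#' @export
peptide_system <- function(seq, params = default_energy_params(),
                           start = "extended") {
  stopifnot(inherits(seq, "mod_sequence"))
  structure(list(seq = seq, params = params, packed = pack_system(seq, params),
                 start = start),
            class = c("peptide_system", "swish_system"))
}

init_state <- function(system, ...) UseMethod("init_state")

#' @export
init_state.peptide_system <- function(system, ...) {
  L <- length(system$seq)
  d <- if (is.character(system$start)) {
    switch(system$start,
           extended = matrix(rep(c(-135, 135), each = L), ncol = 2),
           helix = matrix(rep(c(-57, -47), each = L), ncol = 2),
           rlang::abort("unknown start", class = "swishmc_error_config"))
  } else normalize_dihedrals(system$start, L) |> (\(x) cbind(x$phi, x$psi))()
  e <- cpp_energy_terms(d[, 1], d[, 2], system$packed)
  list(phi = d[, 1], psi = d[, 2], U0 = unname(e["U0"]), W = unname(e["W"]))
}

sweep_block <- function(system, state, lambda, kT, n_sweeps,
                        record_every, delta_max,
                        record_offset = 0) UseMethod("sweep_block")

#' @export
sweep_block.peptide_system <- function(system, state, lambda, kT, n_sweeps,
                                       record_every, delta_max,
                                       record_offset = 0) {
  r <- cpp_mc_block(state$phi, state$psi, system$packed, lambda, kT,
                    delta_max, n_sweeps, record_every, record_offset)
  list(state = list(phi = r$phi, psi = r$psi, U0 = r$U0, W = r$W),
       n_accepted = r$n_accepted, n_moves = r$n_moves,
       rec = list(phi = r$rec_phi, psi = r$rec_psi,
                  U0 = r$rec_U0, W = r$rec_W))
}

fresh_energy <- function(system, state, lambda) UseMethod("fresh_energy")

#' @export
fresh_energy.peptide_system <- function(system, state, lambda) {
  e <- cpp_energy_terms(state$phi, state$psi, system$packed)
  unname(e["U0"]) + lambda * unname(e["W"])
}

state_W <- function(system, state) state$W

# ---------------------------------------------------------------------------

#' Run SWISH Hamiltonian replica exchange
#'
#' Propagates one replica per ladder rung with Metropolis Monte Carlo and
#' periodically attempts swapping adjacent replicas (every `swap_interval`
#' sweeps, the sweep-space analogue of the study's 5 ps interval), with
#' acceptance probability `min(1, exp(-delta))` where `delta` is the
#' [swap_exponent()] preserving the correct replica statistics. Adjacent
#' pairs are attempted on a deterministic alternating even/odd schedule. On
#' acceptance the two replicas exchange rungs; configurations travel with
#' their replica. Frames are recorded per rung ("state-continuous"), and the
#' rung with lambda = 1 is the physical reporting ensemble. Each replica owns
#' an independent RNG stream keyed to its permanent identity, so swaps never
#' perturb random-number state and runs are exactly reproducible given
#' (seed, configuration).
#'
#' @param system A `peptide_system` or `toy_system`.
#' @param ladder A `lambda_ladder` (or numeric vector of rungs).
#' @param n_sweeps Number of Monte Carlo sweeps per replica.
#' @param swap_interval Sweeps between exchange phases.
#' @param temperature Kelvin.
#' @param seed Master seed (spawns per-replica streams).
#' @param record_every Record a frame every this many sweeps.
#' @param delta_max Maximum single-angle displacement, degrees.
#' @param exponent_method `"shortcut"` (cached-W linear formula, default) or
#'   `"full"` (four fresh energy evaluations; verification path).
#' @return A `swish_run` with per-rung `frames`, the `exchange_log`
#'   (tibble: `step`, `pair`, `delta`, `accepted`), the replica-rung trace,
#'   final states and the full configuration echo.
#' @export
run_swish <- function(system, ladder, n_sweeps, swap_interval = 10,
                      temperature = 300, seed = 1, record_every = 1,
                      delta_max = 25, exponent_method = c("shortcut", "full")) {
  stopifnot(inherits(system, "swish_system"), n_sweeps >= 1,
            swap_interval >= 1, temperature > 0)
  exponent_method <- match.arg(exponent_method)
  if (!inherits(ladder, "lambda_ladder")) {
    ladder <- structure(sort(as.numeric(ladder)), class = "lambda_ladder")
  }
  n_rep <- length(ladder)
  if (is.na(ladder_unscaled_index(ladder))) {
    rlang::warn("ladder does not contain lambda = 1: no reporting ensemble",
                class = "swishmc_warn_no_unscaled")
  }
  kT <- KB_KCAL * temperature

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)

  set.seed(as.integer(seed %% 2147483647L), kind = "L'Ecuyer-CMRG")
  streams <- vector("list", n_rep + 1)
  streams[[1]] <- get(".Random.seed", globalenv())
  for (i in seq_len(n_rep)) {
    streams[[i + 1]] <- parallel::nextRNGStream(streams[[i]])
  }
  exch_stream <- streams[[n_rep + 1]]

  states <- lapply(seq_len(n_rep), function(r) init_state(system))
  replica_at_state <- seq_len(n_rep)   # rung k -> replica id
  n_phases <- n_sweeps %/% swap_interval
  trace <- matrix(NA_integer_, n_phases + 1, n_rep)
  trace[1, ] <- replica_at_state

  frames <- lapply(seq_len(n_rep), function(k) list())
  log_rows <- list()
  acc_moves <- 0; tot_moves <- 0
  sweep_done <- 0; phase <- 0

  while (sweep_done < n_sweeps) {
    k_sweeps <- min(swap_interval, n_sweeps - sweep_done)
    for (rung in seq_len(n_rep)) {
      rep_id <- replica_at_state[rung]
      assign(".Random.seed", streams[[rep_id]], globalenv())
      out <- sweep_block(system, states[[rep_id]], ladder[rung], kT,
                         k_sweeps, record_every, delta_max,
                         record_offset = sweep_done)
      streams[[rep_id]] <- get(".Random.seed", globalenv())
      states[[rep_id]] <- out$state
      acc_moves <- acc_moves + out$n_accepted
      tot_moves <- tot_moves + out$n_moves
      n_rec <- length(out$rec$U0)
      if (n_rec > 0) {
        sweeps_at <- (sweep_done %/% record_every + seq_len(n_rec)) *
          record_every
        frames[[rung]][[length(frames[[rung]]) + 1]] <-
          c(out$rec, list(sweep = sweeps_at, replica = rep(rep_id, n_rec)))
      }
    }
    sweep_done <- sweep_done + k_sweeps
    if (k_sweeps == swap_interval && sweep_done %% swap_interval == 0) {
      phase <- phase + 1
      pairs <- phase_pairs(n_rep, phase)
      assign(".Random.seed", exch_stream, globalenv())
      for (pl in pairs) {
        rm_ <- replica_at_state[pl]; rn_ <- replica_at_state[pl + 1]
        if (exponent_method == "shortcut") {
          delta <- swap_exponent(ladder[pl], ladder[pl + 1],
                                 state_W(system, states[[rm_]]),
                                 state_W(system, states[[rn_]]), temperature)
        } else {
          delta <- swap_exponent_full(system, states[[rm_]], states[[rn_]],
                                      ladder[pl], ladder[pl + 1], temperature)
        }
        accepted <- delta <= 0 || stats::runif(1) < exp(-delta)
        if (accepted) {
          replica_at_state[pl] <- rn_; replica_at_state[pl + 1] <- rm_
        }
        log_rows[[length(log_rows) + 1]] <-
          list(step = sweep_done, pair_low = pl, pair_high = pl + 1L,
               delta = delta, accepted = accepted)
      }
      exch_stream <- get(".Random.seed", globalenv())
      stopifnot(!anyDuplicated(replica_at_state))  # bijection invariant
      trace[phase + 1, ] <- replica_at_state
    }
  }

  frames <- lapply(seq_len(n_rep), function(k) bind_frames(frames[[k]]))
  exchange_log <- if (length(log_rows) == 0) {
    tibble::tibble(step = integer(), pair_low = integer(),
                   pair_high = integer(), delta = numeric(),
                   accepted = logical())
  } else dplyr::bind_rows(lapply(log_rows, tibble::as_tibble))

  structure(list(
    system = system, ladder = ladder, frames = frames,
    exchange_log = exchange_log, trace = trace[seq_len(phase + 1), , drop = FALSE],
    final_states = states, replica_at_state = replica_at_state,
    acceptance = if (tot_moves > 0) acc_moves / tot_moves else NA_real_,
    config = list(n_sweeps = n_sweeps, swap_interval = swap_interval,
                  temperature = temperature, seed = seed,
                  record_every = record_every, delta_max = delta_max,
                  exponent_method = exponent_method,
                  ladder = as.numeric(ladder))),
    class = "swish_run")
}

bind_frames <- function(chunks) {
  if (length(chunks) == 0) return(NULL)
  if (!is.null(chunks[[1]]$phi)) {
    list(phi = do.call(rbind, lapply(chunks, `[[`, "phi")),
         psi = do.call(rbind, lapply(chunks, `[[`, "psi")),
         U0 = unlist(lapply(chunks, `[[`, "U0")),
         W = unlist(lapply(chunks, `[[`, "W")),
         sweep = unlist(lapply(chunks, `[[`, "sweep")),
         replica = unlist(lapply(chunks, `[[`, "replica")))
  } else {
    list(micro = unlist(lapply(chunks, `[[`, "micro")),
         U0 = unlist(lapply(chunks, `[[`, "U0")),
         W = unlist(lapply(chunks, `[[`, "W")),
         sweep = unlist(lapply(chunks, `[[`, "sweep")),
         replica = unlist(lapply(chunks, `[[`, "replica")))
  }
}

#' Plain Metropolis Monte Carlo at a single lambda
#'
#' Equivalent to a SWISH run with a single-rung ladder.
#'
#' @inheritParams run_swish
#' @param lambda Solvent-scaling coefficient.
#' @return A `swish_run` with one rung and an empty exchange log.
#' @export
run_mc <- function(system, lambda = 1, n_sweeps = 1000, temperature = 300,
                   seed = 1, record_every = 1, delta_max = 25) {
  suppressWarnings(run_swish(system, structure(lambda, class = "lambda_ladder"),
                             n_sweeps, swap_interval = n_sweeps + 1,
                             temperature = temperature, seed = seed,
                             record_every = record_every,
                             delta_max = delta_max))
}

#' @export
print.swish_run <- function(x, ...) {
  cat("<swish_run> ", length(x$ladder), " rung(s), ",
      x$config$n_sweeps, " sweeps, move acceptance ",
      sprintf("%.1f%%", 100 * x$acceptance), "\n", sep = "")
  if (nrow(x$exchange_log) > 0) {
    cat("  exchange attempts:", nrow(x$exchange_log), " accepted:",
        sum(x$exchange_log$accepted), "\n")
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Demultiplexing: per-state (rung-continuous) -> per-replica trajectories.

# adjacent pairs attempted at a given phase: odd phases start at rung 1,
# even phases at rung 2 (alternating even/odd deterministic schedule)
phase_pairs <- function(n_states, phase) {
  first <- if (phase %% 2 == 1) 1L else 2L
  if (n_states < 2 || first > n_states - 1) return(integer())
  seq(first, n_states - 1, by = 2)
}

replay_exchange_log <- function(exchange_log, n_states, n_sweeps,
                                swap_interval) {
  n_phases <- n_sweeps %/% swap_interval
  map <- seq_len(n_states)            # rung -> replica
  maps <- matrix(NA_integer_, n_phases + 1, n_states)
  maps[1, ] <- map
  log_i <- 1
  nlog <- nrow(exchange_log)
  for (phase in seq_len(n_phases)) {
    step <- phase * swap_interval
    expected <- phase_pairs(n_states, phase)
    for (pl in expected) {
      if (log_i > nlog || exchange_log$step[log_i] != step ||
          exchange_log$pair_low[log_i] != pl) {
        rlang::abort(paste0("exchange log inconsistent at step ", step,
                            ": expected attempt for pair (", pl, ",",
                            pl + 1, ")"),
                     class = "swishmc_error_demux")
      }
      if (exchange_log$pair_high[log_i] != pl + 1) {
        rlang::abort(paste0("exchange log at step ", step,
                            " attempts a non-adjacent pair"),
                     class = "swishmc_error_demux")
      }
      if (exchange_log$accepted[log_i]) {
        tmp <- map[pl]; map[pl] <- map[pl + 1]; map[pl + 1] <- tmp
      }
      log_i <- log_i + 1
    }
    maps[phase + 1, ] <- map
  }
  if (log_i <= nlog) {
    rlang::abort(paste0("exchange log has unexpected extra rows from step ",
                        exchange_log$step[log_i]),
                 class = "swishmc_error_demux")
  }
  maps
}

#' Demultiplex a SWISH run into replica-continuous trajectories
#'
#' Inverts the replica/rung assignment at every exchange interval by
#' replaying the exchange log from the initial identity mapping, and
#' regroups the per-rung frames into per-replica (walker-continuous)
#' trajectories. An inconsistent or gapped log raises an error naming the
#' first bad step.
#'
#' @param run A `swish_run` (or an exchange log tibble, together with
#'   `frames` and the run configuration).
#' @param frames,config Only needed when `run` is an exchange log.
#' @return List per replica mirroring the per-rung frame structure, with a
#'   `state` vector giving the rung occupied at each frame.
#' @export
demux <- function(run, frames = NULL, config = NULL) {
  if (inherits(run, "swish_run")) {
    exchange_log <- run$exchange_log; frames <- run$frames
    config <- run$config
  } else exchange_log <- run
  n_states <- length(frames)
  maps <- replay_exchange_log(exchange_log, n_states, config$n_sweeps,
                              config$swap_interval)
  si <- config$swap_interval
  out <- lapply(seq_len(n_states), function(r) list())
  for (s in seq_len(n_states)) {
    fr <- frames[[s]]
    if (is.null(fr)) next
    # frames recorded during block b (sweeps in ((b-1)*si, b*si]) belong to
    # the replica mapped to rung s *before* the phase at step b*si; sweeps
    # past the last phase use the final map.
    block_idx <- pmin(floor((fr$sweep - 1) / si) + 1, nrow(maps))
    rep_ids <- maps[cbind(block_idx, rep(s, length(fr$sweep)))]
    for (r in unique(rep_ids)) {
      sel <- rep_ids == r
      chunk <- extract_frames(fr, sel)
      chunk$state <- rep(s, sum(sel))
      out[[r]][[length(out[[r]]) + 1]] <- chunk
    }
  }
  lapply(out, function(chunks) {
    if (length(chunks) == 0) return(NULL)
    merged <- bind_frames(chunks)
    merged$state <- unlist(lapply(chunks, `[[`, "state"))
    ord <- order(merged$sweep)
    extract_frames(merged, ord)
  })
}

extract_frames <- function(fr, sel) {
  out <- list()
  for (nm in names(fr)) {
    out[[nm]] <- if (is.matrix(fr[[nm]])) fr[[nm]][sel, , drop = FALSE]
                 else fr[[nm]][sel]
  }
  out
}

#' Re-multiplex replica-continuous trajectories into per-rung frames
#'
#' Inverse of [demux()]; used to verify the round trip is exact.
#'
#' @param replica_frames Output of [demux()].
#' @param n_states Number of rungs.
#' @return Per-rung frame list in the [run_swish()] layout.
#' @export
remux <- function(replica_frames, n_states) {
  out <- lapply(seq_len(n_states), function(s) list())
  for (r in seq_along(replica_frames)) {
    fr <- replica_frames[[r]]
    if (is.null(fr)) next
    for (s in unique(fr$state)) {
      sel <- fr$state == s
      chunk <- extract_frames(fr, sel)
      chunk$replica <- rep(r, sum(sel))
      chunk$state <- NULL
      out[[s]][[length(out[[s]]) + 1]] <- chunk
    }
  }
  lapply(out, function(chunks) {
    if (length(chunks) == 0) return(NULL)
    merged <- bind_frames(chunks)
    ord <- order(merged$sweep)
    extract_frames(merged, ord)
  })
}
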