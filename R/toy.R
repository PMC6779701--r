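#' Exactly enumerable toy sampling system
#'
#' A discrete system used as a brute-force oracle for the replica-exchange
#' machinery: `n_res` residues, each restricted to a small shared alphabet
#' of (phi, psi) states, with the full microstate tables `U0(x)` and `W(x)`
#' given explicitly. With at most 256 microstates the exact Boltzmann
#' distribution of `U0 + lambda * W` at any rung is computable by direct
#' normalisation, so the state-stream statistics of a SWISH run can be
#' checked against the exact answer at every rung.
#'
#' Microstates are indexed 1..S^n with residue 1 as the least-significant
#' digit. Moves are single-residue state proposals, uniform over the
#' alphabet (symmetric, so plain Metropolis acceptance applies).
#'
#' @param n_res Number of residues (<= 4).
#' @param n_states Alphabet size per residue (<= 4).
#' @param U0,W Numeric vectors of length `n_states^n_res`, or functions
#'   taking the microstate digit matrix (rows = microstates) and returning a
#'   vector. If `NULL`, reproducible random tables are drawn from `seed`.
#' @param seed Seed for randomly generated tables.
#' @param U0_scale,W_scale Spread (kcal/mol) of randomly generated tables.
#' @return A `toy_system` (also a `swish_system`).
#' @examples
#' sys <- make_enumerable_system(2, 3, seed = 1)
#' p <- exact_distribution(sys, lambda = 1, temperature = 300)
#' sum(p)  # 1
#' @export
make_enumerable_system <- function(n_res, n_states, U0 = NULL, W = NULL,
                                   seed = 1, U0_scale = 1.5, W_scale = 1.5) {
  stopifnot(n_res >= 1, n_states >= 1)
  n_micro <- n_states^n_res
  if (n_micro > 256) {
    rlang::abort("too many microstates (limit 256)",
                 class = "swishmc_error_toy")
  }
  digits <- as.matrix(expand.grid(rep(list(seq_len(n_states)), n_res)))
  colnames(digits) <- paste0("res", seq_len(n_res))
  materialize <- function(x, default_scale) {
    if (is.null(x)) {
      stats::runif(n_micro, -default_scale, default_scale)
    } else if (is.function(x)) {
      v <- x(digits); stopifnot(length(v) == n_micro); as.numeric(v)
    } else {
      stopifnot(length(x) == n_micro); as.numeric(x)
    }
  }
  if (is.null(U0) || is.null(W)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  }
  U0v <- materialize(U0, U0_scale)
  Wv <- materialize(W, W_scale)
  structure(list(n_res = n_res, n_states = n_states, digits = digits,
                 U0 = U0v, W = Wv),
            class = c("toy_system", "swish_system"))
}

#' Exact Boltzmann distribution of a toy system
#' @param system A `toy_system`.
#' @param lambda Solvent-scaling coefficient.
#' @param temperature Kelvin.
#' @return Probability vector over microstates (sums to 1).
#' @export
exact_distribution <- function(system, lambda = 1, temperature = 300) {
  stopifnot(inherits(system, "toy_system"))
  u <- system$U0 + lambda * system$W
  w <- exp(-(u - min(u)) / (KB_KCAL * temperature))
  w / sum(w)
}

#' @export
init_state.toy_system <- function(system, ...) {
  list(micro = 1L, digits = rep(1L, system$n_res),
       U0 = system$U0[1], W = system$W[1])
}

#' @export
fresh_energy.toy_system <- function(system, state, lambda) {
  system$U0[state$micro] + lambda * system$W[state$micro]
}

#' @export
sweep_block.toy_system <- function(system, state, lambda, kT, n_sweeps,
                                   record_every, delta_max,
                                   record_offset = 0) {
  S <- system$n_states; n <- system$n_res
  radix <- S^(seq_len(n) - 1)
  U <- system$U0 + lambda * system$W
  micro <- state$micro
  digits <- state$digits
  n_acc <- 0L
  n_rec <- if (record_every > 0) {
    (record_offset + n_sweeps) %/% record_every -
      record_offset %/% record_every
  } else 0L
  rec_micro <- integer(n_rec); rec_U0 <- numeric(n_rec); rec_W <- numeric(n_rec)
  ri <- 0L
  for (sw in seq_len(n_sweeps)) {
    for (r in seq_len(n)) {
      prop_digit <- sample.int(S, 1)
      if (prop_digit == digits[r]) { n_acc <- n_acc + 1L; next }
      prop <- micro + (prop_digit - digits[r]) * radix[r]
      dU <- U[prop] - U[micro]
      if (dU <= 0 || stats::runif(1) < exp(-dU / kT)) {
        micro <- prop; digits[r] <- prop_digit; n_acc <- n_acc + 1L
      }
    }
    if (record_every > 0 && (record_offset + sw) %% record_every == 0 &&
        ri < n_rec) {
      ri <- ri + 1L
      rec_micro[ri] <- micro
      rec_U0[ri] <- system$U0[micro]; rec_W[ri] <- system$W[micro]
    }
  }
  list(state = list(micro = micro, digits = digits,
                    U0 = system$U0[micro], W = system$W[micro]),
       n_accepted = n_acc, n_moves = n * n_sweeps,
       rec = list(micro = rec_micro, U0 = rec_U0, W = rec_W))
}

#' @export
print.toy_system <- function(x, ...) {
  cat("<toy_system> ", x$n_res, " residue(s) x ", x$n_states,
      " states = ", length(x$U0), " microstates\n", sep = "")
  invisible(x)
}
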