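# Replica-exchange health metrics: acceptance per adjacent pair, rung
# occupancy per replica, round trips, and block-averaged error bars.

#' Summarise replica-exchange behaviour
#'
#' Counts exchange attempts and acceptances per adjacent rung pair, the
#' rung occupancy of each replica (from replaying the exchange log, sampled
#' once per exchange interval including the initial assignment), and the
#' number of round trips per replica (full traversals bottom rung -> top
#' rung -> bottom rung; no half credit). Healthy SWISH runs show exchange
#' between replicas and occupancies spreading over rungs, the sign that the
#' starting structure does not determine the sampled ensemble.
#'
#' @param x A `swish_run`, or an exchange log tibble (then `n_replicas`,
#'   `n_sweeps` and `swap_interval` are required).
#' @param n_replicas,n_sweeps,swap_interval Run shape when `x` is a log.
#' @param warn_acceptance Warn if the global mean acceptance falls below
#'   this fraction (default 0.1).
#' @return An `exchange_summary`: list with `pairs` (tibble: `pair_low`,
#'   `pair_high`, `attempts`, `acceptances`, `fraction`), `occupancy`
#'   (replica x rung count matrix), `round_trips` (per replica),
#'   `mean_acceptance`.
#' @export
summarize_exchanges <- function(x, n_replicas = NULL, n_sweeps = NULL,
                                swap_interval = NULL, warn_acceptance = 0.1) {
  if (inherits(x, "swish_run")) {
    log <- x$exchange_log
    n_replicas <- length(x$ladder)
    n_sweeps <- x$config$n_sweeps
    swap_interval <- x$config$swap_interval
  } else {
    log <- x
    stopifnot(!is.null(n_replicas), !is.null(n_sweeps), !is.null(swap_interval))
  }
  validate_log(log)
  pairs <- tibble::tibble(pair_low = seq_len(max(0, n_replicas - 1)))
  pairs$pair_high <- pairs$pair_low + 1L
  pairs$attempts <- vapply(pairs$pair_low,
                           function(p) sum(log$pair_low == p), 1L)
  pairs$acceptances <- vapply(pairs$pair_low,
                              function(p) sum(log$accepted[log$pair_low == p]),
                              1L)
  pairs$fraction <- ifelse(pairs$attempts > 0,
                           pairs$acceptances / pairs$attempts, NA_real_)
  maps <- replay_exchange_log(log, n_replicas, n_sweeps, swap_interval)
  occupancy <- matrix(0L, n_replicas, n_replicas,
                      dimnames = list(replica = seq_len(n_replicas),
                                      rung = seq_len(n_replicas)))
  for (i in seq_len(nrow(maps))) {
    for (s in seq_len(n_replicas)) {
      occupancy[maps[i, s], s] <- occupancy[maps[i, s], s] + 1L
    }
  }
  # per-replica rung path over time
  paths <- apply(maps, 1, function(m) order(m))  # replica -> rung, by interval
  paths <- matrix(paths, nrow = n_replicas)      # rows replicas
  round_trips <- apply(paths, 1, count_round_trips, n_replicas)
  mean_acc <- if (sum(pairs$attempts) > 0) {
    sum(pairs$acceptances) / sum(pairs$attempts)
  } else NA_real_
  if (!is.na(mean_acc) && mean_acc < warn_acceptance) {
    rlang::warn(sprintf("mean exchange acceptance %.3f below %.2f",
                        mean_acc, warn_acceptance),
                class = "swishmc_warn_low_acceptance")
  }
  structure(list(pairs = pairs, occupancy = occupancy,
                 round_trips = round_trips, mean_acceptance = mean_acc,
                 n_intervals = nrow(maps)),
            class = "exchange_summary")
}

validate_log <- function(log) {
  needed <- c("step", "pair_low", "pair_high", "delta", "accepted")
  if (!all(needed %in% names(log))) {
    rlang::abort("malformed exchange log: missing columns",
                 class = "swishmc_error_log")
  }
  for (i in seq_len(nrow(log))) {
    row <- log[i, ]
    if (any(is.na(row)) || row$pair_high != row$pair_low + 1) {
      rlang::abort(paste0("malformed exchange log row ", i),
                   class = "swishmc_error_log")
    }
  }
  invisible(log)
}

count_round_trips <- function(path, n_rungs) {
  if (n_rungs < 2) return(0L)
  trips <- 0L
  stage <- 0L  # 0 = not yet at bottom, 1 = seen bottom, 2 = seen top
  for (s in path) {
    if (stage == 0L) {
      if (s == 1L) stage <- 1L
    } else if (stage == 1L) {
      if (s == n_rungs) stage <- 2L
    } else {
      if (s == 1L) { trips <- trips + 1L; stage <- 1L }
    }
  }
  trips
}

#' @export
print.exchange_summary <- function(x, ...) {
  cat("<exchange_summary> mean acceptance ",
      ifelse(is.na(x$mean_acceptance), "NA",
             sprintf("%.3f", x$mean_acceptance)),
      ", round trips ", paste(x$round_trips, collapse = "/"), "\n", sep = "")
  print(x$pairs)
  invisible(x)
}

#' JSON diagnostics report
#' @param summary An `exchange_summary`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_diagnostics_json <- function(summary, path) {
  stopifnot(inherits(summary, "exchange_summary"))
  jsonlite::write_json(
    list(pairs = summary$pairs,
         occupancy = as.data.frame(unclass(summary$occupancy)),
         round_trips = summary$round_trips,
         mean_acceptance = summary$mean_acceptance,
         n_intervals = summary$n_intervals),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Block-averaged mean and standard error
#'
#' Splits the series into `n_blocks` contiguous blocks of equal length
#' (`floor(n / n_blocks)`; trailing remainder dropped) and returns the mean
#' of block means with standard error `sd(block means) / sqrt(n_blocks)`.
#'
#' @param series Numeric vector.
#' @param n_blocks Number of blocks (>= 2).
#' @return List with `mean`, `se`, `n_blocks`, `block_length`.
#' @export
block_average <- function(series, n_blocks = 10) {
  n <- length(series)
  if (n_blocks < 2 || n < n_blocks) {
    rlang::abort("series too short for the requested number of blocks",
                 class = "swishmc_error_blocks")
  }
  bl <- n %/% n_blocks
  means <- vapply(seq_len(n_blocks),
                  function(b) mean(series[((b - 1) * bl + 1):(b * bl)]), 1.0)
  list(mean = mean(means), se = stats::sd(means) / sqrt(n_blocks),
       n_blocks = n_blocks, block_length = bl)
}
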