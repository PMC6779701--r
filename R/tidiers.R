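# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.swish_run <- function(x, ...) x$exchange_log

#' @export
glance.swish_run <- function(x, ...) {
  tibble::tibble(
    n_replicas = length(x$ladder),
    n_sweeps = x$config$n_sweeps,
    swap_interval = x$config$swap_interval,
    temperature = x$config$temperature,
    seed = x$config$seed,
    move_acceptance = x$acceptance,
    exchange_attempts = nrow(x$exchange_log),
    exchange_acceptance = if (nrow(x$exchange_log) > 0)
      mean(x$exchange_log$accepted) else NA_real_)
}

#' @export
tidy.helicity_profile <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.helicity_profile <- function(x, ...) {
  tibble::tibble(overall_helicity = attr(x, "overall"),
                 pct_helicity = 100 * attr(x, "overall"),
                 n_frames = attr(x, "n_frames"),
                 n_residues = nrow(x))
}

#' @export
tidy.exchange_summary <- function(x, ...) x$pairs

#' @export
glance.exchange_summary <- function(x, ...) {
  tibble::tibble(mean_acceptance = x$mean_acceptance,
                 total_round_trips = sum(x$round_trips),
                 n_intervals = x$n_intervals)
}

#' Stacked-bar helicity profile plot
#'
#' Per-residue helix percentage split into alpha and 3-10 contributions.
#'
#' @param object A `helicity_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.helicity_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("f_alpha", "f_three_ten"),
                            names_to = "class", values_to = "fraction")
  df$class <- factor(df$class, c("f_three_ten", "f_alpha"),
                     c("3-10 helix", "alpha helix"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue,
                                   y = 100 * .data$fraction,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_x_continuous(
      breaks = object$residue,
      labels = if (all(is.na(object$code))) object$residue
               else paste0(object$code, object$residue)) +
    ggplot2::labs(x = NULL, y = "helicity / %", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Heat map of backbone hydrogen-bond frequencies
#'
#' Carbonyl residue on the x axis, donor offset (+1..+4) rows, cell colour
#' the fraction of frames with the CO(i) -> NH(i+k) bond.
#'
#' @param object An `hbond_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hbond_matrix <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue,
                                   y = factor(.data$offset),
                                   fill = .data$frequency)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "white") +
    ggplot2::labs(x = "carbonyl residue", y = "amide offset (+k)",
                  fill = "frequency") +
    ggplot2::theme_minimal()
}

#' Ramachandran density plot for one residue
#'
#' @param traj A `trajectory`.
#' @param residue Residue index.
#' @param bin_width Histogram bin width, degrees.
#' @return A ggplot object.
#' @export
plot_ramachandran <- function(traj, residue, bin_width = 10) {
  counts <- dihedral_histogram(traj, residue, bin_width)
  df <- tibble::as_tibble(as.data.frame.table(counts, stringsAsFactors = FALSE))
  names(df) <- c("phi", "psi", "count")
  df$phi <- as.numeric(df$phi); df$psi <- as.numeric(df$psi)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi, y = .data$psi,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "phi / deg", y = "psi / deg", fill = "frames") +
    ggplot2::theme_minimal()
}
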