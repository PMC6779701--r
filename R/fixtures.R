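# Deterministic structure and label generators used in tests and examples.

IDEAL_DIHEDRALS <- list(alpha = c(-57, -47),
                        three_ten = c(-49, -26),
                        extended = c(-135, 135))

#' Build an idealised conformation
#'
#' Generators for canonical test structures: `alpha` (all (-57, -47)),
#' `three_ten` (all (-49, -26)), `extended` (all (-135, 135)), or `mixed`,
#' which applies per-segment dihedrals on an extended background — e.g. the
#' two-helix topology (helical fragments around residues 2-7 and 11-16)
#' characteristic of the huntingtin N-terminal peptide.
#'
#' @param seq A `mod_sequence`.
#' @param kind `"alpha"`, `"three_ten"`, `"extended"` or `"mixed"`.
#' @param segments For `kind = "mixed"`: list of `list(start, end, kind)`
#'   entries (non-overlapping; `kind` one of alpha/three_ten/extended).
#' @return A `conformation`.
#' @examples
#' wt <- parse_modified_sequence("MATLEKLMKAFESLKSFQQ")
#' helix <- make_ideal_structure(wt, "alpha")
#' two <- make_ideal_structure(wt, "mixed",
#'   segments = list(list(start = 2, end = 7, kind = "alpha"),
#'                   list(start = 11, end = 16, kind = "alpha")))
#' @export
make_ideal_structure <- function(seq, kind = c("alpha", "three_ten",
                                               "extended", "mixed"),
                                 segments = NULL) {
  kind <- match.arg(kind)
  L <- length(seq)
  if (kind != "mixed") {
    return(build_conformation(seq, IDEAL_DIHEDRALS[[kind]]))
  }
  if (is.null(segments) || length(segments) == 0) {
    rlang::abort("mixed structures need a segment list",
                 class = "swishmc_error_segments")
  }
  covered <- rep(FALSE, L)
  d <- matrix(rep(IDEAL_DIHEDRALS$extended, each = L), ncol = 2)
  for (s in segments) {
    stopifnot(!is.null(s$start), !is.null(s$end))
    idx <- s$start:s$end
    if (any(idx < 1 | idx > L)) {
      rlang::abort("segment outside the sequence",
                   class = "swishmc_error_segments")
    }
    if (any(covered[idx])) {
      rlang::abort("overlapping segments", class = "swishmc_error_segments")
    }
    covered[idx] <- TRUE
    sk <- if (is.null(s$kind)) "alpha" else s$kind
    d[idx, ] <- matrix(rep(IDEAL_DIHEDRALS[[sk]], each = length(idx)),
                       ncol = 2)
  }
  build_conformation(seq, d)
}

#' Build a synthetic label trajectory
#'
#' Bypasses geometry: turns per-frame secondary-structure label strings
#' into the label matrix consumed by [helicity()], for arithmetic tests of
#' the averaging.
#'
#' @param labels Character vector, one string of per-residue labels
#'   (H/G/T/C) per frame; all strings must have equal length.
#' @return Character matrix, frames x residues.
#' @export
make_label_trajectory <- function(labels) {
  stopifnot(length(labels) >= 1)
  lens <- nchar(labels)
  if (length(unique(lens)) != 1) {
    rlang::abort("all label strings must have the same length",
                 class = "swishmc_error_input")
  }
  do.call(rbind, strsplit(labels, ""))
}
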