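#' Parse a peptide sequence with post-translational modifications
#'
#' Builds a `mod_sequence` object from a one-letter amino-acid string and a
#' list of modification labels. Three modification kinds are supported:
#' phosphorylation of Ser/Thr (`"pThr3"`), side-chain acetylation of Lys
#' (`"acLys6"`), and N-terminal acetylation (`"acNterm"`, or the synonym
#' spelled with the first residue, e.g. `"acMet1"`). Phosphorylation sets the
#' side-chain formal charge to `phosphate_charge` (default -2, the dianionic
#' state at physiological pH; set -1 for the monoanion); side-chain
#' acetylation neutralises the Lys amine; N-terminal acetylation neutralises
#' the terminal amine.
#'
#' @param seq_text One-letter amino-acid string (the 20 standard codes).
#' @param mod_labels Character vector of modification labels, possibly empty.
#' @param phosphate_charge Formal charge assigned to a phosphorylated side
#'   chain; one of -2 (default) or -1.
#' @param nterm_charge,cterm_charge Formal charges of the free termini.
#'   Defaults +1 and -1; set to 0 for capped/amidated termini.
#' @param name Optional display name; defaults to the modification labels.
#' @return A `mod_sequence`: list with `residues` (tibble: `index`, `code`,
#'   `code3`, `ptm`, `sc_charge`, `in_h`, `in_p`, `sc_mass`, `sc_dist`),
#'   `ptms` (tibble: `kind`, `target`, `label`), terminal charges and the
#'   charge configuration.
#' @examples
#' wt <- parse_modified_sequence("MATLEKLMKAFESLKSFQQ")
#' pt3 <- parse_modified_sequence("MATLEKLMKAFESLKSFQQ", "pThr3")
#' total_formal_charge(wt)   # +1
#' total_formal_charge(pt3)  # -1
#' @export
parse_modified_sequence <- function(seq_text, mod_labels = character(),
                                    phosphate_charge = -2,
                                    nterm_charge = 1, cterm_charge = -1,
                                    name = NULL) {
  stopifnot(is.character(seq_text), length(seq_text) == 1)
  codes <- strsplit(toupper(gsub("\\s", "", seq_text)), "")[[1]]
  bad <- setdiff(unique(codes), AA_CODES)
  if (length(bad) > 0) {
    rlang::abort(
      paste0("unknown residue code(s): ", paste(bad, collapse = ", ")),
      class = "swishmc_error_residue_code")
  }
  if (!phosphate_charge %in% c(-2, -1)) {
    rlang::abort("phosphate_charge must be -2 or -1",
                 class = "swishmc_error_config")
  }
  L <- length(codes)
  residues <- tibble::tibble(
    index = seq_len(L),
    code = codes,
    code3 = unname(AA_THREE[codes]),
    ptm = NA_character_,
    sc_charge = unname(ifelse(codes %in% names(AA_SC_CHARGE),
                              AA_SC_CHARGE[codes], 0)),
    sc_mass = unname(AA_SC_MASS[codes]),
    sc_dist = unname(AA_SC_DIST[codes])
  )
  seq <- structure(
    list(name = name, residues = residues,
         ptms = tibble::tibble(kind = character(), target = integer(),
                               label = character()),
         nterm_charge = nterm_charge, cterm_charge = cterm_charge,
         config = list(phosphate_charge = phosphate_charge,
                       nterm_charge = nterm_charge,
                       cterm_charge = cterm_charge)),
    class = "mod_sequence")
  for (lab in mod_labels) seq <- apply_ptm(seq, lab)
  seq$residues <- refresh_classes(seq$residues)
  if (is.null(name)) {
    seq$name <- if (nrow(seq$ptms) == 0) "WT" else
      paste(seq$ptms$label, collapse = "/")
  }
  seq
}

#' Parse a modification label
#'
#' Canonical grammar: `("p"|"ac")` + three-letter residue name + 1-based
#' index, e.g. `"pThr3"`, `"acLys6"`; `"acNterm"` (or `"ac<Res>1"` for a
#' non-Lys first residue) denotes N-terminal acetylation.
#'
#' @param label Modification label string.
#' @param codes Optional character vector of one-letter residue codes used to
#'   validate the target residue type.
#' @return List with `kind` (one of `"phospho"`, `"acetyl_sidechain"`,
#'   `"acetyl_nterm"`), `target` (1-based index, `NA` for the N-terminus) and
#'   the canonical `label`.
#' @export
parse_ptm_label <- function(label, codes = NULL) {
  stopifnot(is.character(label), length(label) == 1)
  if (label %in% c("acNterm", "acNTerm")) {
    return(list(kind = "acetyl_nterm", target = NA_integer_, label = "acNterm"))
  }
  m <- regmatches(label, regexec("^(p|ac)([A-Z][a-z]{2})([0-9]+)$", label))[[1]]
  if (length(m) == 0) {
    rlang::abort(paste0("cannot parse modification label '", label, "'"),
                 class = "swishmc_error_ptm_label")
  }
  prefix <- m[2]; res3 <- m[3]; idx <- as.integer(m[4])
  if (!res3 %in% names(AA_ONE)) {
    rlang::abort(paste0("unknown residue name '", res3, "' in '", label, "'"),
                 class = "swishmc_error_ptm_label")
  }
  code <- AA_ONE[[res3]]
  if (!is.null(codes)) {
    if (idx < 1 || idx > length(codes)) {
      rlang::abort(paste0("modification '", label, "' targets residue ", idx,
                          " outside 1..", length(codes)),
                   class = "swishmc_error_ptm_range")
    }
    if (codes[idx] != code) {
      rlang::abort(paste0("modification '", label, "' names ", res3,
                          " but residue ", idx, " is ",
                          AA_THREE[[codes[idx]]]),
                   class = "swishmc_error_ptm_target")
    }
  }
  if (prefix == "p") {
    if (!code %in% c("S", "T")) {
      rlang::abort(paste0("phosphorylation targets Ser or Thr, not ",
                          res3, " ('", label, "')"),
                   class = "swishmc_error_ptm_target")
    }
    return(list(kind = "phospho", target = idx, label = label))
  }
  # "ac" prefix: Lys -> side-chain acetylation; first residue -> N-terminal.
  if (code == "K") {
    return(list(kind = "acetyl_sidechain", target = idx, label = label))
  }
  if (idx == 1L) {
    return(list(kind = "acetyl_nterm", target = NA_integer_, label = label))
  }
  rlang::abort(paste0("acetylation targets Lys side chains or the N-terminus",
                      " ('", label, "')"),
               class = "swishmc_error_ptm_target")
}

#' Apply a modification to a sequence
#' @param seq A `mod_sequence`.
#' @param label Modification label (see [parse_ptm_label()]).
#' @return Modified `mod_sequence`.
#' @export
apply_ptm <- function(seq, label) {
  stopifnot(inherits(seq, "mod_sequence"))
  p <- parse_ptm_label(label, seq$residues$code)
  if (p$kind == "acetyl_nterm") {
    if ("acetyl_nterm" %in% seq$ptms$kind) {
      rlang::abort("N-terminus is already acetylated",
                   class = "swishmc_error_ptm_duplicate")
    }
    seq$nterm_charge <- 0
  } else {
    already <- seq$ptms$kind == p$kind &
      !is.na(seq$ptms$target) & seq$ptms$target == p$target
    if (any(already)) {
      rlang::abort(paste0("duplicate modification '", label, "'"),
                   class = "swishmc_error_ptm_duplicate")
    }
    i <- p$target
    if (p$kind == "phospho") {
      seq$residues$ptm[i] <- "phospho"
      seq$residues$sc_charge[i] <- seq$config$phosphate_charge
      seq$residues$sc_mass[i] <- seq$residues$sc_mass[i] + PHOSPHATE_MASS
      seq$residues$sc_dist[i] <- seq$residues$sc_dist[i] + PHOSPHO_SC_EXTRA_DIST
    } else {
      seq$residues$ptm[i] <- "acetyl"
      seq$residues$sc_charge[i] <- 0
      seq$residues$sc_mass[i] <- seq$residues$sc_mass[i] + ACETYL_MASS
      seq$residues$sc_dist[i] <- seq$residues$sc_dist[i] + ACETYL_SC_EXTRA_DIST
    }
  }
  seq$ptms <- dplyr::arrange(
    dplyr::bind_rows(seq$ptms,
                     tibble::tibble(kind = p$kind, target = p$target,
                                    label = p$label)),
    !is.na(.data$target), .data$target)
  seq$residues <- refresh_classes(seq$residues)
  seq
}

#' Remove a modification from a sequence
#' @inheritParams apply_ptm
#' @return `mod_sequence` with the modification reverted.
#' @export
remove_ptm <- function(seq, label) {
  stopifnot(inherits(seq, "mod_sequence"))
  p <- parse_ptm_label(label, seq$residues$code)
  hit <- which(seq$ptms$kind == p$kind &
                 (is.na(p$target) | (!is.na(seq$ptms$target) &
                                       seq$ptms$target == p$target)))
  if (length(hit) == 0) {
    rlang::abort(paste0("modification '", label, "' is not present"),
                 class = "swishmc_error_ptm_absent")
  }
  if (p$kind == "acetyl_nterm") {
    seq$nterm_charge <- seq$config$nterm_charge
  } else {
    i <- p$target
    code <- seq$residues$code[i]
    seq$residues$ptm[i] <- NA_character_
    seq$residues$sc_charge[i] <- if (code %in% names(AA_SC_CHARGE))
      AA_SC_CHARGE[[code]] else 0
    seq$residues$sc_mass[i] <- AA_SC_MASS[[code]]
    seq$residues$sc_dist[i] <- AA_SC_DIST[[code]]
  }
  seq$ptms <- seq$ptms[-hit[1], ]
  seq$residues <- refresh_classes(seq$residues)
  seq
}

refresh_classes <- function(residues) {
  residues$in_h <- residues$code %in% AA_H_CLASS
  residues$in_p <- residues$code %in% AA_P_CLASS
  # Phosphorylated S/T stay polar; acetylated Lys keeps its alkyl
  # h-membership (the Aurora-Rose h refers to the alkyl chain). No class
  # therefore changes with the supported modifications.
  residues
}

#' Hydrophobic/polar class of residues
#'
#' Returns the Aurora-Rose capping-alphabet membership of each residue:
#' `h` = hydrophobic residues plus the alkyl side chains of Lys/Arg,
#' `p` = polar residues plus Lys/Arg. Membership is a pure function of
#' (residue code, modification state) and does not depend on position.
#'
#' @param seq A `mod_sequence`.
#' @return Tibble with `index`, `code`, `in_h`, `in_p`.
#' @export
residue_class <- function(seq) {
  stopifnot(inherits(seq, "mod_sequence"))
  dplyr::select(seq$residues, "index", "code", "in_h", "in_p")
}

#' Per-group formal charges of a sequence
#'
#' @param seq A `mod_sequence`.
#' @return Tibble of charged groups: `group` (`"nterm"`, `"sidechain"`,
#'   `"cterm"`), `residue`, `charge`; uncharged side chains included with 0.
#' @export
charge_table <- function(seq) {
  stopifnot(inherits(seq, "mod_sequence"))
  L <- nrow(seq$residues)
  dplyr::bind_rows(
    tibble::tibble(group = "nterm", residue = 1L, charge = seq$nterm_charge),
    tibble::tibble(group = "sidechain", residue = seq$residues$index,
                   charge = seq$residues$sc_charge),
    tibble::tibble(group = "cterm", residue = L, charge = seq$cterm_charge))
}

#' Total formal charge of a modified sequence
#' @param seq A `mod_sequence`.
#' @return Integer total charge (termini included).
#' @export
total_formal_charge <- function(seq) {
  sum(charge_table(seq)$charge)
}

#' @export
print.mod_sequence <- function(x, ...) {
  cat("<mod_sequence> ", x$name, "\n", sep = "")
  cat(" ", paste(x$residues$code, collapse = ""), "  (", nrow(x$residues),
      " residues, total charge ", sprintf("%+d", total_formal_charge(x)),
      ")\n", sep = "")
  if (nrow(x$ptms) > 0) {
    cat("  modifications:", paste(x$ptms$label, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.mod_sequence <- function(x) nrow(x$residues)

#' Modification labels of a sequence
#' @param seq A `mod_sequence`.
#' @return Character vector of canonical labels.
#' @export
ptm_labels <- function(seq) seq$ptms$label

#' Sequence string of a `mod_sequence`
#' @param x A `mod_sequence`.
#' @param ... Unused.
#' @return One-letter string.
#' @export
as.character.mod_sequence <- function(x, ...) {
  paste(x$residues$code, collapse = "")
}

#' Read a modified sequence from FASTA plus a modification list
#'
#' The FASTA file must contain a single record; the sidecar modification file
#' holds one canonical label per line (blank lines and `#` comments ignored).
#'
#' @param fasta_path Path to a FASTA file.
#' @param mods_path Optional path to the modification list.
#' @param ... Passed to [parse_modified_sequence()].
#' @return A `mod_sequence`.
#' @export
read_modified_sequence <- function(fasta_path, mods_path = NULL, ...) {
  fa <- seqinr::read.fasta(fasta_path, seqtype = "AA", as.string = TRUE)
  if (length(fa) != 1) {
    rlang::abort("FASTA file must contain exactly one sequence",
                 class = "swishmc_error_io")
  }
  mods <- character()
  if (!is.null(mods_path)) {
    lines <- trimws(readLines(mods_path))
    mods <- lines[nzchar(lines) & !startsWith(lines, "#")]
  }
  parse_modified_sequence(as.character(fa[[1]]), mods,
                          name = attr(fa[[1]], "name"), ...)
}

#' Write a modified sequence as FASTA plus a modification list
#' @param seq A `mod_sequence`.
#' @param fasta_path,mods_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_modified_sequence <- function(seq, fasta_path, mods_path) {
  stopifnot(inherits(seq, "mod_sequence"))
  writeLines(c(paste0(">", seq$name), as.character(seq)), fasta_path)
  writeLines(ptm_labels(seq), mods_path)
  invisible(c(fasta_path, mods_path))
}
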