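# Multi-model PDB trajectory input/output. PDB is the one trajectory format
# of the toolkit (universally writable by MD packages); coordinate precision
# is limited to 1e-3 Angstrom by the format.

#' Write a trajectory (or conformation) as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame; the side-chain bead is written with
#' atom name CB.
#'
#' @param x A `trajectory` or `conformation`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_multimodel_pdb <- function(x, path) {
  if (inherits(x, "conformation")) x <- as_trajectory(x)
  stopifnot(inherits(x, "trajectory"))
  at <- x$atoms
  name_out <- ifelse(at$atom == "SC", "CB", at$atom)
  res3 <- if (!is.null(x$seq)) {
    toupper(x$seq$residues$code3)[at$residue]
  } else rep("UNK", nrow(at))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(x))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- x$coords[, , f]
    lines <- sprintf(
      "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)), name_out, res3, at$residue,
      xyz[, 1], xyz[, 2], xyz[, 3], at$element)
    writeLines(lines, con)
    writeLines(c("TER", "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Frames are taken in MODEL order (a file without MODEL records is a
#' single-frame trajectory); 1-based residue numbering is preserved. Every
#' model must contain backbone N, CA, C, O for every residue (amide
#' hydrogens are optional and can be reconstructed downstream with
#' [place_amide_hydrogens()]); a CB atom is read as the side-chain bead.
#'
#' @param path PDB file.
#' @param seq Optional `mod_sequence`; when absent a bare sequence is
#'   derived from the residue names.
#' @return A `trajectory`.
#' @export
read_multimodel_pdb <- function(path, seq = NULL) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) {
      rlang::abort(paste0("cannot parse PDB file '", path, "': ",
                          conditionMessage(e)),
                   class = "swishmc_error_io", parent = e)
    })
  atom <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atom) == 0) {
    rlang::abort(paste0("PDB file '", path, "' contains no ATOM records"),
                 class = "swishmc_error_io")
  }
  n_models <- nrow(pdb$xyz)
  res_ids <- sort(unique(atom$resno))
  if (!identical(res_ids, seq(min(res_ids), max(res_ids)))) {
    rlang::abort("residue numbering is not contiguous",
                 class = "swishmc_error_io")
  }
  atom$residue <- atom$resno - min(res_ids) + 1L
  L <- max(atom$residue)
  # model 1 defines the atom inventory; bio3d guarantees equal xyz lengths
  # across models, so later models cannot silently drop atoms.
  for (r in seq_len(L)) {
    have <- atom$elety[atom$residue == r]
    missing <- setdiff(c("N", "CA", "C", "O"), have)
    if (length(missing) > 0) {
      rlang::abort(paste0("model 1, residue ", r, " is missing backbone atom(s) ",
                          paste(missing, collapse = ", ")),
                   class = "swishmc_error_io")
    }
  }
  codes3 <- vapply(seq_len(L), function(r) atom$resid[atom$residue == r][1], "")
  codes1 <- AA_ONE[paste0(substr(codes3, 1, 1),
                          tolower(substr(codes3, 2, 3)))]
  if (is.null(seq) && !any(is.na(codes1))) {
    seq <- parse_modified_sequence(paste(codes1, collapse = ""))
  }
  keep <- atom$elety %in% c("N", "H", "CA", "C", "O", "CB")
  atom <- atom[keep, , drop = FALSE]
  atom_name <- ifelse(atom$elety == "CB", "SC", atom$elety)
  elem <- ifelse(atom$elesy %in% c("N", "C", "O", "H"), atom$elesy,
                 substr(atom$elety, 1, 1))
  atoms <- tibble::tibble(residue = atom$residue, atom = atom_name,
                          element = elem)
  atoms$mass <- ifelse(atoms$atom == "SC",
                       if (!is.null(seq)) seq$residues$sc_mass[atoms$residue]
                       else 12.01,
                       ATOM_MASS[ifelse(atoms$atom %in% names(ATOM_MASS),
                                        atoms$atom, "C")])
  sel <- which(keep)
  coords <- array(NA_real_, c(nrow(atoms), 3, n_models))
  for (m in seq_len(n_models)) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    coords[, , m] <- xyz[sel, , drop = FALSE]
    if (any(!is.finite(coords[, , m]))) {
      bad <- atoms$residue[which(!is.finite(coords[, 1, m]))[1]]
      rlang::abort(paste0("model ", m, ", residue ", bad,
                          " has missing coordinates"),
                   class = "swishmc_error_io")
    }
  }
  new_trajectory(coords, atoms, seq = seq)
}

#' Write a run manifest with configuration, seed and output checksums
#'
#' The manifest (JSON) plus the package version is sufficient to reproduce
#' every output byte-exactly.
#'
#' @param run A `swish_run`.
#' @param dir Directory containing the run outputs.
#' @param files Character vector of output files to checksum (relative to
#'   `dir`).
#' @return Invisibly, the manifest path.
#' @export
write_run_manifest <- function(run, dir, files = character()) {
  stopifnot(inherits(run, "swish_run"))
  manifest <- list(
    package = "swishmc",
    version = as.character(utils::packageVersion("swishmc")),
    config = run$config,
    ladder = as.numeric(run$ladder),
    seed = run$config$seed,
    n_exchange_attempts = nrow(run$exchange_log),
    outputs = lapply(files, function(f) {
      list(file = f,
           md5 = unname(tools::md5sum(file.path(dir, f))))
    }))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the exchange log as a tab-separated table
#' @param run A `swish_run`.
#' @param path Output file.
#' @export
write_exchange_log <- function(run, path) {
  utils::write.table(run$exchange_log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an exchange log written by [write_exchange_log()]
#' @param path Tab-separated log file.
#' @return Tibble with `step`, `pair_low`, `pair_high`, `delta`, `accepted`.
#' @export
read_exchange_log <- function(path) {
  tab <- utils::read.delim(path)
  needed <- c("step", "pair_low", "pair_high", "delta", "accepted")
  if (!all(needed %in% names(tab))) {
    rlang::abort("malformed exchange log: missing columns",
                 class = "swishmc_error_io")
  }
  tibble::as_tibble(tab)
}
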