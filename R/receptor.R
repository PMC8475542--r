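#' Read a receptor structure from a PDB file
#'
#' Parses a PDB file (via \pkg{bio3d}) into a `condock_receptor`: protein
#' (polymer) residues only, heavy atoms only by default. HETATM records,
#' waters and bound ligands are dropped, matching the usual docking
#' preparation in which extraneous chains, solvent and ligands are removed
#' before pose generation. Alternate locations are resolved to the
#' highest-occupancy conformer (ties: first in file order).
#'
#' @param path Path to a PDB file.
#' @param model For multi-model files, which MODEL to read (default: first).
#' @param keep_hydrogens Keep hydrogen atoms? Default `FALSE`; contact
#'   detection is defined on heavy atoms so that structures with and
#'   without hydrogens give identical binding sites.
#' @return A `condock_receptor`: list with `atoms` (data frame with columns
#'   `key`, `chain`, `resno`, `icode`, `resname`, `name`, `element`,
#'   `x`, `y`, `z`), `source_path`, and `model_index`.
#' @examples
#' pdb <- system.file("extdata", "scenario1", "receptor.pdb", package = "condock")
#' rec <- read_receptor(pdb)
#' rec
#' @export
read_receptor <- function(path, model = NULL, keep_hydrogens = FALSE) {
  if (!file.exists(path)) stop("receptor file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  n_models <- nrow(pdb$xyz)
  model <- as.integer(model %||% 1L)
  if (model < 1L || model > n_models)
    stop("model ", model, " requested but file has ", n_models, " model(s)")

  at <- pdb$atom
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]

  # polymer protein residues only
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]

  element <- at$elesy
  blank <- is.na(element) | element == ""
  element[blank] <- element_from_name(at$elety[blank])
  element <- normalize_element(element)
  at$element <- element
  if (!keep_hydrogens) at <- at[!is_hydrogen(at$element), , drop = FALSE]

  if (nrow(at) == 0L)
    stop("no protein residues remain after filtering '", path, "'")

  # altloc: keep the highest-occupancy conformer per (residue, atom name)
  at$icode <- ifelse(is.na(at$insert), "", at$insert)
  at$chain <- ifelse(is.na(at$chain), "", at$chain)
  gk <- paste(at$chain, at$resno, at$icode, at$elety, sep = "\r")
  occ <- ifelse(is.na(at$o), 1, at$o)
  idx <- seq_len(nrow(at))
  keep <- vapply(split(idx, gk), function(ix) ix[order(-occ[ix], ix)][1L], 1L)
  at <- at[sort(keep), , drop = FALSE]

  atoms <- data.frame(
    key = residue_key(at$chain, at$resno, at$icode),
    chain = at$chain, resno = at$resno, icode = at$icode,
    resname = at$resid, name = at$elety, element = at$element,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x + atoms$y + atoms$z)))
    stop("non-finite coordinates in '", path, "'")

  structure(list(atoms = atoms, source_path = path, model_index = model),
            class = "condock_receptor")
}

#' Residue table of a receptor
#'
#' @param receptor A `condock_receptor`.
#' @return Data frame with one row per residue (`key`, `chain`, `resno`,
#'   `icode`, `resname`, `natoms`), in structure order.
#' @export
receptor_residues <- function(receptor) {
  stopifnot(inherits(receptor, "condock_receptor"))
  at <- receptor$atoms
  first <- !duplicated(at$key)
  data.frame(
    key = at$key[first], chain = at$chain[first], resno = at$resno[first],
    icode = at$icode[first], resname = at$resname[first],
    natoms = as.vector(table(factor(at$key, levels = at$key[first]))),
    stringsAsFactors = FALSE
  )
}

# one-letter sequence of the receptor, 'X' for non-standard residues
receptor_sequence <- function(receptor) {
  res <- receptor_residues(receptor)
  aa <- suppressWarnings(bio3d::aa321(res$resname))
  aa[is.na(aa) | !(aa %in% c(AA20, "X"))] <- "X"
  aa
}

receptor_coords <- function(receptor) {
  as.matrix(receptor$atoms[, c("x", "y", "z")])
}

#' @export
print.condock_receptor <- function(x, ...) {
  res <- receptor_residues(x)
  cat("condock receptor: ", nrow(res), " residues, ", nrow(x$atoms),
      " heavy atoms (model ", x$model_index, ")\n", sep = "")
  cat("  chains: ", paste(unique(res$chain), collapse = ", "), "\n", sep = "")
  if (!is.na(x$source_path)) cat("  source: ", x$source_path, "\n", sep = "")
  invisible(x)
}

#' Write a receptor back out as a PDB file
#'
#' Emits standard fixed-column ATOM records for the receptor's heavy atoms.
#' Re-reading the written file with [read_receptor()] reproduces the
#' structure (coordinates at the format's 3-decimal precision).
#'
#' @param receptor A `condock_receptor`.
#' @param path Output path.
#' @param b Optional per-atom B-factor vector (recycled); used by the
#'   conservation B-factor export.
#' @return `path`, invisibly.
#' @export
write_receptor_pdb <- function(receptor, path, b = 0) {
  at <- receptor$atoms
  b <- rep_len(b, nrow(at))
  lines <- format_pdb_atom(seq_len(nrow(at)), at$name, at$resname, at$chain,
                           at$resno, at$icode, at$x, at$y, at$z,
                           toupper(at$element), het = FALSE, b = b)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
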