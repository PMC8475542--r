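#' Construct a ligand pose
#'
#' @param pose_id Character identifier (e.g. SwissDock cluster/element).
#' @param atoms Data frame with columns `element`, `x`, `y`, `z` (Angstrom).
#' @param energy_score Docking fitness for the pose (e.g. SwissDock
#'   FullFitness); dimensionless as reported by the docking program,
#'   more negative = more favorable.
#' @return A `ligand_pose` object.
#' @export
ligand_pose <- function(pose_id, atoms, energy_score) {
  stopifnot(is.data.frame(atoms),
            all(c("element", "x", "y", "z") %in% names(atoms)))
  if (nrow(atoms) == 0L) stop("pose '", pose_id, "' has no atoms")
  if (!all(is.finite(atoms$x + atoms$y + atoms$z)))
    stop("pose '", pose_id, "' has non-finite coordinates")
  if (!is.finite(energy_score))
    stop("pose '", pose_id, "' has a non-finite energy score")
  atoms$element <- normalize_element(atoms$element)
  if (any(atoms$element == "")) stop("pose '", pose_id, "' has empty elements")
  structure(list(pose_id = as.character(pose_id),
                 atoms = atoms[, c("element", "x", "y", "z")],
                 energy_score = as.numeric(energy_score)),
            class = "ligand_pose")
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat("ligand pose '", x$pose_id, "': ", nrow(x$atoms),
      " atoms, energy ", format(x$energy_score), "\n", sep = "")
  invisible(x)
}

pose_coords <- function(pose) as.matrix(pose$atoms[, c("x", "y", "z")])

#' Read docked ligand poses with energy scores
#'
#' Supports three dialects:
#' \describe{
#'   \item{`swissdock`}{a SwissDock-style cluster PDB in which each pose
#'     block is introduced by `REMARK Cluster: <c>, Element: <e>` and
#'     carries a `REMARK FullFitness: <energy>` line; pose ids are
#'     `c<c>.e<e>`.}
#'   \item{`multimodel_pdb`}{one pose per MODEL; energies (and pose ids)
#'     come from a two-column tab-separated sidecar file
#'     (`pose_id<TAB>energy`, one row per MODEL in order).}
#'   \item{`sdf`}{an SD file; `energy_tag` names the data field holding
#'     the energy (e.g. `"FullFitness"`).}
#' }
#'
#' @param path Pose file.
#' @param dialect One of `"swissdock"`, `"multimodel_pdb"`, `"sdf"`.
#' @param energy_tag SDF property name holding the energy (sdf dialect).
#' @param sidecar Path to the energy sidecar (multimodel_pdb dialect).
#' @param elements For the swissdock dialect, `"all"` keeps every cluster
#'   member, `"representative"` keeps only element 0 of each cluster. The
#'   cluster-level FullFitness is assigned to every member.
#' @param keep_hydrogens Keep hydrogens? Default drops them, so contact
#'   detection behaves identically across input sources.
#' @return List of [ligand_pose()] objects, in file order.
#' @export
read_poses <- function(path,
                       dialect = c("swissdock", "multimodel_pdb", "sdf"),
                       energy_tag = NULL, sidecar = NULL,
                       elements = c("all", "representative"),
                       keep_hydrogens = FALSE) {
  dialect <- match.arg(dialect)
  elements <- match.arg(elements)
  if (!file.exists(path)) stop("pose file not found: ", path)
  poses <- switch(dialect,
    swissdock = read_poses_swissdock(path, elements, keep_hydrogens),
    multimodel_pdb = read_poses_multimodel(path, sidecar, keep_hydrogens),
    sdf = read_poses_sdf(path, energy_tag, keep_hydrogens)
  )
  if (length(poses) == 0L) stop("no poses found in '", path, "'")
  poses
}

read_poses_swissdock <- function(path, elements, keep_hydrogens) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^REMARK\\s+Cluster:", lines)
  if (length(starts) == 0L)
    stop("'", path, "' has no 'REMARK Cluster:' records; not a SwissDock-style file")
  ends <- c(starts[-1L] - 1L, length(lines))
  poses <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[starts[i]:ends[i]]
    hdr <- block[1L]
    cl <- sub(".*Cluster:\\s*([0-9]+).*", "\\1", hdr)
    el <- if (grepl("Element:", hdr)) sub(".*Element:\\s*([0-9]+).*", "\\1", hdr) else "0"
    id <- sprintf("c%s.e%s", cl, el)
    if (elements == "representative" && el != "0") next
    en_line <- grep("^(REMARK|USER)\\s+FullFitness:", block, value = TRUE)
    energy <- suppressWarnings(as.numeric(sub(".*FullFitness:\\s*", "", en_line[1L])))
    if (length(en_line) == 0L || is.na(energy))
      stop("pose '", id, "' in '", path, "' has no parseable FullFitness energy")
    at_lines <- grep("^(ATOM  |HETATM)", block, value = TRUE)
    if (length(at_lines) == 0L) stop("pose '", id, "' has no atom records")
    parsed <- lapply(at_lines, parse_pdb_atom)
    el_sym <- vapply(parsed, `[[`, "", "element")
    blank <- el_sym == ""
    el_sym[blank] <- element_from_name(vapply(parsed, `[[`, "", "name")[blank])
    atoms <- data.frame(element = el_sym,
                        x = vapply(parsed, `[[`, 0, "x"),
                        y = vapply(parsed, `[[`, 0, "y"),
                        z = vapply(parsed, `[[`, 0, "z"),
                        stringsAsFactors = FALSE)
    if (!keep_hydrogens) atoms <- atoms[!is_hydrogen(atoms$element), , drop = FALSE]
    poses[[i]] <- ligand_pose(id, atoms, energy)
  }
  poses[!vapply(poses, is.null, TRUE)]
}

read_poses_multimodel <- function(path, sidecar, keep_hydrogens) {
  if (is.null(sidecar))
    stop("multimodel_pdb dialect requires a `sidecar` energy table")
  if (!file.exists(sidecar)) stop("sidecar file not found: ", sidecar)
  side <- read.table(sidecar, header = FALSE, sep = "\t",
                     col.names = c("pose_id", "energy"),
                     colClasses = c("character", "numeric"),
                     comment.char = "#")
  if (nrow(side) == 0L) stop("empty sidecar '", sidecar, "'")
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  n_models <- nrow(pdb$xyz)
  if (n_models != nrow(side))
    stop("'", path, "' has ", n_models, " models but sidecar has ",
         nrow(side), " rows")
  element <- pdb$atom$elesy
  blank <- is.na(element) | element == ""
  element[blank] <- element_from_name(pdb$atom$elety[blank])
  element <- normalize_element(element)
  keep <- if (keep_hydrogens) rep(TRUE, length(element)) else !is_hydrogen(element)
  lapply(seq_len(n_models), function(m) {
    if (!is.finite(side$energy[m]))
      stop("pose '", side$pose_id[m], "' has no parseable energy in sidecar")
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
    ligand_pose(side$pose_id[m],
                data.frame(element = element[keep], x = xyz[keep, 1],
                           y = xyz[keep, 2], z = xyz[keep, 3],
                           stringsAsFactors = FALSE),
                side$energy[m])
  })
}

read_poses_sdf <- function(path, energy_tag, keep_hydrogens) {
  if (is.null(energy_tag))
    stop("sdf dialect requires `energy_tag` naming the energy property")
  sdfs <- suppressMessages(ChemmineR::read.SDFset(path))
  ids <- ChemmineR::sdfid(sdfs)
  lapply(seq_along(sdfs), function(i) {
    sdf <- sdfs[[i]]
    id <- if (!is.na(ids[i]) && nzchar(ids[i])) ids[i] else sprintf("mol%d", i)
    db <- ChemmineR::datablock(sdf)
    if (!(energy_tag %in% names(db)))
      stop("pose '", id, "' has no '", energy_tag, "' property")
    energy <- suppressWarnings(as.numeric(db[[energy_tag]]))
    if (is.na(energy))
      stop("pose '", id, "' has a non-numeric '", energy_tag, "' value")
    ab <- ChemmineR::atomblock(sdf)
    atoms <- data.frame(element = sub("_[0-9]+$", "", rownames(ab)),
                        x = ab[, 1], y = ab[, 2], z = ab[, 3],
                        stringsAsFactors = FALSE)
    if (!keep_hydrogens) atoms <- atoms[!is_hydrogen(atoms$element), , drop = FALSE]
    ligand_pose(id, atoms, energy)
  })
}

#' Write poses as a SwissDock-style cluster file
#'
#' Each pose becomes a block headed by `REMARK Cluster:`/`Element:` and a
#' `REMARK FullFitness:` energy line, followed by HETATM records. Pose ids
#' of the form `c<cluster>.e<element>` are preserved; other ids are written
#' as consecutive clusters with element 0.
#'
#' @param poses List of [ligand_pose()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_poses_swissdock <- function(poses, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("REMARK SwissDock-style cluster file written by condock", con)
  for (i in seq_along(poses)) {
    p <- poses[[i]]
    m <- regmatches(p$pose_id, regexec("^c([0-9]+)\\.e([0-9]+)$", p$pose_id))[[1]]
    if (length(m) == 3L) { cl <- m[2]; el <- m[3] } else { cl <- i - 1L; el <- 0L }
    writeLines(sprintf("REMARK Cluster: %s, Element: %s", cl, el), con)
    writeLines(sprintf("REMARK FullFitness: %.4f", p$energy_score), con)
    a <- p$atoms
    nm <- paste0(toupper(a$element), seq_len(nrow(a)))
    writeLines(format_pdb_atom(seq_len(nrow(a)), nm, "LIG", "X", 1L, "",
                               a$x, a$y, a$z, toupper(a$element), het = TRUE), con)
    writeLines("TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write poses as a multi-model PDB plus energy sidecar
#'
#' @param poses List of [ligand_pose()] objects (equal atom counts).
#' @param path Output PDB path (one MODEL per pose).
#' @param sidecar Output path for the tab-separated `pose_id`/`energy` table.
#' @return `path`, invisibly.
#' @export
write_poses_multimodel <- function(poses, path, sidecar) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(poses)) {
    p <- poses[[i]]
    a <- p$atoms
    nm <- paste0(toupper(a$element), seq_len(nrow(a)))
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(format_pdb_atom(seq_len(nrow(a)), nm, "LIG", "X", 1L, "",
                               a$x, a$y, a$z, toupper(a$element), het = TRUE), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  ids <- vapply(poses, `[[`, "", "pose_id")
  en <- vapply(poses, `[[`, 0, "energy_score")
  writeLines(sprintf("%s\t%.4f", ids, en), sidecar)
  invisible(path)
}

#' Write a single pose as a PDB file
#'
#' @param pose A [ligand_pose()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pose_pdb <- function(pose, path) {
  a <- pose$atoms
  nm <- paste0(toupper(a$element), seq_len(nrow(a)))
  lines <- format_pdb_atom(seq_len(nrow(a)), nm, "LIG", "X", 1L, "",
                           a$x, a$y, a$z, toupper(a$element), het = TRUE)
  writeLines(c(sprintf("REMARK pose %s energy %.4f", pose$pose_id,
                       pose$energy_score), lines, "END"), path)
  invisible(path)
}

#' Read a single ligand pose from a plain PDB file
#'
#' Reads every ATOM/HETATM record in the file as one pose -- the natural
#' format for a reference (crystallographic) ligand position. The energy
#' is taken from a `REMARK pose <id> energy <e>` line when present,
#' otherwise 0 (reference ligands carry no docking score).
#'
#' @param pose_id Identifier to assign when the file does not carry one.
#' @inheritParams write_pose_pdb
#' @param keep_hydrogens Keep hydrogens? Default `FALSE`.
#' @return A [ligand_pose()].
#' @export
read_pose_pdb <- function(path, pose_id = "reference", keep_hydrogens = FALSE) {
  if (!file.exists(path)) stop("pose file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^REMARK pose ", lines, value = TRUE)
  energy <- 0
  if (length(hdr)) {
    m <- regmatches(hdr[1], regexec("^REMARK pose (\\S+) energy (\\S+)", hdr[1]))[[1]]
    if (length(m) == 3L) { pose_id <- m[2]; energy <- as.numeric(m[3]) }
  }
  at_lines <- grep("^(ATOM  |HETATM)", lines, value = TRUE)
  if (length(at_lines) == 0L) stop("no atom records in '", path, "'")
  parsed <- lapply(at_lines, parse_pdb_atom)
  el_sym <- vapply(parsed, `[[`, "", "element")
  blank <- el_sym == ""
  el_sym[blank] <- element_from_name(vapply(parsed, `[[`, "", "name")[blank])
  atoms <- data.frame(element = el_sym,
                      x = vapply(parsed, `[[`, 0, "x"),
                      y = vapply(parsed, `[[`, 0, "y"),
                      z = vapply(parsed, `[[`, 0, "z"),
                      stringsAsFactors = FALSE)
  if (!keep_hydrogens) atoms <- atoms[!is_hydrogen(atoms$element), , drop = FALSE]
  ligand_pose(pose_id, atoms, energy)
}
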