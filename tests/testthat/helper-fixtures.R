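# Fixtures are built in code at test time; nothing binary is stored.

# Hand-written 3-residue poly-alanine PDB (15 heavy atoms), optionally
# with waters and an altloc'd residue appended.
polyala_pdb_lines <- function(waters = 0L, altloc = FALSE) {
  res <- function(resno, x0) {
    c(sprintf("ATOM  %5d  N   ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           N",
              (resno - 1) * 5 + 1, resno, x0 + 0.0, 0.0, 0.0),
      sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
              (resno - 1) * 5 + 2, resno, x0 + 1.458, 0.0, 0.0),
      sprintf("ATOM  %5d  C   ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
              (resno - 1) * 5 + 3, resno, x0 + 2.0, 1.4, 0.0),
      sprintf("ATOM  %5d  O   ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
              (resno - 1) * 5 + 4, resno, x0 + 1.3, 2.4, 0.0),
      sprintf("ATOM  %5d  CB  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
              (resno - 1) * 5 + 5, resno, x0 + 2.0, -1.0, 1.0))
  }
  lines <- c(res(1, 0), res(2, 5), res(3, 10))
  if (altloc) {
    lines <- c(lines,
      "ATOM     16  N  AALA A  25      20.000   0.000   0.000  0.60  0.00           N",
      "ATOM     17  N  BALA A  25      21.000   0.000   0.000  0.40  0.00           N",
      "ATOM     18  CA AALA A  25      20.500   1.000   0.000  0.60  0.00           C",
      "ATOM     19  CA BALA A  25      21.500   1.000   0.000  0.40  0.00           C")
  }
  if (waters > 0L)
    lines <- c(lines, sprintf(
      "HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
      100L + seq_len(waters), 100L + seq_len(waters),
      30 + seq_len(waters), 0, 0))
  c(lines, "END")
}

write_polyala_pdb <- function(path, waters = 0L, altloc = FALSE) {
  writeLines(polyala_pdb_lines(waters, altloc), path)
  path
}

# Receptor built directly as the package's data structure: residues at
# given CB-like single-atom positions (plus optional extra atoms), for
# geometric tests that need exact distances.
make_point_receptor <- function(centers, resnames = "ALA", chain = "A") {
  n <- nrow(centers)
  resnames <- rep_len(resnames, n)
  atoms <- data.frame(
    key = paste(chain, seq_len(n), "", sep = ":"),
    chain = chain, resno = seq_len(n), icode = "",
    resname = resnames, name = "CB", element = "C",
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, source_path = NA_character_,
                 model_index = 1L),
            class = "condock_receptor")
}

# Random receptor for oracle comparisons: n_res residues x atoms_per_res
# atoms in a box.
make_random_receptor <- function(seed, n_res = 50L, atoms_per_res = 3L,
                                 box = 30) {
  set.seed(seed)
  n <- n_res * atoms_per_res
  atoms <- data.frame(
    key = rep(paste("A", seq_len(n_res), "", sep = ":"),
              each = atoms_per_res),
    chain = "A", resno = rep(seq_len(n_res), each = atoms_per_res),
    icode = "", resname = "ALA",
    name = rep(c("N", "CA", "CB"), length.out = n),
    element = rep(c("N", "C", "C"), length.out = n),
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, source_path = NA_character_,
                 model_index = 1L),
            class = "condock_receptor")
}

make_random_pose <- function(seed, n_atoms = 20L, box = 30, id = "p",
                             energy = -100) {
  set.seed(seed)
  ligand_pose(id, data.frame(element = "C",
                             x = runif(n_atoms, 0, box),
                             y = runif(n_atoms, 0, box),
                             z = runif(n_atoms, 0, box)), energy)
}

# Independent brute-force contact oracle: double loop over residues and
# atom pairs, no vectorized trick shared with the implementation.
brute_force_site <- function(receptor, pose, cutoff = 3.5) {
  at <- receptor$atoms
  lig <- as.matrix(pose$atoms[, c("x", "y", "z")])
  hit <- character(0)
  for (key in unique(at$key)) {
    ra <- at[at$key == key, c("x", "y", "z")]
    found <- FALSE
    for (i in seq_len(nrow(ra))) {
      for (j in seq_len(nrow(lig))) {
        d <- sqrt(sum((as.numeric(ra[i, ]) - lig[j, ])^2))
        if (d <= cutoff) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) hit <- c(hit, key)
  }
  hit
}

# Independent JSD oracle, written directly from the definition.
jsd_oracle <- function(column, background = rep(1 / 20, 20),
                       gap_penalty = TRUE) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  inf <- column[column %in% aa]
  n <- length(column)
  f <- sapply(aa, function(a) sum(inf == a)) / length(inf)
  lam <- 1 / (20 * n)
  p <- (f + lam) / (1 + 20 * lam)
  b <- background / sum(background)
  m <- (p + b) / 2
  js <- 0.5 * sum(p * log2(p / m)) + 0.5 * sum(b * log2(b / m))
  if (gap_penalty) js <- js * sum(column != "-") / n
  js
}

# random 3-D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_pose <- function(pose, rot = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(pose$atoms[, c("x", "y", "z")]) %*% t(rot)
  xyz <- sweep(xyz, 2, shift, "+")
  p <- pose
  p$atoms$x <- xyz[, 1]; p$atoms$y <- xyz[, 2]; p$atoms$z <- xyz[, 3]
  p
}

transform_receptor <- function(receptor, rot = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(receptor$atoms[, c("x", "y", "z")]) %*% t(rot)
  xyz <- sweep(xyz, 2, shift, "+")
  r <- receptor
  r$atoms$x <- xyz[, 1]; r$atoms$y <- xyz[, 2]; r$atoms$z <- xyz[, 3]
  r
}

# Valid Clustal rendering of an alignment (Biostrings requires the two
# blank lines after the header and a consensus line per block).
write_clustal <- function(ids, seqs, path) {
  pad <- formatC(ids, width = max(nchar(ids)) + 4, flag = "-")
  lines <- c("CLUSTAL W (1.82) multiple sequence alignment", "", "",
             paste0(pad, seqs),
             paste0(strrep(" ", max(nchar(ids)) + 4),
                    strrep(" ", nchar(seqs[1]))),
             "")
  writeLines(lines, path)
  path
}

scenario_fixture_dir <- function() {
  system.file("extdata", "scenario1", package = "condock")
}
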