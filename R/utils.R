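# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# The 20 standard amino acids, one-letter, alphabetical.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Residue key: "chain:resno:icode" (icode usually empty -> trailing colon).
residue_key <- function(chain, resno, icode = "") {
  icode[is.na(icode)] <- ""
  chain[is.na(chain)] <- ""
  paste(chain, as.integer(resno), icode, sep = ":")
}

# Fixed-column PDB coordinate record. Atom names shorter than 4 characters
# start in column 14 per the format spec.
format_pdb_atom <- function(serial, name, resname, chain, resno, icode,
                            x, y, z, element, het = FALSE, b = 0) {
  rec <- if (het) "HETATM" else "ATOM"
  name4 <- ifelse(nchar(name) < 4L, sprintf(" %-3s", name), name)
  sprintf("%-6s%5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name4, resname, chain, resno,
          ifelse(nchar(icode), icode, " "), x, y, z, 1, b, element)
}

# Parse one ATOM/HETATM line by fixed columns; returns a one-row list.
parse_pdb_atom <- function(line) {
  num <- function(s) suppressWarnings(as.numeric(trimws(s)))
  list(
    name    = trimws(substr(line, 13, 16)),
    altloc  = trimws(substr(line, 17, 17)),
    resname = trimws(substr(line, 18, 20)),
    chain   = trimws(substr(line, 22, 22)),
    resno   = suppressWarnings(as.integer(trimws(substr(line, 23, 26)))),
    icode   = trimws(substr(line, 27, 27)),
    x = num(substr(line, 31, 38)),
    y = num(substr(line, 39, 46)),
    z = num(substr(line, 47, 54)),
    element = trimws(substr(line, 77, 78))
  )
}

# Derive an element symbol from a PDB atom name when columns 77-78 are blank.
element_from_name <- function(name) {
  s <- gsub("[0-9'\"]", "", name)
  two <- toupper(substr(s, 1, 2))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"),
         paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))),
         substr(s, 1, 1))
}

normalize_element <- function(el) {
  el <- trimws(el)
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}

is_hydrogen <- function(element) normalize_element(element) %in% c("H", "D")

md5_file <- function(path) unname(tools::md5sum(path))

md5_string <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf)
  md5_file(tf)
}

# Squared-distance minimum between each row of `a` (n x 3) and any row of
# `b` (m x 3); returns length-n vector. Plain matrix algebra; problem sizes
# here (a few thousand atoms) need nothing fancier.
min_dist2_to_set <- function(a, b) {
  ra <- rowSums(a^2)
  rb <- rowSums(b^2)
  d2 <- outer(ra, rb, "+") - 2 * (a %*% t(b))
  d2[d2 < 0] <- 0
  apply(d2, 1L, min)
}

write_fasta <- function(ids, seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
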