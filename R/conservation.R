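#' Read a multiple sequence alignment
#'
#' Reads a protein alignment in FASTA or Clustal format (via
#' \pkg{Biostrings}). All sequences must have equal aligned length;
#' letters outside the 20 standard amino acids are mapped to `X`, and
#' `.` gap characters to `-`.
#'
#' @param path Alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return A `condock_alignment`: list with `ids`, `seqs` (character
#'   vector of aligned sequences) and `ncol`.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "fasta") {
    ss <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) stop("failed to parse FASTA '", path,
                                            "': ", conditionMessage(e),
                                            call. = FALSE))
    ids <- names(ss)
    seqs <- as.character(ss)
  } else {
    ma <- tryCatch(Biostrings::readAAMultipleAlignment(path, format = "clustal"),
                   error = function(e) stop("failed to parse Clustal '", path,
                                            "': ", conditionMessage(e),
                                            call. = FALSE))
    seqs <- as.character(ma)
    ids <- names(seqs)
  }
  make_alignment_object(ids, seqs, path)
}

make_alignment_object <- function(ids, seqs, path = NA_character_) {
  if (length(seqs) < 2L)
    stop("alignment has ", length(seqs),
         " sequence(s); conservation needs at least 2")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: sequence lengths ",
         paste(unique(widths), collapse = ", "))
  seqs <- toupper(seqs)
  seqs <- chartr(".", "-", seqs)
  seqs <- vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[!(ch %in% c(AA20, "X", "-"))] <- "X"
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
  if (is.null(ids)) ids <- rep("", length(seqs))
  ids <- ifelse(is.na(ids) | ids == "", sprintf("seq%d", seq_along(seqs)), ids)
  # first whitespace-delimited token, as FASTA ids are usually treated
  ids <- sub("\\s.*$", "", ids)
  structure(list(ids = unname(ids), seqs = unname(seqs),
                 ncol = unname(widths[1L]), source_path = path),
            class = "condock_alignment")
}

#' @export
print.condock_alignment <- function(x, ...) {
  cat("alignment: ", length(x$ids), " sequences x ", x$ncol, " columns\n",
      sep = "")
  invisible(x)
}

alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
}

#' Background amino-acid distributions for conservation scoring
#'
#' `"uniform"` is 1/20 for each residue. `"robinson"` is the Robinson &
#' Robinson (1991) empirical amino-acid frequency set, the standard
#' database background used by BLAST-era sequence statistics.
#'
#' @param type `"uniform"` or `"robinson"`.
#' @return Named numeric vector over the 20 standard residues, summing to 1.
#' @export
jsd_background <- function(type = c("uniform", "robinson")) {
  type <- match.arg(type)
  if (type == "uniform") return(setNames(rep(1 / 20, 20), AA20))
  rb <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
          Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
          L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
          S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
  rb <- rb[order(names(rb))]
  rb / sum(rb)
}

#' Jensen-Shannon divergence conservation score for one alignment column
#'
#' Measures how far the column's residue composition `P` diverges from a
#' background distribution `B`:
#' `JSD = 1/2 KL(P||M) + 1/2 KL(B||M)` with `M = (P+B)/2`, logarithms
#' base 2, so the score lies in `[0, 1]` (1 bit is the maximum). Gaps are
#' excluded from `P`; a pseudo-count of `1/(20 * n_seq)` is added to the
#' column frequencies so no KL term has zero support. With
#' `gap_penalty = TRUE` the score is multiplied by the fraction of
#' non-gap symbols, down-weighting gappy columns.
#'
#' A column identical in composition to the background scores 0; a fully
#' conserved column scores near 1.
#'
#' @param column Character vector of single-letter symbols (one per
#'   sequence), `-` for gaps; `X` is treated as non-informative.
#' @param background Named distribution over the 20 residues, see
#'   [jsd_background()].
#' @param gap_penalty Multiply by the non-gap fraction? Default `TRUE`.
#' @return Conservation score in `[0, 1]`.
#' @export
jsd_column_score <- function(column, background = jsd_background(),
                             gap_penalty = TRUE) {
  stopifnot(length(column) > 0L)
  column <- toupper(column)
  n_seq <- length(column)
  informative <- column[column %in% AA20]
  if (length(informative) == 0L) {
    warning("column has no informative (non-gap, non-X) symbols; score 0")
    return(0)
  }
  counts <- table(factor(informative, levels = AA20))
  f <- as.numeric(counts) / length(informative)
  lambda <- 1 / (20 * n_seq)
  p <- (f + lambda) / (1 + 20 * lambda)
  b <- as.numeric(background[AA20])
  b <- b / sum(b)
  m <- (p + b) / 2
  kl <- function(a, mm) sum(ifelse(a > 0, a * log2(a / mm), 0))
  score <- 0.5 * kl(p, m) + 0.5 * kl(b, m)
  score <- min(max(score, 0), 1)
  if (gap_penalty) score <- score * sum(column != "-") / n_seq
  score
}

#' Per-position conservation profile of one aligned sequence
#'
#' Scores every alignment column with [jsd_column_score()] and reports
#' the scores at the target sequence's positions: entry `i` corresponds
#' to the i-th non-gap residue of the target (1-based ungapped ordinal).
#' Columns where the target has a gap are skipped.
#'
#' @param alignment A `condock_alignment` from [read_alignment()].
#' @param target_id Id of the sequence whose positions index the profile.
#' @param background,gap_penalty Passed to [jsd_column_score()].
#' @return A `position_scores` data frame with columns `pos`, `aa`,
#'   `score`, and attribute `provenance = "jsd"`.
#' @export
profile_from_alignment <- function(alignment, target_id,
                                   background = jsd_background(),
                                   gap_penalty = TRUE) {
  stopifnot(inherits(alignment, "condock_alignment"))
  hit <- which(alignment$ids == target_id)
  if (length(hit) == 0L)
    stop("target_id '", target_id, "' not found in alignment (ids: ",
         paste(head(alignment$ids, 5), collapse = ", "), " ...)")
  mat <- alignment_matrix(alignment)
  target <- mat[hit[1L], ]
  cols <- which(target != "-")
  scores <- vapply(cols, function(j)
    jsd_column_score(mat[, j], background, gap_penalty), 0)
  position_scores(pos = seq_along(cols), aa = target[cols], score = scores,
                  provenance = "jsd")
}

position_scores <- function(pos, aa, score, provenance, grade = NULL) {
  df <- data.frame(pos = as.integer(pos), aa = aa, score = as.numeric(score),
                   stringsAsFactors = FALSE)
  if (!is.null(grade)) df$grade <- as.integer(grade)
  attr(df, "provenance") <- provenance
  class(df) <- c("position_scores", "data.frame")
  df
}

#' Read a ConSurf-style grades table
#'
#' Expects a whitespace- or tab-delimited text table whose first three
#' columns are sequence position, one-letter residue, and an integer
#' conservation grade from 0 to 9 (9 = retained in all organisms).
#' Lines starting with `#` are ignored.
#'
#' @param path Grades file.
#' @return A `position_scores` data frame (`pos`, `aa`, `score`, `grade`),
#'   with `score = grade / 9` and `provenance = "consurf_grades"`. The
#'   residue letters are retained for identity checking when the profile
#'   is mapped onto a structure.
#' @export
read_consurf_grades <- function(path) {
  if (!file.exists(path)) stop("grades file not found: ", path)
  tab <- tryCatch(
    read.table(path, header = FALSE, stringsAsFactors = FALSE,
               comment.char = "#"),
    error = function(e) stop("cannot parse grades table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(tab) == 0L || ncol(tab) < 3L)
    stop("grades table '", path,
         "' needs at least 3 columns: position, residue, grade")
  # tolerate a header row of column names
  if (is.na(suppressWarnings(as.integer(tab[1, 1])))) tab <- tab[-1, , drop = FALSE]
  if (nrow(tab) == 0L) stop("grades table '", path, "' is empty")
  pos <- suppressWarnings(as.integer(tab[[1]]))
  grade <- suppressWarnings(as.numeric(tab[[3]]))
  bad <- which(is.na(pos) | is.na(grade) | grade != round(grade) |
                 grade < 0 | grade > 9)
  if (length(bad))
    stop("grades table '", path, "': invalid grade (must be an integer 0-9) ",
         "at row(s) ", paste(head(bad, 5), collapse = ", "))
  if (anyDuplicated(pos))
    stop("grades table '", path, "': duplicate position(s) ",
         paste(head(unique(pos[duplicated(pos)]), 5), collapse = ", "))
  ord <- order(pos)
  position_scores(pos = pos[ord], aa = toupper(tab[[2]][ord]),
                  score = grade[ord] / 9, provenance = "consurf_grades",
                  grade = as.integer(grade[ord]))
}

#' Map per-position conservation scores onto a receptor structure
#'
#' Aligns the score table's sequence against the structure's one-letter
#' sequence (global alignment, BLOSUM62, gap open/extend 10/0.5 via
#' \pkg{Biostrings}) and carries each position's score onto the matched
#' structure residue. Structure residues with no aligned score carry no
#' profile entry. An aligned-position identity below `min_identity`
#' aborts with the alignment shown; individual residue-letter mismatches
#' only warn (the score is still assigned).
#'
#' @param scores A `position_scores` object from [read_consurf_grades()]
#'   or [profile_from_alignment()].
#' @param structure A `condock_receptor`.
#' @param normalize For grade provenance, divide grades by 9 to `[0, 1]`
#'   (default `TRUE`; exact: value times 9 recovers the integer grade).
#'   Ignored for JSD provenance, whose scores are already in `[0, 1]`.
#' @param min_identity Minimum sequence identity over aligned positions
#'   (default 0.8).
#' @return A `conservation_profile`: list with `values` (named numeric in
#'   `[0, 1]`, keyed by residue key), `provenance`, and `raw_grades`
#'   (named integer, grade provenance only).
#' @export
map_profile_to_structure <- function(scores, structure, normalize = TRUE,
                                     min_identity = 0.8) {
  stopifnot(inherits(scores, "position_scores"),
            inherits(structure, "condock_receptor"))
  prov <- attr(scores, "provenance")
  res <- receptor_residues(structure)
  struct_seq <- paste(receptor_sequence(structure), collapse = "")
  target_seq <- paste(scores$aa, collapse = "")

  b62 <- get_blosum62()
  pa <- Biostrings::pairwiseAlignment(target_seq, struct_seq,
                                      substitutionMatrix = b62,
                                      gapOpening = 10, gapExtension = 0.5,
                                      type = "global")
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ti <- si <- 0L
  pairs <- matrix(0L, nrow = 0L, ncol = 2L)
  match_flag <- logical(0)
  for (k in seq_along(ap)) {
    if (ap[k] != "-") ti <- ti + 1L
    if (as_[k] != "-") si <- si + 1L
    if (ap[k] != "-" && as_[k] != "-") {
      pairs <- rbind(pairs, c(ti, si))
      match_flag <- c(match_flag, ap[k] == as_[k])
    }
  }
  if (nrow(pairs) == 0L)
    stop("no aligned positions between score table and structure")
  identity <- mean(match_flag)
  if (identity < min_identity)
    stop(sprintf(
      "score/structure sequence identity %.1f%% below threshold %.1f%%\n%s\n%s",
      100 * identity, 100 * min_identity,
      paste0("scores:    ", paste(ap, collapse = "")),
      paste0("structure: ", paste(as_, collapse = ""))))
  n_mis <- sum(!match_flag)
  if (n_mis > 0L)
    warning(n_mis, " aligned position(s) differ between score table and ",
            "structure; scores assigned anyway")

  val <- scores$score
  if (prov == "consurf_grades" && !isTRUE(normalize)) val <- as.numeric(scores$grade)
  values <- setNames(val[pairs[, 1]], res$key[pairs[, 2]])
  raw <- NULL
  if (prov == "consurf_grades")
    raw <- setNames(scores$grade[pairs[, 1]], res$key[pairs[, 2]])
  out <- list(values = values, provenance = prov, raw_grades = raw)
  class(out) <- "conservation_profile"
  out
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Build a conservation profile from a plain named vector
#'
#' Convenience constructor, mainly for ablation experiments (e.g. a
#' constant profile to show that a flat conservation surface reduces the
#' combined ranking to the pure energy ranking).
#'
#' @param values Named numeric vector in `[0, 1]`, keyed by residue key
#'   (`"chain:resno:icode"`).
#' @param provenance Free-text provenance label.
#' @return A `conservation_profile`.
#' @export
conservation_profile <- function(values, provenance = "manual") {
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (any(values < 0 | values > 1))
    stop("conservation values must lie in [0, 1]")
  structure(list(values = values, provenance = provenance, raw_grades = NULL),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("conservation profile (", x$provenance, "): ", length(x$values),
      " residues, range [", sprintf("%.3f", min(x$values)), ", ",
      sprintf("%.3f", max(x$values)), "]\n", sep = "")
  invisible(x)
}

#' Export a conservation profile as TSV
#'
#' @param profile A `conservation_profile`.
#' @param structure The `condock_receptor` the profile is keyed to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, structure, path) {
  res <- receptor_residues(structure)
  sc <- unname(profile$values[res$key])
  df <- data.frame(chain = res$chain, resseq = res$resno, icode = res$icode,
                   resname = res$resname,
                   score = ifelse(is.na(sc), NA, sprintf("%.6f", sc)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# condock conservation profile", con)
  writeLines(paste0("# provenance: ", profile$provenance), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a PDB copy with conservation in the B-factor column
#'
#' Standard trick for coloring a surface by conservation in a molecular
#' viewer: every atom of a residue gets the residue's profile value
#' (scaled 0-1) as its B-factor; residues without a value get 0.
#'
#' @inheritParams write_profile_tsv
#' @return `path`, invisibly.
#' @export
write_profile_pdb <- function(profile, structure, path) {
  at <- structure$atoms
  b <- unname(profile$values[at$key])
  b[is.na(b)] <- 0
  write_receptor_pdb(structure, path, b = b)
}
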