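aln_ids <- sprintf("sp%d", 1:6)
aln_seqs <- c("MKVLITAGPTREPIDPVRYISNHSSGKMGFAIAEAAARRGA",
              "MKVLVTAGPTREPIDPVRYISNHSSGKMGYAIAEAAARRGA",
              "MKVLITAGPTHEPIDPVRYISNHSSGKMGFAIAEAAARRGA",
              "MKVLITAGPTREPLDPVRYISNHSSGKMGFAIAEAASRRGA",
              "MKVLITAGPTREPIDPVRYISNFSSGKMGFAIAEAAARRGA",
              "MKVLITAGPTREPIDPVRYISNHSSGKMCFAIAEAAARRGA")

test_that("FASTA and Clustal renderings of one alignment parse identically", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", aln_ids), aln_seqs)), fa)
  a1 <- read_alignment(fa, "fasta")
  expect_equal(length(a1$ids), 6L)
  expect_equal(a1$ncol, nchar(aln_seqs[1]))

  cl <- write_clustal(aln_ids, aln_seqs, withr::local_tempfile(fileext = ".aln"))
  a2 <- read_alignment(cl, "clustal")
  expect_equal(a2$ids, a1$ids)
  expect_equal(a2$seqs, a1$seqs)
})

test_that("single-sequence and ragged alignments are rejected; odd letters map to X", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">only", aln_seqs[1]), fa)
  expect_error(read_alignment(fa), "at least 2")

  ragged <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEF", ">b", "ACD"), ragged)
  expect_error(read_alignment(ragged), "ragged")

  odd <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACZEF", ">b", "AC-EF"), odd)
  a <- read_alignment(odd)
  expect_equal(substr(a$seqs[1], 3, 3), "X")
})

test_that("JSD scoring matches the definition: background-identical columns score 0, conserved columns match the oracle", {
  # one of each residue: column frequencies equal the uniform background
  expect_equal(jsd_column_score(c("A", "C", "D", "E", "F", "G", "H", "I",
                                  "K", "L", "M", "N", "P", "Q", "R", "S",
                                  "T", "V", "W", "Y")), 0, tolerance = 1e-12)
  col <- rep("A", 6)
  expect_equal(jsd_column_score(col), jsd_oracle(col), tolerance = 1e-12)
  # with the 1/(20 n) pseudo-count a 6-deep conserved column sits well
  # above the background but below the 1-bit ceiling
  expect_gt(jsd_column_score(col), 0.5)
  expect_gt(jsd_column_score(rep("A", 50)), jsd_column_score(col))
  # robinson background, mixed column
  mixed <- c("A", "A", "A", "L", "L", "S")
  expect_equal(jsd_column_score(mixed, jsd_background("robinson")),
               jsd_oracle(mixed, as.numeric(jsd_background("robinson"))),
               tolerance = 1e-12)
})

test_that("the gap penalty is exactly the non-gap fraction and all-gap columns warn with score 0", {
  full <- jsd_column_score(rep("A", 6), gap_penalty = TRUE)
  half <- jsd_column_score(c("A", "A", "A", "-", "-", "-"), gap_penalty = TRUE)
  expect_identical(half, full / 2)
  expect_warning(s <- jsd_column_score(rep("-", 4)), "no informative")
  expect_identical(s, 0)
})

test_that("JSD is permutation-invariant and stable under duplicating the alignment", {
  set.seed(31)
  for (i in 1:20) {
    col <- sample(c("A", "L", "S", "G", "-"), 40, replace = TRUE)
    expect_identical(jsd_column_score(col), jsd_column_score(sample(col)))
    # duplicating every sequence changes counts proportionally: the
    # column frequencies are exactly unchanged, and the score moves only
    # through the 1/(20 n) pseudo-count, i.e. by O(1/n)
    expect_lt(abs(jsd_column_score(c(col, col)) - jsd_column_score(col)),
              0.03)
  }
})

test_that("alignment profiles index the target's ungapped positions and skip its gap columns", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  # target has a gap at column 7
  writeLines(c(">t", "ACDEFG-IK", ">u", "ACDEFGHIK", ">v", "ACDEFGHIK"), fa)
  aln <- read_alignment(fa)
  ps <- profile_from_alignment(aln, "t")
  expect_equal(nrow(ps), 8L)
  expect_equal(ps$pos, 1:8)
  expect_equal(ps$aa, c("A", "C", "D", "E", "F", "G", "I", "K"))
  expect_error(profile_from_alignment(aln, "nope"), "not found")

  # fully conserved alignment: every position scores the same value
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "AAAA", ">b", "AAAA", ">c", "AAAA"), fa2)
  ps2 <- profile_from_alignment(read_alignment(fa2), "a")
  expect_equal(length(unique(ps2$score)), 1L)
  expect_true(all(ps2$score >= 0 & ps2$score <= 1))
})

test_that("ConSurf-style grades tables parse, validate, and normalize exactly", {
  g <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# pos aa grade", "1 M 9", "2 K 9", "3 V 3", "4 L 0", "5 I 7"), g)
  ps <- read_consurf_grades(g)
  expect_equal(ps$pos, 1:5)
  expect_equal(ps$grade, c(9L, 9L, 3L, 0L, 7L))
  expect_identical(ps$score * 9, as.numeric(ps$grade))  # exact, bit-for-bit

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 M 9", "2 K 11"), bad)
  expect_error(read_consurf_grades(bad), "row")
  dup <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 M 9", "1 K 3"), dup)
  expect_error(read_consurf_grades(dup), "duplicate")
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_error(read_consurf_grades(empty))
})

test_that("profiles map onto structures 1:1 when sequences match, and grade 9 becomes 1.0", {
  sc <- make_scenario(scenario_spec(seed = 5, pocket_conservation = 1.0))
  prof <- map_profile_to_structure(sc$grades, sc$receptor)
  res <- receptor_residues(sc$receptor)
  expect_setequal(names(prof$values), res$key)
  expect_true(all(prof$values >= 0 & prof$values <= 1))
  expect_true(all(prof$values[sc$pocket] == 1.0))
  # grade recovery through the mapped profile is exact
  expect_identical(unname(prof$values * 9), as.numeric(unname(prof$raw_grades)))
})

test_that("structure residues absent from the score table carry no profile entry", {
  # 10-residue structure; grades only for the last 8 positions
  resnames <- c("GLY", "ALA", "VAL", "LEU", "ILE", "PHE", "PRO", "SER",
                "THR", "TYR")
  centers <- cbind(seq(0, 45, by = 5), 0, 0)
  rec <- make_point_receptor(centers, resnames)
  g <- withr::local_tempfile(fileext = ".txt")
  writeLines(sprintf("%d %s %d", 1:8, c("V", "L", "I", "F", "P", "S", "T", "Y"),
                     c(9, 8, 7, 6, 5, 4, 3, 2)), g)
  prof <- map_profile_to_structure(read_consurf_grades(g), rec)
  res <- receptor_residues(rec)
  expect_false(res$key[1] %in% names(prof$values))
  expect_false(res$key[2] %in% names(prof$values))
  expect_setequal(names(prof$values), res$key[3:10])
  expect_equal(unname(prof$values[res$key[3]]), 1.0)
})

test_that("low-identity mappings abort and letter mismatches only warn", {
  resnames <- rep(c("GLY", "ALA", "VAL", "LEU", "ILE"), 2)
  rec <- make_point_receptor(cbind(seq(0, 45, by = 5), 0, 0), resnames)
  g <- withr::local_tempfile(fileext = ".txt")
  writeLines(sprintf("%d %s %d", 1:10, c("G", "A", "V", "L", "I",
                                         "G", "A", "V", "L", "F"), 5), g)
  expect_warning(map_profile_to_structure(read_consurf_grades(g), rec),
                 "differ")
  far <- withr::local_tempfile(fileext = ".txt")
  writeLines(sprintf("%d %s %d", 1:10, c("W", "W", "W", "W", "W",
                                         "W", "W", "W", "W", "W"), 5), far)
  expect_error(suppressWarnings(
    map_profile_to_structure(read_consurf_grades(far), rec)), "identity")
})

test_that("profile exports write a TSV and a B-factor PDB keyed to the structure", {
  sc <- make_scenario(scenario_spec(seed = 6))
  prof <- scenario_profile(sc)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(prof, sc$receptor, tsv)
  tab <- read.table(tsv, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(tab), nrow(receptor_residues(sc$receptor)))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_profile_pdb(prof, sc$receptor, pdb)
  lines <- grep("^ATOM", readLines(pdb), value = TRUE)
  b <- as.numeric(substr(lines, 61, 66))
  expect_true(all(b >= 0 & b <= 1))
  expect_gt(max(b), min(b))
})
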