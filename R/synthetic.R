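# Seeded synthetic scenarios: a toy receptor bundle with a central
# cavity, an MSA encoding a planted conservation profile, and a pose set
# mixing one true pose in a conserved pocket with surface decoys.

# Pseudo-receptor geometry, fixed in one place. CA atoms sit on a
# cylinder of radius `radius` surrounding a central cavity (the toy
# analogue of the large extracellular cavity ligands bind in); each
# residue is a rigid 5-heavy-atom alanine-like unit with CB pointing
# inward; pocket/decoy anchors sit `anchor_inset` inside the wall.
BUNDLE <- list(ring_size = 12L, radius = 8.5, rise = 3.0,
               cb_len = 1.53, anchor_inset = 4.5, ligand_half = 0.7)

#' Specify a synthetic binding-site scenario
#'
#' Bundles every knob of the generator: receptor size, how conserved the
#' planted pocket is versus the background surface, how many decoy poses
#' surround the one true pose, and where the true pose's docking energy
#' falls among the decoys (percentile 0 = best energy of all, so docking
#' alone already wins; percentile 1 = worst, so only conservation can
#' rescue the ranking).
#'
#' @param seed Integer RNG seed; every artifact of the scenario is a pure
#'   function of this spec, including the seed.
#' @param n_residues Receptor size (>= 24, so the cylinder closes around
#'   a cavity). Default 60.
#' @param pocket_fraction Fraction of residues forming the conserved
#'   pocket (nearest the pocket anchor). Default 0.2.
#' @param pocket_conservation Planted conservation level of pocket
#'   columns in `[0, 1]`. Default 0.9.
#' @param background_conservation Planted level elsewhere. Default 0.2;
#'   must not exceed `pocket_conservation`.
#' @param n_decoys Number of decoy poses (>= 1). Default 10.
#' @param true_energy_percentile Where the true pose's energy falls in
#'   the decoy energy distribution (0 = most negative/best). Default 0.7,
#'   i.e. the true pose is *not* the energy-best -- the rescue setup.
#' @param n_msa_sequences Sequences in the generated alignment (incl. the
#'   unmutated target). Default 50.
#' @param mutation_rate Probability scale for mutating non-conserved
#'   columns; a column of planted level `c` keeps the consensus residue
#'   with probability `1 - mutation_rate * (1 - c)`. Default 1, so the
#'   expected retention equals the planted level.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(seed, n_residues = 60L, pocket_fraction = 0.2,
                          pocket_conservation = 0.9,
                          background_conservation = 0.2, n_decoys = 10L,
                          true_energy_percentile = 0.7,
                          n_msa_sequences = 50L, mutation_rate = 1.0) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("scenario_spec requires an explicit integer `seed` (no hidden entropy)")
  spec <- list(seed = as.integer(seed), n_residues = as.integer(n_residues),
               pocket_fraction = pocket_fraction,
               pocket_conservation = pocket_conservation,
               background_conservation = background_conservation,
               n_decoys = as.integer(n_decoys),
               true_energy_percentile = true_energy_percentile,
               n_msa_sequences = as.integer(n_msa_sequences),
               mutation_rate = mutation_rate)
  probs <- c("pocket_fraction", "pocket_conservation",
             "background_conservation", "true_energy_percentile",
             "mutation_rate")
  for (p in probs)
    if (!is.numeric(spec[[p]]) || spec[[p]] < 0 || spec[[p]] > 1)
      stop("`", p, "` must lie in [0, 1]")
  if (spec$n_residues < 24L)
    stop("n_residues must be >= 24 to close a cavity")
  if (spec$n_decoys < 1L) stop("n_decoys must be >= 1 (rescue needs decoys)")
  if (spec$n_msa_sequences < 2L) stop("n_msa_sequences must be >= 2")
  if (spec$pocket_conservation < spec$background_conservation)
    stop("pocket_conservation must be >= background_conservation")
  if (spec$pocket_fraction <= 0)
    stop("pocket_fraction must be positive")
  class(spec) <- "scenario_spec"
  spec
}

# deterministic residue frame on the bundle wall
bundle_frames <- function(n_residues) {
  i <- seq_len(n_residues) - 1L
  ring <- i %/% BUNDLE$ring_size
  k <- i %% BUNDLE$ring_size
  theta <- 2 * pi * k / BUNDLE$ring_size + (ring %% 2L) * pi / BUNDLE$ring_size
  list(theta = theta, z = ring * BUNDLE$rise,
       n_rings = max(ring) + 1L)
}

#' Generate the toy receptor of a scenario
#'
#' A poly-alanine pseudo-receptor: residues placed on a staggered
#' cylindrical bundle around a central cavity, each a rigid 5-heavy-atom
#' unit (N, CA, C, O, CB) with CB pointing into the cavity. Fully
#' deterministic given the spec; coordinates are pre-rounded to PDB
#' precision (3 decimals) so writing and re-reading is an identity.
#'
#' @param spec A [scenario_spec()].
#' @return A `condock_receptor`.
#' @export
make_receptor <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  fr <- bundle_frames(spec$n_residues)
  rows <- vector("list", spec$n_residues)
  for (i in seq_len(spec$n_residues)) {
    th <- fr$theta[i]; z0 <- fr$z[i]
    u <- c(-cos(th), -sin(th), 0)          # inward
    tv <- c(-sin(th), cos(th), 0)          # tangential
    zv <- c(0, 0, 1)
    ca <- c(BUNDLE$radius * cos(th), BUNDLE$radius * sin(th), z0)
    pos <- rbind(N  = ca - 1.20 * tv + 0.50 * zv,
                 CA = ca,
                 C  = ca + 1.20 * tv + 0.50 * zv,
                 O  = ca + 1.60 * tv + 1.60 * zv,
                 CB = ca + BUNDLE$cb_len * u)
    rows[[i]] <- data.frame(
      key = residue_key("A", i, ""), chain = "A", resno = i, icode = "",
      resname = "ALA", name = rownames(pos),
      element = c("N", "C", "C", "O", "C"),
      x = round(pos[, 1], 3), y = round(pos[, 2], 3), z = round(pos[, 3], 3),
      stringsAsFactors = FALSE)
  }
  out <- list(atoms = do.call(rbind, c(rows, make.row.names = FALSE)),
              source_path = NA_character_, model_index = 1L)
  class(out) <- "condock_receptor"
  out
}

# anchor point of the planted pocket: just inside the wall, mid-height,
# at the angle of the first residue of the middle ring
pocket_anchor <- function(spec) {
  fr <- bundle_frames(spec$n_residues)
  mid_ring <- fr$n_rings %/% 2L
  idx <- mid_ring * BUNDLE$ring_size + 1L
  th <- fr$theta[min(idx, spec$n_residues)]
  r <- BUNDLE$radius - BUNDLE$anchor_inset
  c(r * cos(th), r * sin(th), fr$z[min(idx, spec$n_residues)])
}

# pocket membership: the round(fraction * n) residues whose CB lies
# nearest the pocket anchor
pocket_keys <- function(spec, receptor) {
  anchor <- pocket_anchor(spec)
  cb <- receptor$atoms[receptor$atoms$name == "CB", ]
  d <- sqrt((cb$x - anchor[1])^2 + (cb$y - anchor[2])^2 + (cb$z - anchor[3])^2)
  n_pocket <- max(1L, round(spec$pocket_fraction * spec$n_residues))
  cb$key[order(d)][seq_len(n_pocket)]
}

#' Simulate an alignment with planted per-column conservation
#'
#' Columns evolve independently: sequence 1 (`target`) keeps the
#' consensus everywhere; every other sequence keeps the consensus residue
#' of column `j` with probability `1 - mutation_rate * (1 - levels[j])`
#' and otherwise mutates to one of the 19 other residues uniformly. The
#' expected fraction of sequences retaining the consensus therefore
#' tracks the planted level, and the recovered column conservation score
#' should rank-correlate with `levels`.
#'
#' @param levels Numeric vector of planted conservation levels in
#'   `[0, 1]`, one per column.
#' @param n_seq Number of sequences (>= 2), including the target.
#' @param seed Integer seed.
#' @param mutation_rate Scale in `[0, 1]`, see [scenario_spec()].
#' @param consensus Optional consensus sequence (character vector, one
#'   letter per column); default all-alanine.
#' @return A `condock_alignment`; sequence 1 is `target`.
#' @export
simulate_alignment <- function(levels, n_seq, seed, mutation_rate = 1.0,
                               consensus = NULL) {
  stopifnot(all(levels >= 0 & levels <= 1), n_seq >= 2L)
  ncol <- length(levels)
  consensus <- consensus %||% rep("A", ncol)
  stopifnot(length(consensus) == ncol)
  with_seed(seed, {
    seqs <- character(n_seq)
    seqs[1] <- paste(consensus, collapse = "")
    keep_p <- 1 - mutation_rate * (1 - levels)
    others <- lapply(consensus, function(a) setdiff(AA20, a))
    for (s in 2:n_seq) {
      ch <- consensus
      mut <- runif(ncol) > keep_p
      if (any(mut))
        ch[mut] <- vapply(which(mut), function(j)
          sample(others[[j]], 1L), "")
      seqs[s] <- paste(ch, collapse = "")
    }
    make_alignment_object(c("target", sprintf("seq%03d", seq_len(n_seq - 1L))),
                          seqs)
  })
}

#' Generate the alignment and grades table of a scenario
#'
#' Pocket columns get the spec's pocket conservation level, all others
#' the background level; the alignment is simulated with
#' [simulate_alignment()] and the grades are `round(9 * level)` per
#' column -- the integer 0-9 grade convention of ConSurf-style tables.
#'
#' @param spec A [scenario_spec()].
#' @param receptor The matching receptor from [make_receptor()].
#' @return List with `alignment` (a `condock_alignment`), `grades` (a
#'   `position_scores` table usable exactly like an imported grades
#'   file), and `levels` (the planted per-column levels).
#' @export
make_alignment_and_grades <- function(spec, receptor) {
  stopifnot(inherits(spec, "scenario_spec"))
  pk <- pocket_keys(spec, receptor)
  res <- receptor_residues(receptor)
  levels <- ifelse(res$key %in% pk, spec$pocket_conservation,
                   spec$background_conservation)
  aln <- simulate_alignment(levels, spec$n_msa_sequences,
                            seed = spec$seed + 1L,
                            mutation_rate = spec$mutation_rate,
                            consensus = receptor_sequence(receptor))
  grades <- position_scores(pos = seq_along(levels),
                            aa = receptor_sequence(receptor),
                            score = round(9 * levels) / 9,
                            provenance = "consurf_grades",
                            grade = as.integer(round(9 * levels)))
  list(alignment = aln, grades = grades, levels = levels)
}

# rigid 8-heavy-atom toy ligand: cube corners, side 2 * ligand_half
ligand_template <- function() {
  h <- BUNDLE$ligand_half
  corners <- as.matrix(expand.grid(x = c(-h, h), y = c(-h, h), z = c(-h, h)))
  dimnames(corners) <- NULL
  corners
}

place_ligand <- function(center, pose_id, energy) {
  xyz <- sweep(ligand_template(), 2L, center, "+")
  ligand_pose(pose_id,
              data.frame(element = "C", x = round(xyz[, 1], 3),
                         y = round(xyz[, 2], 3), z = round(xyz[, 3], 3),
                         stringsAsFactors = FALSE),
              energy)
}

#' Generate the pose set of a scenario
#'
#' One true pose of a rigid 8-heavy-atom toy ligand centered in the
#' planted pocket, plus `n_decoys` decoys at random non-pocket surface
#' patches. Decoy energies are drawn from a normal distribution (mean
#' -1500, sd 100, the magnitude regime of SwissDock FullFitness values);
#' the true pose's energy is set at the spec's percentile of the decoy
#' energies. Generated sites are validated: the true pose's contact site
#' is non-empty and lies within the pocket, every decoy site is non-empty
#' and overlaps the pocket by < 20% of its residues.
#'
#' @param spec A [scenario_spec()].
#' @param receptor The matching receptor.
#' @return List with `poses` (cluster ids `c0.e0`, `c1.e0`, ... in a
#'   seeded random order so the true pose's id is not positional),
#'   `reference` (the true pose, re-labelled `reference`), and `truth`
#'   (the true pose's id).
#' @export
make_poses <- function(spec, receptor) {
  stopifnot(inherits(spec, "scenario_spec"))
  pk <- pocket_keys(spec, receptor)
  anchor <- pocket_anchor(spec)
  fr <- bundle_frames(spec$n_residues)
  r_anchor <- BUNDLE$radius - BUNDLE$anchor_inset

  with_seed(spec$seed + 2L, {
    true_raw <- place_ligand(anchor, "true", 0)
    tsite <- binding_site_residues(receptor, true_raw)
    if (tsite$n == 0L || !all(tsite$keys %in% pk))
      stop("internal geometry failure: true-pose site not inside the pocket")

    centers <- vector("list", spec$n_decoys)
    for (j in seq_len(spec$n_decoys)) {
      placed <- FALSE
      for (try in 1:200) {
        phi <- runif(1, 0, 2 * pi)
        ring <- sample.int(fr$n_rings, 1L) - 1L
        ctr <- c(r_anchor * cos(phi), r_anchor * sin(phi), ring * BUNDLE$rise)
        s <- binding_site_residues(receptor, place_ligand(ctr, "d", 0))
        if (s$n >= 1L && length(intersect(s$keys, pk)) / s$n < 0.2) {
          centers[[j]] <- ctr
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place decoy ", j,
             " without pocket overlap after 200 tries")
    }

    decoy_en <- round(rnorm(spec$n_decoys, mean = -1500, sd = 100), 4)
    p <- spec$true_energy_percentile
    true_en <- if (p <= 0) min(decoy_en) - 25
               else if (p >= 1) max(decoy_en) + 25
               else round(quantile(decoy_en, p, names = FALSE), 4)
    # an exact tie with a decoy would make the energy ranking ambiguous
    while (true_en %in% decoy_en) true_en <- true_en + 0.0001

    all_centers <- c(list(anchor), centers)
    all_en <- c(true_en, decoy_en)
    ord <- sample.int(length(all_centers))
    ids <- sprintf("c%d.e0", seq_along(all_centers) - 1L)
    poses <- lapply(seq_along(ord), function(k)
      place_ligand(all_centers[[ord[k]]], ids[k], all_en[ord[k]]))
    truth <- ids[which(ord == 1L)]
    list(poses = poses,
         reference = place_ligand(anchor, "reference", true_en),
         truth = truth)
  })
}

#' Generate a complete synthetic scenario
#'
#' @param spec A [scenario_spec()].
#' @return A `condock_scenario`: list with `spec`, `receptor`, `poses`,
#'   `reference`, `alignment`, `grades`, `levels`, `pocket` (residue
#'   keys) and `truth` (true pose id).
#' @export
make_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  receptor <- make_receptor(spec)
  ag <- make_alignment_and_grades(spec, receptor)
  ps <- make_poses(spec, receptor)
  out <- list(spec = spec, receptor = receptor, poses = ps$poses,
              reference = ps$reference, alignment = ag$alignment,
              grades = ag$grades, levels = ag$levels,
              pocket = pocket_keys(spec, receptor), truth = ps$truth)
  class(out) <- "condock_scenario"
  out
}

#' Conservation profile of a scenario's planted grades
#'
#' Maps the scenario's grades table onto its receptor -- the same path an
#' imported ConSurf-style table takes.
#'
#' @param scenario A `condock_scenario`.
#' @return A `conservation_profile`.
#' @export
scenario_profile <- function(scenario) {
  map_profile_to_structure(scenario$grades, scenario$receptor)
}

#' @export
print.condock_scenario <- function(x, ...) {
  cat("synthetic scenario (seed ", x$spec$seed, "): ",
      x$spec$n_residues, " residues, ", length(x$poses), " poses (truth '",
      x$truth, "'), ", length(x$alignment$ids), "-sequence alignment\n",
      sep = "")
  invisible(x)
}

#' Write a scenario to disk in the package's own exchange formats
#'
#' Emits `receptor.pdb`, the pose set in both dialects
#' (`poses_swissdock.pdb`; `poses_models.pdb` + `poses_energies.tsv`),
#' `alignment.fasta`, `grades.txt`, `reference.pdb`, `truth.json` and a
#' `manifest.json` recording the full spec, so the scenario can be
#' regenerated byte-identically from the manifest alone.
#'
#' @param scenario A `condock_scenario`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths (the manifest).
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "condock_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(name) file.path(dir, name)
  write_receptor_pdb(scenario$receptor, f("receptor.pdb"))
  write_poses_swissdock(scenario$poses, f("poses_swissdock.pdb"))
  write_poses_multimodel(scenario$poses, f("poses_models.pdb"),
                         f("poses_energies.tsv"))
  write_fasta(scenario$alignment$ids, scenario$alignment$seqs,
              f("alignment.fasta"))
  g <- scenario$grades
  writeLines(c("# pos aa grade", sprintf("%d %s %d", g$pos, g$aa, g$grade)),
             f("grades.txt"))
  write_pose_pdb(scenario$reference, f("reference.pdb"))
  jsonlite::write_json(list(truth = scenario$truth), f("truth.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(list(spec = unclass(scenario$spec)),
                       f("manifest.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(receptor = f("receptor.pdb"),
             poses_swissdock = f("poses_swissdock.pdb"),
             poses_models = f("poses_models.pdb"),
             poses_energies = f("poses_energies.tsv"),
             alignment = f("alignment.fasta"), grades = f("grades.txt"),
             reference = f("reference.pdb"), truth = f("truth.json"),
             manifest = f("manifest.json"))
  invisible(paths)
}

#' Regenerate a scenario from a written manifest
#'
#' @param path Path to a `manifest.json` written by [write_scenario()].
#' @return A `condock_scenario` identical to the one that was written.
#' @export
scenario_from_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  make_scenario(do.call(scenario_spec, as.list(m$spec)))
}
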