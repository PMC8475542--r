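# Benchmarking: center-of-mass distance between predicted and reference
# ligand positions, and residue-set overlap between binding sites.

# IUPAC 2021 standard atomic weights for elements common in ligands.
ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904, B = 10.81,
  Se = 78.971, Na = 22.990, K = 39.098, Mg = 24.305, Ca = 40.078,
  Fe = 55.845, Zn = 65.38, Cu = 63.546, Mn = 54.938
)

#' Center of mass of a ligand pose
#'
#' @param pose A [ligand_pose()].
#' @param weighting `"mass"` (default) weights atoms by standard atomic
#'   masses; `"geometric"` is the unweighted centroid. The two agree
#'   exactly for homo-elemental ligands.
#' @return Numeric length-3 vector (x, y, z) in Angstrom.
#' @export
center_of_mass <- function(pose, weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  xyz <- unname(pose_coords(pose))
  if (weighting == "geometric") return(colMeans(xyz))
  el <- normalize_element(pose$atoms$element)
  m <- ATOMIC_MASSES[el]
  if (any(is.na(m)))
    stop("no atomic mass for element(s): ",
         paste(unique(el[is.na(m)]), collapse = ", "),
         "; use weighting = \"geometric\" or extend the mass table")
  unname(colSums(xyz * m) / sum(m))
}

#' Center-of-mass distance between two ligand placements
#'
#' The benchmark distance for binding-site prediction: the Euclidean
#' distance between the centers of mass of a predicted and a reference
#' ligand position. Unlike RMSD it requires no atom matching, so the two
#' poses may have different atom counts or even be different molecules --
#' appropriate when the question is *where* the ligand binds rather than
#' its precise pose.
#'
#' @param predicted,reference [ligand_pose()] objects.
#' @param weighting Passed to [center_of_mass()].
#' @return Distance in Angstrom (>= 0).
#' @export
com_distance <- function(predicted, reference,
                         weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  sqrt(sum((center_of_mass(predicted, weighting) -
              center_of_mass(reference, weighting))^2))
}

#' Matched-atom RMSD (optional diagnostic)
#'
#' Plain coordinate RMSD over atoms in order; both poses must have the
#' same atom count. No symmetry or graph matching is attempted -- the
#' center-of-mass distance is the benchmark of record here; RMSD is only
#' a convenience diagnostic for identically-ordered poses.
#'
#' @param a,b [ligand_pose()] objects with equal atom counts.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(a, b) {
  xa <- pose_coords(a); xb <- pose_coords(b)
  if (nrow(xa) != nrow(xb))
    stop("pose_rmsd needs equal atom counts (", nrow(xa), " vs ", nrow(xb),
         "); use com_distance() for unmatched poses")
  sqrt(mean(rowSums((xa - xb)^2)))
}

#' Residue-set overlap between two binding sites
#'
#' @param predicted,reference `binding_site` objects (or plain character
#'   vectors of residue keys) from the same structure.
#' @return List with `jaccard` (|intersection| / |union|; `NA` when both
#'   sites are empty), `shared` (character vector), `n_predicted`,
#'   `n_reference`.
#' @export
compare_sites <- function(predicted, reference) {
  keys <- function(s) if (inherits(s, "binding_site")) s$keys else as.character(s)
  a <- unique(keys(predicted)); b <- unique(keys(reference))
  u <- union(a, b)
  shared <- intersect(a, b)
  jac <- if (length(u) == 0L) {
    message("both sites empty: overlap undefined")
    NA_real_
  } else length(shared) / length(u)
  list(jaccard = jac, shared = shared,
       n_predicted = length(a), n_reference = length(b))
}

#' Evaluate a pose ranking against a reference ligand position
#'
#' For every ranked pose, computes the center-of-mass distance to the
#' reference ligand and the Jaccard overlap between the pose's binding
#' site and the reference ligand's own site (derived with the same
#' contact cutoff, so the two sites are commensurable). A prediction is
#' flagged successful when its COM distance is at or below
#' `success_threshold` (default 4 Angstrom; predictions a few Angstrom
#' off still identify the right pocket, >10 Angstrom off are failures).
#'
#' @param ranking A `condock_ranking` from [rank_poses()].
#' @param reference_pose The reference [ligand_pose()] (e.g. the
#'   crystallographic ligand position).
#' @param structure The `condock_receptor` used for the ranking.
#' @param profile Optional `conservation_profile`; when given, the
#'   reference site's conservation score is reported in the summary.
#' @param cutoff Contact cutoff for the reference site, default 3.5.
#' @param success_threshold Success cutoff on the COM distance (Angstrom).
#' @param weighting COM weighting, see [center_of_mass()].
#' @return A `site_evaluation`: list with `per_pose` (data frame:
#'   `pose_id`, `rank`, `com_distance`, `jaccard`, `success`), `rank1`
#'   (list: `pose_id`, `com_distance`, `jaccard`, `success`,
#'   `reference_site_n`, `reference_site_conservation`),
#'   `success_threshold`, `weighting`.
#' @export
evaluate_prediction <- function(ranking, reference_pose, structure,
                                profile = NULL, cutoff = 3.5,
                                success_threshold = 4.0,
                                weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(ranking, "condock_ranking"),
            inherits(reference_pose, "ligand_pose"))
  if (nrow(reference_pose$atoms) == 0L) stop("empty reference pose")
  stopifnot(success_threshold > 0)
  ref_site <- binding_site_residues(structure, reference_pose, profile, cutoff)
  pred <- ranking$predictions
  dist <- vapply(pred$pose_id, function(id)
    com_distance(ranking$poses[[id]], reference_pose, weighting), 0)
  jac <- vapply(pred$pose_id, function(id)
    compare_sites(ranking$sites[[id]], ref_site)$jaccard, 0)
  per_pose <- data.frame(pose_id = pred$pose_id, rank = pred$rank,
                         com_distance = unname(dist), jaccard = unname(jac),
                         success = unname(dist) <= success_threshold,
                         stringsAsFactors = FALSE)
  ref_cons <- NA_real_
  if (!is.null(profile) && length(ref_site$conservation))
    ref_cons <- conservation_score(ref_site)
  rank1 <- list(pose_id = per_pose$pose_id[1L],
                com_distance = per_pose$com_distance[1L],
                jaccard = per_pose$jaccard[1L],
                success = per_pose$success[1L],
                reference_site_n = ref_site$n,
                reference_site_conservation = ref_cons)
  out <- list(per_pose = per_pose, rank1 = rank1,
              success_threshold = success_threshold, weighting = weighting)
  class(out) <- "site_evaluation"
  out
}

#' @export
print.site_evaluation <- function(x, ...) {
  cat("site evaluation (threshold ", x$success_threshold, " A, ",
      x$weighting, "-weighted COM)\n", sep = "")
  cat(sprintf("  rank-1 pose '%s': COM distance %.2f A, jaccard %s, %s\n",
              x$rank1$pose_id, x$rank1$com_distance,
              ifelse(is.na(x$rank1$jaccard), "NA",
                     sprintf("%.2f", x$rank1$jaccard)),
              if (isTRUE(x$rank1$success)) "SUCCESS" else "failure"))
  invisible(x)
}

#' Write an evaluation report as TSV (+ JSON summary)
#'
#' @param evaluation A `site_evaluation`.
#' @param path Output TSV path.
#' @param json_path Optional JSON summary path.
#' @param meta Optional `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(evaluation, path, json_path = NULL,
                                    meta = NULL) {
  pp <- evaluation$per_pose
  df <- data.frame(pose_id = pp$pose_id, rank = pp$rank,
                   com_distance = sprintf("%.4f", pp$com_distance),
                   jaccard = ifelse(is.na(pp$jaccard), "NA",
                                    sprintf("%.4f", pp$jaccard)),
                   success = pp$success)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(meta, con)
  writeLines(paste(names(df), collapse = "\t"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(rank1 = evaluation$rank1,
           success_threshold = evaluation$success_threshold,
           weighting = evaluation$weighting),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
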