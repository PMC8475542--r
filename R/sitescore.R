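# Core scoring: contact-based binding sites, mean site conservation,
# the combined conservation x energy score, and pose ranking.

#' Binding-site residues of a docked pose
#'
#' The binding site of a pose is the set of receptor residues having at
#' least one heavy atom within `cutoff` Angstrom (inclusive, Euclidean)
#' of at least one ligand heavy atom. The default cutoff is 3.5 Angstrom.
#' An empty site is a valid result (the pose touches no residue) and is
#' flagged rather than raised as an error.
#'
#' @param structure A `condock_receptor`.
#' @param pose A [ligand_pose()].
#' @param profile Optional `conservation_profile`; when given, the site
#'   carries each residue's conservation value (residues with no profile
#'   entry are listed in `$missing`).
#' @param cutoff Contact distance in Angstrom (> 0), default 3.5.
#' @return A `binding_site`: list with `keys` (residue keys in structure
#'   order), `n`, `conservation` (named numeric, possibly with gaps) and
#'   `missing` (keys lacking a conservation value).
#' @export
binding_site_residues <- function(structure, pose, profile = NULL,
                                  cutoff = 3.5) {
  stopifnot(inherits(structure, "condock_receptor"),
            inherits(pose, "ligand_pose"))
  if (!(is.numeric(cutoff) && length(cutoff) == 1L && cutoff > 0))
    stop("cutoff must be a single positive number (Angstrom)")
  rec <- receptor_coords(structure)
  lig <- pose_coords(pose)
  d2min <- min_dist2_to_set(rec, lig)
  contact_keys <- unique(structure$atoms$key[d2min <= cutoff^2])
  cons <- NULL
  missing <- character(0)
  if (!is.null(profile)) {
    stopifnot(inherits(profile, "conservation_profile"))
    v <- profile$values[contact_keys]
    names(v) <- contact_keys
    missing <- contact_keys[is.na(v)]
    cons <- v[!is.na(v)]
  }
  out <- list(keys = contact_keys, n = length(contact_keys),
              conservation = cons, missing = missing,
              pose_id = pose$pose_id, cutoff = cutoff)
  class(out) <- "binding_site"
  out
}

#' @export
print.binding_site <- function(x, ...) {
  cat("binding site (pose '", x$pose_id, "', cutoff ", x$cutoff, " A): ",
      x$n, " residue(s)\n", sep = "")
  if (x$n) cat(" ", paste(x$keys, collapse = " "), "\n")
  invisible(x)
}

#' Conservation Score of a binding site
#'
#' The arithmetic mean of the per-residue conservation values over the
#' `n` residues of the site: `(1/n) * sum(c_k)`. This is the
#' "Conservation Score" half of the combined scoring scheme.
#'
#' @param site A `binding_site` built with a conservation profile.
#' @param na_policy What to do when a site residue has no conservation
#'   value: `"omit"` (default) drops it from the mean and reports it via
#'   a message; `"strict"` raises an error.
#' @return Mean conservation in `[0, 1]`.
#' @export
conservation_score <- function(site, na_policy = c("omit", "strict")) {
  na_policy <- match.arg(na_policy)
  stopifnot(inherits(site, "binding_site"))
  if (site$n == 0L)
    stop("empty binding site: conservation score undefined for pose '",
         site$pose_id, "'")
  if (is.null(site$conservation))
    stop("binding site carries no conservation values; ",
         "pass a profile to binding_site_residues()")
  if (length(site$missing)) {
    if (na_policy == "strict")
      stop("site residue(s) without conservation value: ",
           paste(site$missing, collapse = ", "))
    message("pose '", site$pose_id, "': ", length(site$missing),
            " site residue(s) lack a conservation value and are omitted ",
            "from the mean")
  }
  if (length(site$conservation) == 0L)
    stop("no site residue of pose '", site$pose_id,
         "' has a conservation value")
  mean(site$conservation)
}

#' Combined conservation x energy score
#'
#' The exact product of the Conservation Score and the Energy Score; no
#' clamping or rescaling. The energy score is a modified free energy, so
#' the most negative product marks the most probable binding site. A
#' positive energy inverts that ordering for the pose, hence a warning.
#'
#' @param conservation Conservation Score in `[0, 1]` (vectorized).
#' @param energy Energy Score (finite; vectorized).
#' @return `conservation * energy`.
#' @examples
#' condock_score(0.5, -100)  # -50
#' @export
condock_score <- function(conservation, energy) {
  if (!all(is.finite(conservation)) || !all(is.finite(energy)))
    stop("conservation and energy must be finite")
  if (any(conservation < 0 | conservation > 1))
    stop("conservation must lie in [0, 1]")
  if (any(energy > 0))
    warning("positive energy score(s): the product ordering assumes ",
            "negative (favorable) energies")
  conservation * energy
}

#' Rank docked poses by the combined score
#'
#' For each pose: extract the binding site at `cutoff`, average its
#' conservation, multiply by the pose's energy score, and rank all
#' scoreable poses by ascending combined score (most negative first).
#' Exact ties are broken by ascending energy score, then pose id. Poses
#' with an empty site, or whose site has no conservation value at all,
#' are excluded from the ranking and listed with a reason code. The
#' rank-1 pose's site is the predicted binding site.
#'
#' @param structure A `condock_receptor`.
#' @param poses List of [ligand_pose()] objects.
#' @param profile A `conservation_profile` mapped onto `structure`.
#' @param cutoff Contact cutoff in Angstrom, default 3.5.
#' @param na_policy Missing-conservation policy, see [conservation_score()].
#' @return A `condock_ranking`: list with `predictions` (data frame:
#'   `pose_id`, `energy_score`, `conservation_score`, `condock_score`,
#'   `rank`, `n_site`, `site_residues`), `sites` (named list of
#'   `binding_site`s), `unranked` (data frame `pose_id`, `reason`),
#'   `poses` (named list of the input poses) and `cutoff`.
#' @export
rank_poses <- function(structure, poses, profile, cutoff = 3.5,
                       na_policy = "omit") {
  stopifnot(length(poses) > 0L)
  ids <- vapply(poses, `[[`, "", "pose_id")
  if (anyDuplicated(ids))
    stop("duplicate pose ids: ", paste(unique(ids[duplicated(ids)]),
                                       collapse = ", "))
  names(poses) <- ids
  sites <- lapply(poses, function(p)
    binding_site_residues(structure, p, profile, cutoff))
  rows <- list()
  unranked <- list()
  for (id in ids) {
    s <- sites[[id]]
    if (s$n == 0L) {
      unranked[[id]] <- "empty_site"
      next
    }
    if (length(s$conservation) == 0L) {
      unranked[[id]] <- "no_conservation_values"
      next
    }
    cons <- conservation_score(s, na_policy)
    en <- poses[[id]]$energy_score
    rows[[id]] <- data.frame(pose_id = id, energy_score = en,
                             conservation_score = cons,
                             condock_score = condock_score(cons, en),
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("zero scoreable poses: every pose has an empty or unscoreable ",
         "binding site at cutoff ", cutoff, " A")
  pred <- do.call(rbind, rows)
  ord <- order(pred$condock_score, pred$energy_score, pred$pose_id,
               method = "radix")
  pred <- pred[ord, , drop = FALSE]
  pred$rank <- seq_len(nrow(pred))
  pred$n_site <- vapply(pred$pose_id, function(id) sites[[id]]$n, 1L)
  pred$site_residues <- vapply(pred$pose_id, function(id)
    paste(sites[[id]]$keys, collapse = ";"), "")
  rownames(pred) <- NULL
  unranked_df <- if (length(unranked))
    data.frame(pose_id = names(unranked), reason = unlist(unranked),
               row.names = NULL, stringsAsFactors = FALSE)
  else data.frame(pose_id = character(0), reason = character(0))
  out <- list(predictions = pred, sites = sites, unranked = unranked_df,
              poses = poses, cutoff = cutoff)
  class(out) <- "condock_ranking"
  out
}

#' @export
print.condock_ranking <- function(x, ...) {
  cat("condock ranking: ", nrow(x$predictions), " ranked pose(s), ",
      nrow(x$unranked), " unranked (cutoff ", x$cutoff, " A)\n", sep = "")
  print(head(x$predictions[, c("pose_id", "energy_score",
                               "conservation_score", "condock_score",
                               "rank", "n_site")], 10))
  invisible(x)
}

#' Predicted binding site of a ranking (the rank-1 pose's site)
#'
#' @param ranking A `condock_ranking`.
#' @return The rank-1 pose's `binding_site`.
#' @export
predicted_site <- function(ranking) {
  stopifnot(inherits(ranking, "condock_ranking"))
  ranking$sites[[ranking$predictions$pose_id[1L]]]
}

#' Write a ranking as a tab-separated table
#'
#' @param ranking A `condock_ranking`.
#' @param path Output path.
#' @param meta Optional character vector of `#`-prefixed header lines to
#'   prepend (e.g. provenance comments).
#' @return `path`, invisibly.
#' @export
write_ranked_tsv <- function(ranking, path, meta = NULL) {
  pred <- ranking$predictions
  num <- function(v) sprintf("%.6f", v)
  df <- data.frame(pose_id = pred$pose_id,
                   energy_score = num(pred$energy_score),
                   conservation_score = num(pred$conservation_score),
                   condock_score = num(pred$condock_score),
                   rank = pred$rank, n_site_residues = pred$n_site,
                   site_residues = pred$site_residues)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(meta, con)
  writeLines(paste(names(df), collapse = "\t"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
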