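#' Ligand-receptor contact fingerprints (LRCF)
#'
#' A docked pose touches a receptor atom when any ligand atom (hydrogens
#' included) lies within the distance threshold — 2.5 Angstrom inclusive
#' by default. Per scoring channel (`LD` for a LibDock-style score, `CD`
#' for a CDOCKER-style interaction energy) the top-scoring pose of each
#' ligand contributes one binary fingerprint row; columns are named
#' `RES_<num>_<atomname>^<channel>`.
#'
#' @name lrcf
NULL

#' Scored docking pose
#'
#' @param ligand_id,pose_id identifiers.
#' @param coords per-atom 3D coordinates (n x 3, Angstrom).
#' @param scores named numeric vector with any of the channels `LD`, `CD`.
#' @export
scored_pose <- function(ligand_id, pose_id, coords, scores) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, all(is.finite(coords)))
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop("pose '", pose_id, "' of ligand '", ligand_id,
                            "' has no score")
  structure(list(ligand_id = ligand_id, pose_id = pose_id,
                 coords = coords, scores = scores), class = "ScoredPose")
}

#' Contact-fingerprint settings
#'
#' @param threshold contact distance threshold in Angstrom (inclusive).
#' @param higher_is_better named logical per channel; both scoring
#'   channels default to "higher score wins".
#' @export
contact_settings <- function(threshold = 2.5,
                             higher_is_better = c(LD = TRUE, CD = TRUE)) {
  stopifnot(threshold > 0)
  list(threshold = threshold, higher_is_better = higher_is_better)
}

#' Top-scoring pose of a ligand for one channel
#'
#' Argmax of the channel score (argmin when the channel is configured
#' lower-is-better); ties broken by lexicographic `pose_id`.
#'
#' @param poses list of [scored_pose()]s for one ligand.
#' @param channel "LD" or "CD".
#' @param settings a [contact_settings()].
#' @export
select_top_pose <- function(poses, channel, settings = contact_settings()) {
  has <- vapply(poses, function(p) channel %in% names(p$scores), logical(1))
  if (!any(has)) {
    lig <- if (length(poses)) poses[[1]]$ligand_id else "<empty>"
    stop("ligand '", lig, "' has no pose scored on channel ", channel)
  }
  poses <- poses[has]
  sc <- vapply(poses, function(p) p$scores[[channel]], numeric(1))
  if (!isTRUE(settings$higher_is_better[[channel]])) sc <- -sc
  ids <- vapply(poses, `[[`, "", "pose_id")
  poses[[order(-sc, ids)[1L]]]
}

#' Receptor atoms contacted by a pose
#'
#' All-atom Euclidean distances; a receptor atom is contacted when at
#' least one ligand atom sits at distance <= threshold.
#'
#' @param receptor a `ReceptorStructure`.
#' @param pose a [scored_pose()].
#' @inheritParams select_top_pose
#' @param restrict_keys optional key subset (e.g. [binding_site_atoms()]
#'   output) limiting contact-eligible receptor atoms.
#' @return Character vector of contacted receptor atom keys (unsuffixed).
#' @export
contact_bits <- function(receptor, pose, settings = contact_settings(),
                         restrict_keys = NULL) {
  rec <- receptor
  if (!is.null(restrict_keys)) rec <- rec[rec$key %in% restrict_keys, ]
  if (!nrow(rec)) return(character())
  rxyz <- cbind(rec$x, rec$y, rec$z)
  lxyz <- pose$coords
  th2 <- settings$threshold^2
  hit <- logical(nrow(rec))
  for (i in seq_len(nrow(lxyz))) {
    d2 <- rowSums(sweep(rxyz, 2, lxyz[i, ])^2)
    hit <- hit | d2 <= th2
    if (all(hit)) break
  }
  rec$key[hit]
}

#' Build the binary LRCF matrix over a compound set
#'
#' For each channel the top pose per ligand is selected and its contact
#' set computed (once, when both channels pick the same pose). Columns
#' are the union of contacted atoms across ligands, suffixed `^LD`/`^CD`
#' and ordered channel, residue number, atom name.
#'
#' @param receptor a `ReceptorStructure`.
#' @param pose_sets named list (by ligand id) of lists of
#'   [scored_pose()]s.
#' @inheritParams select_top_pose
#' @param channels channels to emit (default both).
#' @param restrict_keys optional contact-eligible key subset.
#' @return data.frame: `compound_id` first column, then 0/1 columns.
#' @export
build_lrcf_matrix <- function(receptor, pose_sets,
                              settings = contact_settings(),
                              channels = c("LD", "CD"),
                              restrict_keys = NULL) {
  ids <- names(pose_sets)
  if (is.null(ids)) stop("pose_sets must be a named list (ligand ids)")
  per_lig <- lapply(ids, function(lig) {
    poses <- pose_sets[[lig]]
    sel <- lapply(channels, function(ch)
      select_top_pose(poses, ch, settings))
    names(sel) <- channels
    bits <- list(); cache <- list()
    for (ch in channels) {
      pid <- sel[[ch]]$pose_id
      if (is.null(cache[[pid]]))
        cache[[pid]] <- contact_bits(receptor, sel[[ch]], settings,
                                     restrict_keys)
      bits[[ch]] <- cache[[pid]]
    }
    bits
  })
  names(per_lig) <- ids
  cols <- character()
  for (ch in channels) {
    keys <- sort(unique(unlist(lapply(per_lig, `[[`, ch))))
    if (length(keys)) {
      resnum <- as.integer(sub("^[A-Z0-9]+_([0-9]+)[A-Za-z]?_.*$", "\\1", keys))
      atom <- sub("^.*_", "", keys)
      keys <- keys[order(resnum, atom)]
      cols <- c(cols, paste0(keys, "^", ch))
    }
  }
  mat <- matrix(0L, nrow = length(ids), ncol = length(cols),
                dimnames = list(ids, cols))
  for (lig in ids)
    for (ch in channels) {
      hit <- paste0(per_lig[[lig]][[ch]], "^", ch)
      mat[lig, intersect(hit, cols)] <- 1L
    }
  out <- data.frame(compound_id = ids, mat, check.names = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Read scored poses from SDF + score table
#'
#' Poses live in a multi-record SDF whose records carry `ligand_id` and
#' `pose_id` data fields (record title is used as `ligand_id` fallback);
#' scores come from a TSV with columns `ligand_id`, `pose_id`, `LD`, `CD`
#' (empty cell = channel absent).
#'
#' @param sdf_path,scores_path file paths.
#' @return Named list of pose lists, ready for [build_lrcf_matrix()].
#' @export
read_pose_sets <- function(sdf_path, scores_path) {
  scores <- utils::read.table(scores_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  mols <- read_sdf(sdf_path, merge_conformers = FALSE)
  out <- list()
  for (m in mols) {
    props <- attr(m, "sdf_props")
    lig <- if (!is.null(props$ligand_id)) props$ligand_id else m$id
    pid <- if (!is.null(props$pose_id)) props$pose_id else
      as.character(length(out[[lig]]) + 1L)
    row <- scores[scores$ligand_id == lig & scores$pose_id == pid, ]
    if (!nrow(row)) stop("no score row for ligand '", lig, "' pose '", pid, "'")
    sc <- c(LD = suppressWarnings(as.numeric(row$LD[1])),
            CD = suppressWarnings(as.numeric(row$CD[1])))
    out[[lig]] <- c(out[[lig]],
                    list(scored_pose(lig, pid, m$conformers[[1]]$coords, sc)))
  }
  out
}
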