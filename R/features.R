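#' Perceive chemical features on a conformer
#'
#' Applies a documented, configurable rule table to locate the four
#' classic pharmacophoric feature kinds on a 3D conformer:
#'
#' * `HBA` — N or O carrying at least one lone pair and no positive formal
#'   charge; projection point placed `hba_proj` (1.9) Angstrom along the
#'   lone-pair bisector (the direction opposite the mean of bond vectors).
#' * `HBD` — each O-H / N-H hydrogen; origin at the heavy atom, projection
#'   at the hydrogen position. Hydrogens must be explicit atoms with
#'   coordinates (see [add_hydrogens()]).
#' * `RingArom` — each fully aromatic SSSR ring; origin at the ring
#'   centroid, projection `rarom_proj` (2.0) Angstrom along the ring
#'   normal (normal direction fixed by ascending atom order, so output is
#'   deterministic).
#' * `Hbic` — centroid of each connected group of carbon/halogen atoms
#'   none of which touches a charged atom or an atom bonded to two or more
#'   heteroatoms; aromatic ring centroids are added unless they duplicate
#'   a group centroid.
#'
#' @param mol a `MoleculeRecord`.
#' @param conformer_index which conformer to use (1-based).
#' @param rules optional rule table from [feature_rules()].
#' @return A list of `ChemicalFeature` objects, each with fields `kind`,
#'   `origin`, `projection` (NULL for Hbic) and `source_atoms`; ordered by
#'   kind then source atoms, so repeated calls are bit-identical.
#' @export
perceive_features <- function(mol, conformer_index = 1L,
                              rules = feature_rules()) {
  if (conformer_index < 1L || conformer_index > length(mol$conformers))
    stop("molecule '", mol$id, "' has no conformer ", conformer_index)
  xyz <- mol$conformers[[conformer_index]]$coords
  el <- mol$atoms$element
  chg <- mol$atoms$charge
  adj <- .adjacency(mol)
  feats <- list()
  add <- function(kind, origin, projection, src) {
    feats[[length(feats) + 1L]] <<- structure(
      list(kind = kind, origin = as.numeric(origin),
           projection = if (is.null(projection)) NULL else as.numeric(projection),
           source_atoms = sort(as.integer(src))),
      class = "ChemicalFeature")
  }
  hetero <- el %in% c("N", "O", "S", "P")

  ## HBA
  for (i in which(el %in% c("N", "O"))) {
    if (chg[i] > 0L) next
    nb <- adj[[i]]
    bond_orders <- vapply(nb, function(j) {
      k <- which((mol$bonds$from == i & mol$bonds$to == j) |
                 (mol$bonds$to == i & mol$bonds$from == j))[1L]
      if (mol$bonds$aromatic[k]) 1.5 else as.numeric(mol$bonds$order[k])
    }, numeric(1))
    val <- sum(bond_orders) + .h_count_implicit(mol, i)
    lone_pairs <- if (el[i] == "O") 3 - ceiling(val) + 1 else 4 - ceiling(val)
    # O: 2 lone pairs at valence 2; N: 1 at valence 3, 0 when quaternary
    if (el[i] == "O") lone_pairs <- max(0, 2 - max(0, ceiling(val) - 2))
    if (lone_pairs < 1) next
    dir <- .lone_pair_dir(xyz, i, nb)
    add("HBA", xyz[i, ], xyz[i, ] + rules$hba_proj * dir, i)
  }

  ## HBD
  for (i in which(el %in% c("N", "O"))) {
    for (j in adj[[i]]) {
      if (el[j] == "H")
        add("HBD", xyz[i, ], xyz[j, ], c(i, j))
    }
  }

  ## RingArom
  rings <- .sssr(mol)
  arom_centroids <- list()
  for (ring in rings) {
    if (!all(mol$atoms$aromatic[ring])) next
    pts <- xyz[ring[order(ring)], , drop = FALSE]
    cen <- colMeans(pts)
    nrm <- .ring_normal(pts)
    add("RingArom", cen, cen + rules$rarom_proj * nrm, ring)
    arom_centroids[[length(arom_centroids) + 1L]] <- cen
  }

  ## Hbic
  cand <- which(el %in% c("C", "F", "Cl", "Br", "I"))
  ok <- vapply(cand, function(i) {
    for (j in adj[[i]]) {
      if (chg[j] != 0L) return(FALSE)
      n_het <- sum(hetero[adj[[j]]])
      if (n_het >= 2L) return(FALSE)
    }
    TRUE
  }, logical(1))
  cand <- cand[ok]
  if (length(cand)) {
    groups <- .components_within(cand, mol$bonds)
    for (g in groups) {
      cen <- colMeans(xyz[g, , drop = FALSE])
      add("Hbic", cen, NULL, g)
    }
    for (k in seq_along(arom_centroids)) {
      cen <- arom_centroids[[k]]
      dup <- any(vapply(feats, function(f)
        f$kind == "Hbic" && sqrt(sum((f$origin - cen)^2)) < 0.5, logical(1)))
      if (!dup) add("Hbic", cen, NULL, integer())
    }
  } else {
    for (cen in arom_centroids) add("Hbic", cen, NULL, integer())
  }

  kinds <- vapply(feats, `[[`, "", "kind")
  srck <- vapply(feats, function(f)
    paste(sprintf("%05d", f$source_atoms), collapse = ","), "")
  ord <- order(match(kinds, c("HBA", "HBD", "Hbic", "RingArom")), srck)
  feats[ord]
}

#' @param hba_proj HBA projection distance in Angstrom.
#' @param rarom_proj aromatic-ring projection distance in Angstrom.
#' @rdname perceive_features
#' @export
feature_rules <- function(hba_proj = 1.9, rarom_proj = 2.0) {
  list(hba_proj = hba_proj, rarom_proj = rarom_proj)
}

#' @export
print.ChemicalFeature <- function(x, ...) {
  cat(sprintf("<%s at (%.2f, %.2f, %.2f)%s>\n", x$kind,
              x$origin[1], x$origin[2], x$origin[3],
              if (is.null(x$projection)) "" else " +proj"))
  invisible(x)
}

.h_count_implicit <- function(mol, i) {
  if ("hcount" %in% names(mol$atoms)) mol$atoms$hcount[i] else 0L
}

# direction opposite the mean of unit bond vectors; +z for isolated atoms
.lone_pair_dir <- function(xyz, i, nb) {
  if (!length(nb)) return(c(0, 0, 1))
  vs <- sapply(nb, function(j) {
    v <- xyz[j, ] - xyz[i, ]
    v / sqrt(sum(v^2))
  })
  m <- -rowMeans(matrix(vs, nrow = 3))
  len <- sqrt(sum(m^2))
  if (len < 1e-8) return(c(0, 0, 1))  # linear environment: arbitrary axis
  m / len
}

# unit normal of best plane through ring points (SVD), sign fixed so the
# first nonzero component is positive — deterministic across runs
.ring_normal <- function(pts) {
  cen <- colMeans(pts)
  sv <- svd(sweep(pts, 2, cen))
  nrm <- sv$v[, 3]
  nz <- which(abs(nrm) > 1e-10)[1L]
  if (length(nz) && nrm[nz] < 0) nrm <- -nrm
  nrm
}

# connected components of the induced subgraph on `keep` atom indices
.components_within <- function(keep, bonds) {
  idx <- match(keep, keep)
  comp <- seq_along(keep)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  for (i in seq_len(nrow(bonds))) {
    a <- match(bonds$from[i], keep); b <- match(bonds$to[i], keep)
    if (!is.na(a) && !is.na(b)) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) comp[ra] <- rb
    }
  }
  roots <- vapply(seq_along(keep), find, integer(1))
  lapply(unique(roots), function(r) keep[roots == r])
}
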