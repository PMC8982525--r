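#' Molecule, conformer and activity records
#'
#' A `MoleculeRecord` is a light molecular container: a labelled graph
#' (atoms + bonds), zero or more 3D conformers, and an optional activity
#' record. It is deliberately minimal — enough chemistry for pharmacophore
#' perception and the topological/geometric descriptors this package
#' computes, not a general cheminformatics toolkit.
#'
#' @param id character scalar identifying the compound.
#' @param atoms data.frame with columns `element` (symbol), `charge`
#'   (integer formal charge) and `aromatic` (logical).
#' @param bonds data.frame with columns `from`, `to` (1-based atom
#'   indices), `order` (1, 2 or 3) and `aromatic` (logical). May have zero
#'   rows for a single-atom molecule.
#' @param conformers list of [conformer()] objects.
#' @param activity optional [activity_record()].
#' @return An object of class `MoleculeRecord`.
#' @examples
#' m <- mol_from_smiles("CCO", id = "ethanol")
#' n_atoms(m)
#' @export
molecule_record <- function(id, atoms, bonds, conformers = list(),
                            activity = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) == 0L) {
    bonds <- data.frame(from = integer(), to = integer(),
                        order = integer(), aromatic = logical())
  }
  need_a <- c("element", "charge", "aromatic")
  need_b <- c("from", "to", "order", "aromatic")
  if (!all(need_a %in% names(atoms)))
    stop("atoms must have columns: ", paste(need_a, collapse = ", "))
  if (!all(need_b %in% names(bonds)))
    stop("bonds must have columns: ", paste(need_b, collapse = ", "))
  na <- nrow(atoms)
  if (nrow(bonds) > 0L) {
    idx <- c(bonds$from, bonds$to)
    if (any(idx < 1L | idx > na))
      stop("bond references non-existent atom in molecule '", id, "'")
  }
  if (na > 1L && !.graph_connected(na, bonds))
    stop("molecular graph of '", id, "' is not connected")
  for (cf in conformers) {
    if (!inherits(cf, "Conformer")) stop("conformers must be Conformer objects")
    if (nrow(cf$coords) != na)
      stop("conformer atom count (", nrow(cf$coords),
           ") differs from graph atom count (", na, ") in '", id, "'")
  }
  structure(list(id = id, atoms = atoms, bonds = bonds,
                 conformers = conformers, activity = activity),
            class = "MoleculeRecord")
}

#' @param coords numeric matrix, one row per atom, columns x/y/z in
#'   Angstrom.
#' @param energy optional relative conformer energy in kcal/mol.
#' @rdname molecule_record
#' @export
conformer <- function(coords, energy = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("conformer coordinates must be n x 3")
  if (!all(is.finite(coords))) stop("conformer coordinates must be finite")
  if (!is.null(energy)) stopifnot(is.numeric(energy), length(energy) == 1L)
  structure(list(coords = coords, energy = energy), class = "Conformer")
}

#' @param ic50 half-maximal inhibitory concentration in molar; must be
#'   positive.
#' @rdname molecule_record
#' @export
activity_record <- function(ic50) {
  stopifnot(is.numeric(ic50), length(ic50) == 1L)
  if (!is.finite(ic50) || ic50 <= 0) stop("ic50 must be positive and finite")
  structure(list(ic50 = ic50, log_inv_ic50 = log_inverse_ic50(ic50)),
            class = "ActivityRecord")
}

#' @export
print.MoleculeRecord <- function(x, ...) {
  cat(sprintf("<MoleculeRecord '%s': %d atoms, %d bonds, %d conformer(s)%s>\n",
              x$id, nrow(x$atoms), nrow(x$bonds), length(x$conformers),
              if (is.null(x$activity)) "" else
                sprintf(", pIC50 %.3f", x$activity$log_inv_ic50)))
  invisible(x)
}

#' @rdname molecule_record
#' @param mol a `MoleculeRecord`.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

.graph_connected <- function(n, bonds) {
  if (n <= 1L) return(TRUE)
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$from[i]; b <- bonds$to[i]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

# adjacency list over all atoms
.adjacency <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  b <- mol$bonds
  for (i in seq_len(nrow(b))) {
    adj[[b$from[i]]] <- c(adj[[b$from[i]]], b$to[i])
    adj[[b$to[i]]]   <- c(adj[[b$to[i]]], b$from[i])
  }
  adj
}

# Hydrogen-suppressed view: indices of heavy atoms, their pairwise bonds
# re-indexed 1..n_heavy, and heavy-atom degrees.
.heavy_graph <- function(mol) {
  heavy <- which(mol$atoms$element != "H")
  map <- integer(n_atoms(mol)); map[heavy] <- seq_along(heavy)
  b <- mol$bonds
  keep <- b$from %in% heavy & b$to %in% heavy
  hb <- data.frame(from = map[b$from[keep]], to = map[b$to[keep]])
  deg <- integer(length(heavy))
  if (nrow(hb)) {
    t1 <- tabulate(hb$from, nbins = length(heavy))
    t2 <- tabulate(hb$to, nbins = length(heavy))
    deg <- t1 + t2
  }
  list(heavy = heavy, bonds = hb, degree = deg)
}

# number of hydrogens (explicit atoms + implicit count column if present)
.h_count <- function(mol, i) {
  adj <- .adjacency(mol)
  expl <- sum(mol$atoms$element[adj[[i]]] == "H")
  impl <- if ("hcount" %in% names(mol$atoms)) mol$atoms$hcount[i] else 0L
  expl + impl
}

#' Filter a conformer ensemble by relative energy and size
#'
#' Conformer generators typically emit ensembles pruned to a maximum
#' relative energy above the minimum and a hard count cap (defaults: 20
#' kcal/mol and 250 conformers). Energies are metadata here; conformers
#' without an energy are always retained (they count toward the cap).
#'
#' @param mol a `MoleculeRecord`.
#' @param max_energy relative energy window in kcal/mol.
#' @param max_conformers ensemble size cap.
#' @return The molecule with a (possibly) reduced conformer list.
#' @export
filter_conformers <- function(mol, max_energy = 20, max_conformers = 250L) {
  en <- vapply(mol$conformers, function(cf)
    if (is.null(cf$energy)) NA_real_ else cf$energy, numeric(1))
  keep <- rep(TRUE, length(en))
  if (any(!is.na(en))) {
    rel <- en - min(en, na.rm = TRUE)
    keep <- is.na(rel) | rel <= max_energy
  }
  kept <- mol$conformers[keep]
  if (length(kept) > max_conformers) kept <- kept[seq_len(max_conformers)]
  mol$conformers <- kept
  mol
}
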