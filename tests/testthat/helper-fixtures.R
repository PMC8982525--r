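# Shared fixture builders. Everything is constructed in code; no binary
# data is read from disk.

# water with explicit hydrogens and a bent 3D geometry
fix_water <- function() {
  m <- add_hydrogens(mol_from_smiles("O", id = "water"))
  m$conformers <- list(conformer(matrix(
    c(0, 0, 0,
      0.7572, 0.5865, 0,
      -0.7572, 0.5865, 0), 3, 3, byrow = TRUE)))
  m
}

# benzene as a regular hexagon in the XY plane (C-C 1.39 A)
fix_benzene <- function() {
  m <- mol_from_smiles("c1ccccc1", id = "benzene")
  ang <- (0:5) * pi / 3
  m$conformers <- list(conformer(cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)))
  m
}

fix_ethane <- function() {
  m <- mol_from_smiles("CC", id = "ethane")
  m$conformers <- list(conformer(matrix(c(0, 0, 0, 1.54, 0, 0),
                                        2, 3, byrow = TRUE)))
  m
}

# random-geometry alkane used by permutation/rotation property tests
fix_random_mol <- function(seed, n = 7L) {
  set.seed(seed)
  atoms <- data.frame(element = rep("C", n), charge = 0L, aromatic = FALSE)
  bonds <- data.frame(from = 1:(n - 1), to = 2:n, order = 1L,
                      aromatic = FALSE)
  # add one extra branch bond when possible (keeps the graph connected)
  if (n >= 5L)
    bonds <- rbind(bonds, data.frame(from = 2L, to = n, order = 1L,
                                     aromatic = FALSE))
  molecule_record(sprintf("rand%02d", seed), atoms, bonds,
                  list(conformer(matrix(rnorm(3 * n, sd = 2), n, 3))))
}

# apply a random atom relabelling to a molecule (graph + conformers)
permute_molecule <- function(mol, seed) {
  set.seed(seed)
  n <- n_atoms(mol)
  perm <- sample.int(n)          # perm[old] = new index
  atoms <- mol$atoms[order(perm), , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds
  bonds$from <- perm[bonds$from]
  bonds$to <- perm[bonds$to]
  cfs <- lapply(mol$conformers, function(cf)
    conformer(cf$coords[order(perm), , drop = FALSE], cf$energy))
  molecule_record(mol$id, atoms, bonds, cfs, mol$activity)
}

rigid_motion <- function(seed) {
  set.seed(seed)
  axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  list(R = R, t = runif(3, -8, 8))
}

move_molecule <- function(mol, motion) {
  mol$conformers <- lapply(mol$conformers, function(cf)
    conformer(sweep(cf$coords %*% motion$R, 2, motion$t, "+"), cf$energy))
  mol
}

# small synthetic receptor grid: n atoms on a line, 3 A apart
fix_line_receptor <- function(n = 10L) {
  df <- data.frame(chain = "A", resname = "GLY", resnum = seq_len(n) + 10L,
                   icode = "", atom = "CA", element = "C",
                   x = 3 * seq_len(n), y = 0, z = 0,
                   stringsAsFactors = FALSE)
  df$key <- receptor_atom_key(df$resname, df$resnum, df$atom)
  class(df) <- c("ReceptorStructure", "data.frame")
  df
}

shipped_phore <- function(which) {
  path <- system.file("extdata", paste0("hypo_", which, ".phore"),
                      package = "phoreqsar")
  stopifnot(nzchar(path))
  path
}

# point features placed exactly (bypassing perception) for engine tests
pf <- function(kind, origin, tol = 1.6, proj = NULL, ptol = NULL)
  phore_feature(kind, origin, tol, proj, ptol)

lf <- function(kind, origin, proj = NULL)
  structure(list(kind = kind, origin = as.numeric(origin),
                 projection = if (is.null(proj)) NULL else as.numeric(proj),
                 source_atoms = integer()), class = "ChemicalFeature")
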