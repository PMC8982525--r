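#' Topological and geometric molecular descriptors
#'
#' The descriptor set mirrors what shows up in kinase-inhibitor QSAR
#' equations: Kier-Hall connectivity and shape indices, SSSR ring counts,
#' a charge-based dipole component, principal moments of inertia and a
#' shadow-area fraction. All topological indices work on the
#' hydrogen-suppressed graph.
#'
#' @name descriptors
NULL

#' Second-order Kier-Hall connectivity index
#'
#' \eqn{^2\chi = \sum (\delta_i \delta_j \delta_k)^{-1/2}} over all simple
#' 3-heavy-atom paths, with \eqn{\delta} the heavy-atom degree.
#'
#' @param mol a `MoleculeRecord`.
#' @return Non-negative real; 0 when no 3-atom path exists.
#' @export
chi2_index <- function(mol) {
  hg <- .heavy_graph(mol)
  if (length(hg$heavy) == 0L) stop("molecule has no heavy atom")
  adj <- .adj_from(hg$bonds, length(hg$heavy))
  total <- 0
  for (j in seq_along(hg$heavy)) {
    nb <- adj[[j]]
    if (length(nb) < 2L) next
    prs <- utils::combn(nb, 2L)
    for (k in seq_len(ncol(prs))) {
      i <- prs[1L, k]; l <- prs[2L, k]
      total <- total + 1 / sqrt(hg$degree[i] * hg$degree[j] * hg$degree[l])
    }
  }
  total
}

#' Third-order Kier kappa shape index
#'
#' \eqn{^3\kappa = (A-1)(A-3)^2/P_3^2} for odd heavy-atom count A,
#' \eqn{(A-3)(A-2)^2/P_3^2} for even A, with \eqn{P_3} the number of
#' simple 3-bond (4-atom) paths; 0 when \eqn{P_3 = 0}.
#'
#' @inheritParams chi2_index
#' @export
kappa3_index <- function(mol) {
  hg <- .heavy_graph(mol)
  A <- length(hg$heavy)
  if (A == 0L) stop("molecule has no heavy atom")
  p3 <- .count_p3(hg)
  if (p3 == 0L) return(0)
  if (A %% 2L == 1L) (A - 1) * (A - 3)^2 / p3^2 else (A - 3) * (A - 2)^2 / p3^2
}

# number of simple length-3 paths i-j-k-l (each counted once)
.count_p3 <- function(hg) {
  adj <- .adj_from(hg$bonds, length(hg$heavy))
  count <- 0L
  for (e in seq_len(nrow(hg$bonds))) {
    j <- hg$bonds$from[e]; k <- hg$bonds$to[e]
    for (i in setdiff(adj[[j]], k))
      for (l in setdiff(adj[[k]], j))
        if (i != l) count <- count + 1L
  }
  count
}

.adj_from <- function(bonds, n) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    adj[[bonds$from[i]]] <- c(adj[[bonds$from[i]]], bonds$to[i])
    adj[[bonds$to[i]]] <- c(adj[[bonds$to[i]]], bonds$from[i])
  }
  adj
}

#' Count SSSR rings of a given size
#'
#' @inheritParams chi2_index
#' @param size ring size (>= 3).
#' @return Integer count of rings of exactly that size in the smallest
#'   set of smallest rings.
#' @export
ring_count <- function(mol, size) {
  stopifnot(size >= 3L)
  sum(lengths(.sssr(mol)) == size)
}

#' Dipole moment component from partial charges
#'
#' \eqn{\mu_{axis} = 4.80321 \sum_i q_i r_{i,axis}} with charges in e and
#' coordinates in Angstrom, giving debye.
#'
#' @param cf a [conformer()].
#' @param charges per-atom partial charges in elementary charge units.
#' @param axis one of "x", "y", "z".
#' @export
dipole_component <- function(cf, charges, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  if (length(charges) != nrow(cf$coords))
    stop("charge list length (", length(charges),
         ") differs from atom count (", nrow(cf$coords), ")")
  ax <- match(axis, c("x", "y", "z"))
  4.80321 * sum(charges * cf$coords[, ax])
}

#' Principal moment of inertia
#'
#' Eigenvalues of the inertia tensor about the centre of mass, ascending;
#' `axis_rank` 1 is the smallest moment.
#'
#' @param cf a [conformer()].
#' @param masses per-atom masses in amu.
#' @param axis_rank 1, 2 or 3.
#' @return Moment in amu A^2.
#' @export
principal_moment <- function(cf, masses, axis_rank = 1L) {
  stopifnot(axis_rank %in% 1:3, length(masses) == nrow(cf$coords))
  sort(.inertia_eigs(cf$coords, masses))[axis_rank]
}

.inertia_eigs <- function(xyz, masses) {
  com <- colSums(xyz * masses) / sum(masses)
  r <- sweep(xyz, 2, com)
  x <- r[, 1]; y <- r[, 2]; z <- r[, 3]
  I <- matrix(c(sum(masses * (y^2 + z^2)), -sum(masses * x * y), -sum(masses * x * z),
                -sum(masses * x * y), sum(masses * (x^2 + z^2)), -sum(masses * y * z),
                -sum(masses * x * z), -sum(masses * y * z), sum(masses * (x^2 + y^2))),
              3, 3)
  ev <- eigen(I, symmetric = TRUE)$values
  pmax(ev, 0)
}

#' Shadow area fraction in the XY plane
#'
#' The conformer is first rotated into its principal axes (largest moment
#' of unit-mass atoms along Z) so the value is orientation-free, then atom
#' disks (van der Waals radii) are projected onto XY and rasterised on a
#' grid. Returns the union area divided by the area of the tight bounding
#' rectangle of the projection; in (0, 1].
#'
#' @param cf a [conformer()].
#' @param vdw_radii per-atom radii in Angstrom.
#' @param grid_step raster step in Angstrom (default 0.05).
#' @param align rotate to principal axes first (default TRUE; FALSE is
#'   used by convergence tests on fixed orientations).
#' @export
shadow_xy_fraction <- function(cf, vdw_radii, grid_step = 0.05, align = TRUE) {
  stopifnot(grid_step > 0, length(vdw_radii) == nrow(cf$coords))
  xyz <- cf$coords
  if (align && nrow(xyz) > 1L) {
    com <- colMeans(xyz)
    r <- sweep(xyz, 2, com)
    ev <- eigen(crossprod(r), symmetric = TRUE)  # largest spread along X/Y
    # inertia largest -> Z means smallest coordinate spread along Z:
    # order eigenvectors by descending spread, mapped to (x, y, z)
    xyz <- r %*% ev$vectors[, order(ev$values, decreasing = TRUE)]
  }
  px <- xyz[, 1]; py <- xyz[, 2]
  x0 <- min(px - vdw_radii); x1 <- max(px + vdw_radii)
  y0 <- min(py - vdw_radii); y1 <- max(py + vdw_radii)
  if (x1 - x0 < grid_step || y1 - y0 < grid_step) return(1.0)
  gx <- seq(x0 + grid_step / 2, x1, by = grid_step)
  gy <- seq(y0 + grid_step / 2, y1, by = grid_step)
  covered <- matrix(FALSE, length(gx), length(gy))
  for (i in seq_len(nrow(xyz))) {
    dx2 <- (gx - px[i])^2
    dy2 <- (gy - py[i])^2
    covered <- covered | outer(dx2, dy2, "+") <= vdw_radii[i]^2
  }
  area <- sum(covered) * grid_step^2
  area / ((x1 - x0) * (y1 - y0))
}

#' log10(1 / IC50) with IC50 in molar (pIC50)
#'
#' @param ic50 positive concentration(s) in molar.
#' @export
log_inverse_ic50 <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("ic50 must be positive and finite")
  log10(1 / ic50)
}

# Pauling-ish van der Waals radii (Angstrom) for shadow projections
.vdw_radius <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                 P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92)
# atomic masses (amu)
.atomic_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
                  P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904,
                  B = 10.81)

#' Compute the standard descriptor table for a set of molecules
#'
#' Produces the named descriptor columns used by the packaged QSAR
#' equations: `CHI_2`, `Kappa_3`, `Num_Rings5`, `Num_Rings6`, `Dipole_Y`,
#' `PMI_x`, `Shadow_XYfrac`. Geometry descriptors use the first conformer
#' and are `NA`-free only when a conformer is present; `Dipole_Y` needs a
#' per-compound charge vector (zero charges assumed when absent).
#'
#' @param mols list of `MoleculeRecord`s.
#' @param charges optional named list of per-atom partial charge vectors.
#' @param grid_step raster step for `Shadow_XYfrac`.
#' @return data.frame with `compound_id` first column.
#' @export
descriptor_table <- function(mols, charges = NULL, grid_step = 0.05) {
  rows <- lapply(mols, function(m) {
    cf <- if (length(m$conformers)) m$conformers[[1L]] else NULL
    q <- if (!is.null(charges) && !is.null(charges[[m$id]])) charges[[m$id]]
         else rep(0, n_atoms(m))
    vr <- unname(.vdw_radius[m$atoms$element])
    ms <- unname(.atomic_mass[m$atoms$element])
    data.frame(
      compound_id = m$id,
      CHI_2 = chi2_index(m),
      Kappa_3 = kappa3_index(m),
      Num_Rings5 = ring_count(m, 5L),
      Num_Rings6 = ring_count(m, 6L),
      Dipole_Y = if (is.null(cf)) NA_real_ else dipole_component(cf, q, "y"),
      PMI_x = if (is.null(cf)) NA_real_ else principal_moment(cf, ms, 1L),
      Shadow_XYfrac = if (is.null(cf)) NA_real_ else
        shadow_xy_fraction(cf, vr, grid_step))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a TSV descriptor (or any compound) table
#'
#' Plain tab-separated tables with `compound_id` as the first column are
#' the interchange format between pipeline stages.
#'
#' @param df data.frame whose first column is `compound_id`.
#' @param path file path.
#' @export
write_compound_tsv <- function(df, path) {
  stopifnot(names(df)[1] == "compound_id")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_compound_tsv
#' @export
read_compound_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
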