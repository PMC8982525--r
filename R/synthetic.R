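#' Seeded synthetic-data generators
#'
#' Every input the pipeline consumes can be generated in code: a labelled
#' receptor pocket, ligands with plantable pharmacophore matches, scored
#' pose sets realising a chosen contact pattern, bioactivities from a
#' known sparse linear model, and a two-class set for ROC machinery. All
#' generators are pure functions of their configuration: a fixed seed
#' gives bit-identical output, and the caller's RNG stream is left
#' untouched.
#'
#' @param seed integer RNG seed.
#' @param n_compounds number of compounds.
#' @param noise_sd activity noise standard deviation in log units
#'   (default 0.1).
#' @param activity_range dynamic range of the planted activities in log
#'   units (default 2.2, matching the 2-2.5 log-cycle training-set
#'   convention).
#' @param true_support named numeric vector: descriptor name ->
#'   generating coefficient.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(seed = 1L, n_compounds = 40L, noise_sd = 0.1,
                       activity_range = 2.2, true_support = NULL) {
  structure(list(seed = as.integer(seed),
                 n_compounds = as.integer(n_compounds),
                 noise_sd = noise_sd, activity_range = activity_range,
                 true_support = true_support),
            class = "SimConfig")
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic receptor pocket
#'
#' Atoms are scattered on a concave hemispherical shell around the
#' origin (the "binding site" opens toward +z), grouped into named
#' residues of four backbone-style atoms, plus a few water oxygens. The
#' result is a `ReceptorStructure` interchangeable with [read_pdb()]
#' output.
#'
#' @param config a [sim_config()].
#' @param n_atoms total atom count (50-500 sensible; default 120).
#' @export
gen_pocket <- function(config = sim_config(), n_atoms = 120L) {
  stopifnot(n_atoms >= 8L)
  .with_seed(config$seed + 101L, {
    resnames <- c("LEU", "PHE", "LYS", "VAL", "ASP", "GLY", "SER", "ALA")
    atomnames <- c("N", "CA", "CB", "O")
    n_wat <- max(2L, n_atoms %/% 20L)
    n_prot <- n_atoms - n_wat
    rows <- vector("list", n_atoms)
    placed <- matrix(NA_real_, n_atoms, 3)
    for (i in seq_len(n_prot)) {
      res_i <- (i - 1L) %/% 4L
      # shell point: radius 8-11 A, z <= 3 (concave upper opening);
      # min 2 A spacing so planted contacts can be realised cleanly
      for (try in 1:200) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        if (u[3] >= 0.3) next
        r <- stats::runif(1, 8, 11)
        pos <- r * u
        prev <- placed[seq_len(i - 1L), , drop = FALSE]
        if (!nrow(prev) ||
            min(rowSums(sweep(prev, 2, pos)^2)) > 4) break
      }
      placed[i, ] <- r * u
      rows[[i]] <- data.frame(
        chain = "A", resname = resnames[res_i %% length(resnames) + 1L],
        resnum = res_i + 100L, icode = "",
        atom = atomnames[(i - 1L) %% 4L + 1L],
        element = substr(atomnames[(i - 1L) %% 4L + 1L], 1, 1),
        x = r * u[1], y = r * u[2], z = r * u[3])
    }
    for (j in seq_len(n_wat)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      r <- stats::runif(1, 9, 12)
      rows[[n_prot + j]] <- data.frame(
        chain = "W", resname = "HOH", resnum = 900L + j, icode = "",
        atom = "O", element = "O", x = r * u[1], y = r * u[2], z = r * u[3])
    }
    df <- do.call(rbind, rows)
    df$key <- receptor_atom_key(df$resname, df$resnum, df$atom, df$icode)
    class(df) <- c("ReceptorStructure", "data.frame")
    df
  })
}

#' Generate ligands with plantable pharmacophore matches
#'
#' A `match_fraction` subset are point-cloud constructs whose perceived
#' features reproduce every feature of `model` (HBA: an O with one
#' carbon neighbour oriented so the lone-pair projection points at the
#' model projection; HBD: an O-H with the hydrogen placed on the model
#' projection point; Hbic: an isolated carbon bridged through ether
#' oxygens; RingArom: a benzene hexagon centred on the feature,
#' perpendicular to the projection axis). Non-matching ligands are plain
#' alkane chains, guaranteed to lack the model's polar feature types.
#' Planted ligands are built directly in the model frame, then rigidly
#' rotated/translated (seeded), and their atoms are kept clear of the
#' model's exclusion spheres.
#'
#' @param config a [sim_config()].
#' @param model a [pharmacophore_model()].
#' @param match_fraction fraction of compounds planted as hits.
#' @return Named list of `MoleculeRecord`s (`LIG001`, ...).
#' @export
gen_ligands <- function(config, model, match_fraction = 0.5) {
  stopifnot(match_fraction >= 0, match_fraction <= 1)
  n <- config$n_compounds
  n_hit <- round(match_fraction * n)
  .with_seed(config$seed + 202L, {
    out <- list()
    for (i in seq_len(n)) {
      id <- sprintf("LIG%03d", i)
      mol <- if (i <= n_hit) .planted_ligand(id, model)
             else .decoy_ligand(id, n_carbons = sample(4:8, 1L))
      out[[id]] <- mol
    }
    out
  })
}

# point-cloud molecule reproducing every model feature, in model frame,
# then randomly rigidly moved (RNG stream of the caller)
.planted_ligand <- function(id, model) {
  atoms <- data.frame(element = character(), charge = integer(),
                      aromatic = logical())
  bonds <- data.frame(from = integer(), to = integer(),
                      order = integer(), aromatic = logical())
  xyz <- matrix(numeric(), 0, 3)
  anchors <- integer()          # one representative atom per feature group
  push_atom <- function(el, pos, aromatic = FALSE) {
    atoms <<- rbind(atoms, data.frame(element = el, charge = 0L,
                                      aromatic = aromatic))
    xyz <<- rbind(xyz, pos)
    nrow(atoms)
  }
  push_bond <- function(a, b, aromatic = FALSE) {
    bonds <<- rbind(bonds, data.frame(from = a, to = b, order = 1L,
                                      aromatic = aromatic))
  }
  excl <- model$exclusion_spheres
  # nudge a position well clear of every exclusion sphere (alignment
  # noise after superposition is well under the 1.2 A margin used here)
  clear_of_exclusions <- function(pos) {
    if (!nrow(excl)) return(pos)
    for (k in seq_len(nrow(excl))) {
      c0 <- c(excl$x[k], excl$y[k], excl$z[k])
      d <- sqrt(sum((pos - c0)^2))
      if (d < excl$radius[k] + 1.0)
        pos <- c0 + (pos - c0) / max(d, 1e-6) * (excl$radius[k] + 1.2)
    }
    pos
  }
  # bridges attach to these companion atoms, never to the feature-bearing
  # oxygen itself (extra bonds would tilt its lone-pair projection)
  for (f in model$features) {
    o <- f$origin
    u <- if (!is.null(f$projection)) {
      v <- f$projection - o; v / sqrt(sum(v^2))
    } else c(0, 0, 1)
    if (f$kind == "HBA") {
      a <- push_atom("O", o)
      b <- push_atom("C", clear_of_exclusions(o - 1.5 * u))
      push_bond(a, b)
      anchors <- c(anchors, b)
    } else if (f$kind == "HBD") {
      a <- push_atom("O", o)
      b <- push_atom("C", clear_of_exclusions(o - 1.4 * u))
      h <- push_atom("H", f$projection)
      push_bond(a, b); push_bond(a, h)
      anchors <- c(anchors, b)
    } else if (f$kind == "Hbic") {
      a <- push_atom("C", o)
      anchors <- c(anchors, a)
    } else {                      # RingArom: benzene hexagon centred on o
      perp1 <- .any_perp(u)
      perp2 <- c(u[2] * perp1[3] - u[3] * perp1[2],
                 u[3] * perp1[1] - u[1] * perp1[3],
                 u[1] * perp1[2] - u[2] * perp1[1])
      ring_idx <- integer()
      for (k in 0:5) {
        ang <- k * pi / 3
        pos <- o + 1.39 * (cos(ang) * perp1 + sin(ang) * perp2)
        ring_idx <- c(ring_idx, push_atom("C", pos, aromatic = TRUE))
      }
      for (k in seq_along(ring_idx))
        push_bond(ring_idx[k], ring_idx[k %% 6L + 1L], aromatic = TRUE)
      anchors <- c(anchors, ring_idx[1])
    }
  }
  # connect feature groups through ether-oxygen bridges so the graph is
  # one component without merging hydrophobic carbon groups
  if (length(anchors) > 1L) {
    for (k in seq_len(length(anchors) - 1L)) {
      a <- anchors[k]; b <- anchors[k + 1L]
      mid <- clear_of_exclusions((xyz[a, ] + xyz[b, ]) / 2 + c(0.3, 0.3, 0.3))
      br <- push_atom("O", mid)
      push_bond(a, br); push_bond(br, b)
    }
  }
  # random rigid motion so planted hits are not pre-aligned
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  ang <- stats::runif(1, 0, 2 * pi)
  R <- .rotation_about(axis, ang)
  shift <- stats::runif(3, -5, 5)
  moved <- sweep(xyz %*% R, 2, shift, "+")
  molecule_record(id, atoms, bonds, list(conformer(moved)))
}

.any_perp <- function(u) {
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- v - sum(v * u) * u
  w / sqrt(sum(w^2))
}

.rotation_about <- function(axis, theta) {
  a <- axis; c1 <- cos(theta); s1 <- sin(theta)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + s1 * K + (1 - c1) * (K %*% K)
}

# straight-chain alkane with explicit hydrogens omitted: no N/O and no
# aromatic ring, so any model with a polar or aromatic feature misses
.decoy_ligand <- function(id, n_carbons = 6L) {
  atoms <- data.frame(element = rep("C", n_carbons),
                      charge = 0L, aromatic = FALSE)
  bonds <- data.frame(from = seq_len(n_carbons - 1L),
                      to = 2:n_carbons, order = 1L, aromatic = FALSE)
  xyz <- cbind(1.5 * seq_len(n_carbons) +
                 stats::rnorm(n_carbons, 0, 0.05),
               stats::rnorm(n_carbons, 0, 0.3),
               stats::rnorm(n_carbons, 0, 0.3))
  molecule_record(id, atoms, bonds, list(conformer(xyz)))
}

#' Generate scored pose sets realising a planted contact pattern
#'
#' Per ligand, 3-10 poses with LD and CD scores. The top-scoring pose in
#' both channels places one ligand atom at a distance drawn in
#' [2.0, 2.4] Angstrom from each planted receptor contact atom; decoy
#' poses keep every atom more than 3 Angstrom from the whole receptor.
#' [build_lrcf_matrix()] on the output therefore reproduces exactly the
#' planted bit pattern.
#'
#' @param config a [sim_config()].
#' @param pocket a `ReceptorStructure` (e.g. [gen_pocket()]).
#' @param ligands named list of ligands ([gen_ligands()]).
#' @param contact_keys named list: ligand id -> character vector of
#'   receptor atom keys to realise (missing ids get zero contacts).
#' @return Named list of [scored_pose()] lists.
#' @export
gen_poses <- function(config, pocket, ligands, contact_keys = list()) {
  .with_seed(config$seed + 303L, {
    far <- c(0, 0, 60)               # comfortably outside the pocket shell
    out <- list()
    for (id in names(ligands)) {
      keys <- contact_keys[[id]]
      n_atoms_lig <- max(4L, n_atoms(ligands[[id]]), length(keys) + 1L)
      n_poses <- sample(3:10, 1L)
      poses <- vector("list", n_poses)
      top <- sample.int(n_poses, 1L)
      for (pi in seq_len(n_poses)) {
        if (pi == top && length(keys)) {
          rxyz <- cbind(pocket$x, pocket$y, pocket$z)
          pos <- matrix(NA_real_, n_atoms_lig, 3)
          for (k in seq_along(keys)) {
            row <- which(pocket$key == keys[k])
            if (!length(row)) stop("unknown receptor key: ", keys[k])
            ctr <- rxyz[row, ]
            # search directions until the placed atom touches only the
            # intended receptor atom (margin 2.6 A to everything else)
            d <- stats::runif(1, 2.0, 2.4)
            cand <- ctr - d * ctr / max(sqrt(sum(ctr^2)), 1e-6)
            for (try in 1:100) {
              dmin <- sqrt(min(rowSums(sweep(rxyz[-row, , drop = FALSE],
                                             2, cand)^2)))
              if (dmin > 2.6) break
              u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
              cand <- ctr + d * u
            }
            pos[k, ] <- cand
          }
          extra <- which(is.na(pos[, 1]))
          for (e in extra) {
            v <- stats::rnorm(3)
            pos[e, ] <- v / sqrt(sum(v^2)) * stats::runif(1, 0, 2.5)
          }
          coords <- pos
        } else {
          coords <- sweep(matrix(stats::rnorm(3 * n_atoms_lig, 0, 1.5),
                                 ncol = 3), 2, far, "+")
        }
        sc_base <- if (pi == top) c(LD = 100, CD = 50) else
          c(LD = stats::runif(1, 40, 80), CD = stats::runif(1, 10, 40))
        poses[[pi]] <- scored_pose(id, sprintf("p%02d", pi), coords, sc_base)
      }
      out[[id]] <- poses
    }
    out
  })
}

#' Generate activities from a known sparse linear model
#'
#' y = sum(coef * z-scored descriptor) + N(0, noise_sd), anchored at a
#' mean pIC50 of 7 (typical 100 nM potency scale) — the anchor is an
#' affine shift and does not affect support recovery. IC50s are
#' back-computed in molar.
#'
#' @param matrix a `DescriptorMatrix` or plain data.frame with
#'   `compound_id` first column.
#' @param config a [sim_config()] whose `true_support` names matrix
#'   columns.
#' @return data.frame: `compound_id`, `log_inv_ic50`, `ic50_M`.
#' @export
gen_activities <- function(matrix, config) {
  if (inherits(matrix, "DescriptorMatrix")) {
    vals <- matrix$values; ids <- matrix$ids
  } else {
    vals <- as.matrix(matrix[, -1, drop = FALSE]); ids <- matrix$compound_id
  }
  support <- config$true_support
  if (is.null(support)) stop("config$true_support is not set")
  missing <- setdiff(names(support), colnames(vals))
  if (length(missing))
    stop("unknown support column(s): ", paste(missing, collapse = ", "))
  .with_seed(config$seed + 404L, {
    y <- rep(0, nrow(vals))
    for (nm in names(support)) {
      x <- vals[, nm]
      sdx <- stats::sd(x)
      z <- if (sdx > 0) (x - mean(x)) / sdx else x * 0
      y <- y + support[[nm]] * z
    }
    # anchor the noiseless dynamic range at activity_range log cycles
    span <- diff(range(y))
    if (span > 0 && !is.null(config$activity_range))
      y <- y * config$activity_range / span
    y <- y + stats::rnorm(length(y), 0, config$noise_sd) + 7
    data.frame(compound_id = ids, log_inv_ic50 = y, ic50_M = 10^(-y),
               stringsAsFactors = FALSE)
  })
}

#' Generate a two-class set for ROC machinery
#'
#' Latent screening scores are N(separation, 1) for actives and N(0, 1)
#' for inactives; IC50s are drawn inside the active (<= 400 nM) and
#' inactive (> 3000 nM) bands so threshold classification recovers the
#' class sizes exactly.
#'
#' @param config a [sim_config()].
#' @param separation mean score shift of actives (>= 0).
#' @param n_active,n_inactive class sizes (defaults 383 / 270).
#' @return List with `table` (compound_id, ic50_M, label) and `scores`
#'   (named numeric).
#' @export
gen_roc_set <- function(config, separation = 1, n_active = 383L,
                        n_inactive = 270L) {
  stopifnot(separation >= 0)
  .with_seed(config$seed + 505L, {
    ids <- sprintf("ROC%04d", seq_len(n_active + n_inactive))
    label <- c(rep("active", n_active), rep("inactive", n_inactive))
    scores <- c(stats::rnorm(n_active, separation, 1),
                stats::rnorm(n_inactive, 0, 1))
    names(scores) <- ids
    ic50 <- c(10^stats::runif(n_active, -9, log10(400e-9)),
              10^stats::runif(n_inactive, log10(3001e-9), -4.5))
    list(table = data.frame(compound_id = ids, ic50_M = ic50, label = label,
                            stringsAsFactors = FALSE),
         scores = scores)
  })
}
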