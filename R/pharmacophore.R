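#' Pharmacophore models
#'
#' A pharmacophore model is a set of typed feature spheres (hydrogen-bond
#' acceptor/donor, hydrophobic, ring-aromatic) in a common 3D frame, each
#' with an origin point and tolerance radius and — for vectored features —
#' a projected point with its own tolerance. A per-model weight `W` scales
#' fit values, and exclusion spheres mark receptor-occupied space that a
#' mapped ligand may not enter.
#'
#' @param name model name.
#' @param weight positive weight `W` applied in the fit-value formula.
#' @param features list of feature specs from [phore_feature()].
#' @param exclusion_spheres data.frame with columns `x`, `y`, `z`,
#'   `radius` (possibly empty).
#' @return An object of class `PharmacophoreModel`.
#' @export
pharmacophore_model <- function(name, weight, features,
                                exclusion_spheres = NULL) {
  stopifnot(length(features) >= 1L, is.numeric(weight), weight > 0)
  if (is.null(exclusion_spheres))
    exclusion_spheres <- data.frame(x = numeric(), y = numeric(),
                                    z = numeric(), radius = numeric())
  if (nrow(exclusion_spheres) && any(exclusion_spheres$radius <= 0))
    stop("exclusion sphere radii must be positive")
  for (f in features)
    if (!inherits(f, "PhoreFeature")) stop("features must come from phore_feature()")
  structure(list(name = name, weight = weight, features = features,
                 exclusion_spheres = exclusion_spheres),
            class = "PharmacophoreModel")
}

#' @param kind one of "HBA", "HBD", "Hbic", "RingArom".
#' @param origin feature sphere centre (length-3 numeric, Angstrom).
#' @param origin_tol sphere radius (tolerance) in Angstrom.
#' @param projection optional projected-point centre.
#' @param projection_tol tolerance of the projected point; required iff
#'   `projection` is given.
#' @rdname pharmacophore_model
#' @export
phore_feature <- function(kind, origin, origin_tol,
                          projection = NULL, projection_tol = NULL) {
  kind <- match.arg(kind, c("HBA", "HBD", "Hbic", "RingArom"))
  stopifnot(length(origin) == 3L, origin_tol > 0)
  if (xor(is.null(projection), is.null(projection_tol)))
    stop("projection and projection_tol must be supplied together")
  if (kind == "Hbic" && !is.null(projection))
    stop("Hbic features carry no projection point")
  if (!is.null(projection)) stopifnot(length(projection) == 3L,
                                      projection_tol > 0)
  structure(list(kind = kind, origin = as.numeric(origin),
                 origin_tol = origin_tol,
                 projection = if (is.null(projection)) NULL else as.numeric(projection),
                 projection_tol = projection_tol),
            class = "PhoreFeature")
}

#' @export
print.PharmacophoreModel <- function(x, ...) {
  cat(sprintf("<PharmacophoreModel '%s': W = %.2f, %d feature(s) [%s], %d exclusion sphere(s)>\n",
              x$name, x$weight, length(x$features),
              paste(vapply(x$features, `[[`, "", "kind"), collapse = ", "),
              nrow(x$exclusion_spheres)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# PHORE v1 text format
#
#   MODEL <name>
#   WEIGHT <w>
#   FEATURE <HBA|HBD|HBIC|RAROM> <x> <y> <z> <tol> [PROJ <x> <y> <z> <tol>]
#   EXCLUDE <x> <y> <z> <radius>
#   END
#
# Whitespace-delimited, '#' starts a comment, coordinates in Angstrom.
# ---------------------------------------------------------------------------

.kind_to_token <- c(HBA = "HBA", HBD = "HBD", Hbic = "HBIC", RingArom = "RAROM")
.token_to_kind <- c(HBA = "HBA", HBD = "HBD", HBIC = "Hbic", RAROM = "RingArom")

#' Read or write a pharmacophore model in PHORE text format
#'
#' @param path file path.
#' @return `read_pharmacophore()`: a [pharmacophore_model()].
#'   Round-tripping through `write_pharmacophore()` is identity to 1e-6
#'   Angstrom.
#' @export
read_pharmacophore <- function(path) {
  lines <- readLines(path, warn = FALSE)
  name <- NULL; weight <- 1.0; features <- list()
  excl <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                     radius = numeric())
  seen_end <- FALSE
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[ln])
    toks <- strsplit(trimws(raw), "\\s+")[[1]]
    if (!length(toks) || !nzchar(toks[1])) next
    bad <- function(msg) stop("PHORE parse error at line ", ln, " of '",
                              path, "': ", msg)
    switch(toks[1],
      MODEL = { if (length(toks) < 2L) bad("MODEL needs a name")
                name <- paste(toks[-1L], collapse = " ") },
      WEIGHT = { w <- suppressWarnings(as.numeric(toks[2]))
                 if (length(toks) != 2L || is.na(w)) bad("WEIGHT needs one number")
                 weight <- w },
      FEATURE = {
        if (length(toks) < 6L) bad("FEATURE needs kind + 4 numbers")
        kind <- .token_to_kind[[toks[2]]]
        if (is.null(kind)) bad(paste0("unknown feature kind '", toks[2], "'"))
        v <- suppressWarnings(as.numeric(toks[3:6]))
        if (any(is.na(v))) bad("non-numeric FEATURE fields")
        proj <- NULL; ptol <- NULL
        if (length(toks) > 6L) {
          if (toks[7] != "PROJ" || length(toks) != 11L)
            bad("trailing fields must be PROJ x y z tol")
          pv <- suppressWarnings(as.numeric(toks[8:11]))
          if (any(is.na(pv))) bad("non-numeric PROJ fields")
          proj <- pv[1:3]; ptol <- pv[4]
        }
        features[[length(features) + 1L]] <-
          phore_feature(kind, v[1:3], v[4], proj, ptol)
      },
      EXCLUDE = {
        v <- suppressWarnings(as.numeric(toks[2:5]))
        if (length(toks) != 5L || any(is.na(v))) bad("EXCLUDE needs 4 numbers")
        excl <- rbind(excl, data.frame(x = v[1], y = v[2], z = v[3],
                                       radius = v[4]))
      },
      END = { seen_end <- TRUE },
      bad(paste0("unknown directive '", toks[1], "'")))
  }
  if (is.null(name)) stop("PHORE file '", path, "' has no MODEL line")
  if (!length(features))
    stop("PHORE model '", name, "' has an empty FEATURE block")
  pharmacophore_model(name, weight, features, excl)
}

#' @param model a `PharmacophoreModel` (for the writer).
#' @rdname read_pharmacophore
#' @export
write_pharmacophore <- function(model, path) {
  lines <- c(sprintf("MODEL %s", model$name),
             sprintf("WEIGHT %.6f", model$weight))
  for (f in model$features) {
    base <- sprintf("FEATURE %s %.6f %.6f %.6f %.6f", .kind_to_token[[f$kind]],
                    f$origin[1], f$origin[2], f$origin[3], f$origin_tol)
    if (!is.null(f$projection))
      base <- paste(base, sprintf("PROJ %.6f %.6f %.6f %.6f",
                                  f$projection[1], f$projection[2],
                                  f$projection[3], f$projection_tol))
    lines <- c(lines, base)
  }
  e <- model$exclusion_spheres
  for (i in seq_len(nrow(e)))
    lines <- c(lines, sprintf("EXCLUDE %.6f %.6f %.6f %.6f",
                              e$x[i], e$y[i], e$z[i], e$radius[i]))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Mapping enumeration, superposition, fit values
# ---------------------------------------------------------------------------

#' Enumerate type-compatible feature assignments
#'
#' All injective assignments of model features to ligand features with
#' matching kinds, in deterministic order. With `require_all = TRUE` only
#' assignments covering every model feature are returned; otherwise every
#' non-empty subset of model features is considered.
#'
#' @param ligand_features list of features from [perceive_features()].
#' @param model a `PharmacophoreModel`.
#' @param require_all must every model feature be mapped?
#' @param cap maximum number of assignments explored (deterministic
#'   truncation; the bundled models have at most 4 features so the
#'   cap is never reached there).
#' @return List of integer matrices with columns `model` and `ligand`,
#'   one row per mapped pair.
#' @export
enumerate_mappings <- function(ligand_features, model, require_all = TRUE,
                               cap = 10000L) {
  mk <- vapply(model$features, `[[`, "", "kind")
  lk <- vapply(ligand_features, `[[`, "", "kind")
  nm <- length(mk)
  subsets <- if (require_all) list(seq_len(nm)) else {
    s <- list()
    for (size in nm:1)
      s <- c(s, utils::combn(nm, size, simplify = FALSE))
    s
  }
  out <- list()
  for (sub in subsets) {
    # candidate ligand features per model feature in this subset
    cands <- lapply(sub, function(mi) which(lk == mk[mi]))
    if (any(lengths(cands) == 0L)) next
    assign_rec <- function(pos, used, acc) {
      if (length(out) >= cap) return()
      if (pos > length(sub)) {
        out[[length(out) + 1L]] <<- cbind(model = sub, ligand = acc)
        return()
      }
      for (li in cands[[pos]]) {
        if (li %in% used) next
        assign_rec(pos + 1L, c(used, li), c(acc, li))
      }
    }
    assign_rec(1L, integer(), integer())
    if (length(out) >= cap) break
  }
  out
}

#' Kabsch rigid-body superposition
#'
#' Least-squares proper rotation (determinant +1; reflections rejected)
#' plus translation taking `moving` onto `reference`.
#'
#' @param moving,reference n x 3 coordinate matrices, matched rows.
#' @return List with `rotation` (3x3), `translation` (length 3) and
#'   `rmsd`; apply as `sweep(moving %*% rotation, 2, translation, "+")` or
#'   via [apply_transform()].
#' @export
superpose <- function(moving, reference) {
  moving <- as.matrix(moving); reference <- as.matrix(reference)
  if (!all(dim(moving) == dim(reference)))
    stop("point sets differ in size: ", nrow(moving), " vs ", nrow(reference))
  cm <- colMeans(moving); cr <- colMeans(reference)
  A <- sweep(moving, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)        # row-vector convention: y = x %*% t(R)? see below
  rot <- t(R)                         # so that  moved = A %*% rot  aligns to B
  moved <- A %*% rot
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  list(rotation = rot, translation = as.numeric(cr - cm %*% rot), rmsd = rmsd)
}

#' @param points n x 3 matrix (or length-3 vector) to transform.
#' @param tf transform from [superpose()].
#' @rdname superpose
#' @export
apply_transform <- function(points, tf) {
  v <- is.null(dim(points))
  pts <- if (v) matrix(points, 1, 3) else as.matrix(points)
  out <- sweep(pts %*% tf$rotation, 2, tf$translation, "+")
  if (v) as.numeric(out) else out
}

#' Fit value of a mapped pose
#'
#' The literal printed formula
#' \deqn{Fit = N_{mapped} \times W \times [1 - \sum (disp/tol)^2]}
#' where the sum runs over every mapped feature point — origin and, for
#' vectored features, projection. `per_feature_sum` instead accumulates
#' \eqn{\sum W (1 - (disp/tol)^2)} per feature (the product form can go
#' negative when many features map poorly).
#'
#' @param disps named list with elements `origin` and `projection`
#'   (numeric vectors of displacements per mapped feature; `projection`
#'   entries are `NA` for point features).
#' @param tols matching list of tolerances.
#' @param weight model weight `W`.
#' @param formula `"product"` (printed form) or `"per_feature_sum"`.
#' @return The fit value (unbounded below for `"product"`).
#' @export
fit_value <- function(disps, tols, weight, formula = c("product",
                                                       "per_feature_sum")) {
  formula <- match.arg(formula)
  n <- length(disps$origin)
  ratio2 <- (disps$origin / tols$origin)^2
  has_proj <- !is.na(disps$projection)
  proj2 <- ifelse(has_proj, (disps$projection / tols$projection)^2, 0)
  if (formula == "product")
    n * weight * (1 - sum(ratio2) - sum(proj2))
  else
    sum(weight * (1 - ratio2 - proj2))
}

#' Best fit of a molecule against a pharmacophore model
#'
#' Searches every conformer, every type-compatible feature assignment and
#' one Kabsch superposition per assignment (on all mapped origin +
#' projection points), keeping the mapping with the highest fit value
#' among those whose displacements all sit within their tolerances.
#'
#' @inheritParams enumerate_mappings
#' @param mol a `MoleculeRecord` with at least one conformer.
#' @param formula passed to [fit_value()].
#' @return `NULL` when no admissible mapping exists (the fit descriptor is
#'   then 0 by convention), else a list with `conformer`, `pairs`,
#'   `transform`, `disps`, `fit`.
#' @export
best_fit <- function(mol, model, require_all = FALSE,
                     formula = "product", cap = 10000L) {
  if (!length(mol$conformers))
    stop("molecule '", mol$id, "' has no conformer")
  best <- NULL
  for (ci in seq_along(mol$conformers)) {
    lf <- perceive_features(mol, ci)
    cand <- .best_fit_features(lf, model, require_all, formula, cap)
    if (!is.null(cand) && (is.null(best) || cand$fit > best$fit)) {
      best <- cand
      best$conformer <- ci
    }
  }
  best
}

# core search on an explicit ligand feature list (unit-testable directly)
#
# Ring-aromatic ligand projections have no intrinsic sign (a ring normal
# points out of either face), so for every mapping each mapped RingArom
# ligand feature is tried with its projection as perceived and mirrored
# through the origin, and the best variant wins.
.best_fit_features <- function(ligand_features, model, require_all,
                               formula = "product", cap = 10000L) {
  maps <- enumerate_mappings(ligand_features, model, require_all, cap)
  best <- NULL
  for (mp in maps) {
    ring_rows <- which(vapply(seq_len(nrow(mp)), function(r)
      ligand_features[[mp[r, 2]]]$kind == "RingArom" &&
        !is.null(ligand_features[[mp[r, 2]]]$projection), logical(1)))
    n_flip <- length(ring_rows)
    flip_sets <- if (n_flip == 0L) list(logical(0)) else
      lapply(seq_len(2^min(n_flip, 6L)) - 1L, function(code)
        as.logical(bitwAnd(bitwShiftR(code, seq_len(n_flip) - 1L), 1L)))
    for (flips in flip_sets) {
    mpts <- list(); lpts <- list()
    for (r in seq_len(nrow(mp))) {
      mf <- model$features[[mp[r, 1]]]
      lf <- ligand_features[[mp[r, 2]]]
      mpts[[length(mpts) + 1L]] <- mf$origin
      lpts[[length(lpts) + 1L]] <- lf$origin
      if (!is.null(mf$projection)) {
        if (is.null(lf$projection)) { mpts <- NULL; break }
        proj <- lf$projection
        fi <- match(r, ring_rows)
        if (!is.na(fi) && isTRUE(flips[fi]))
          proj <- 2 * lf$origin - proj
        mpts[[length(mpts) + 1L]] <- mf$projection
        lpts[[length(lpts) + 1L]] <- proj
      }
    }
    if (is.null(mpts)) next
    ref <- do.call(rbind, mpts)
    mov <- do.call(rbind, lpts)
    tf <- superpose(mov, ref)
    placed <- apply_transform(mov, tf)
    # per-feature displacements in the model frame
    disp_o <- numeric(nrow(mp)); disp_p <- rep(NA_real_, nrow(mp))
    tol_o <- numeric(nrow(mp)); tol_p <- rep(NA_real_, nrow(mp))
    row <- 1L; ok <- TRUE
    for (r in seq_len(nrow(mp))) {
      mf <- model$features[[mp[r, 1]]]
      disp_o[r] <- sqrt(sum((placed[row, ] - mf$origin)^2))
      tol_o[r] <- mf$origin_tol
      row <- row + 1L
      if (!is.null(mf$projection)) {
        disp_p[r] <- sqrt(sum((placed[row, ] - mf$projection)^2))
        tol_p[r] <- mf$projection_tol
        row <- row + 1L
      }
      if (disp_o[r] > tol_o[r] ||
          (!is.na(disp_p[r]) && disp_p[r] > tol_p[r])) { ok <- FALSE; break }
    }
    if (!ok) next
    fv <- fit_value(list(origin = disp_o, projection = disp_p),
                    list(origin = tol_o, projection = tol_p),
                    model$weight, formula)
    if (is.null(best) || fv > best$fit)
      best <- list(pairs = mp, transform = tf,
                   disps = list(origin = disp_o, projection = disp_p),
                   fit = fv)
    }
  }
  best
}

#' Fit-value descriptor for a compound set
#'
#' Vector of best-fit values against one model; molecules with no
#' admissible mapping get 0 so downstream matrices stay dense.
#'
#' @param mols list of `MoleculeRecord`s.
#' @inheritParams best_fit
#' @export
fit_descriptors <- function(mols, model, require_all = FALSE,
                            formula = "product") {
  vapply(mols, function(m) {
    bf <- best_fit(m, model, require_all, formula)
    if (is.null(bf)) 0 else bf$fit
  }, numeric(1))
}

#' Screen a molecule against a pharmacophore query
#'
#' A hit must (i) map every model feature within tolerance in some
#' conformer (best fit with `require_all`) and (ii) place no heavy atom
#' inside any exclusion sphere in the aligned pose.
#'
#' @inheritParams best_fit
#' @return List with `hit` (logical) and, when hit, `mapping`.
#' @export
screen_molecule <- function(mol, model, formula = "product") {
  bf <- best_fit(mol, model, require_all = TRUE, formula = formula)
  if (is.null(bf)) return(list(hit = FALSE))
  excl <- model$exclusion_spheres
  if (nrow(excl)) {
    heavy <- mol$atoms$element != "H"
    xyz <- apply_transform(mol$conformers[[bf$conformer]]$coords[heavy, ,
                                                                 drop = FALSE],
                           bf$transform)
    for (i in seq_len(nrow(excl))) {
      d <- sqrt(rowSums(sweep(xyz, 2, c(excl$x[i], excl$y[i], excl$z[i]))^2))
      if (any(d < excl$radius[i])) return(list(hit = FALSE))
    }
  }
  list(hit = TRUE, mapping = bf)
}

#' F statistic of fit values against bioactivities
#'
#' Simple linear regression of activity on fit value;
#' \eqn{F = r^2 (n-2) / (1-r^2)}, capped at 1e12 for collinear data.
#' Used to rank competing pharmacophore models.
#'
#' @param fit_values,activities equal-length numeric vectors (n >= 3).
#' @export
f_score <- function(fit_values, activities) {
  n <- length(fit_values)
  stopifnot(n == length(activities), n >= 3L)
  if (stats::sd(fit_values) == 0 || stats::sd(activities) == 0)
    stop("f_score requires nonzero variance in fit values and activities")
  r2 <- stats::cor(fit_values, activities)^2
  if (1 - r2 < 1e-12) return(1e12)
  min(r2 * (n - 2) / (1 - r2), 1e12)
}
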