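test_that("shipped pharmacophore fixtures parse with full fidelity", {
  m1 <- read_pharmacophore(shipped_phore("5-R2-08"))
  expect_equal(m1$name, "Hypo(5-R2-08)")
  expect_equal(m1$weight, 2.26)
  expect_equal(vapply(m1$features, `[[`, "", "kind"),
               c("HBA", "Hbic", "Hbic", "RingArom"))
  expect_equal(nrow(m1$exclusion_spheres), 3L)
  expect_equal(m1$features[[1]]$origin, c(5.60, -0.30, -0.002))
  expect_equal(m1$features[[1]]$origin_tol, 1.60)
  expect_equal(m1$features[[1]]$projection_tol, 2.20)
  expect_equal(m1$exclusion_spheres$radius, rep(0.6, 3))

  m2 <- read_pharmacophore(shipped_phore("6-R2-07"))
  expect_equal(m2$weight, 1.97)
  expect_equal(vapply(m2$features, `[[`, "", "kind"),
               c("HBA", "HBD", "Hbic", "RingArom"))
  expect_equal(nrow(m2$exclusion_spheres), 4L)

  m3 <- read_pharmacophore(shipped_phore("8-R3-08"))
  expect_equal(m3$weight, 2.18)
  expect_equal(nrow(m3$exclusion_spheres), 0L)
})

test_that("PHORE round-trip is bit-stable to 1e-6 A", {
  for (which in c("5-R2-08", "6-R2-07", "8-R3-08")) {
    m <- read_pharmacophore(shipped_phore(which))
    path <- withr::local_tempfile(fileext = ".phore")
    write_pharmacophore(m, path)
    back <- read_pharmacophore(path)
    expect_equal(back$name, m$name)
    expect_equal(back$weight, m$weight, tolerance = 1e-6)
    for (k in seq_along(m$features)) {
      expect_equal(back$features[[k]]$origin, m$features[[k]]$origin,
                   tolerance = 1e-6)
      if (!is.null(m$features[[k]]$projection))
        expect_equal(back$features[[k]]$projection,
                     m$features[[k]]$projection, tolerance = 1e-6)
    }
    expect_equal(back$exclusion_spheres, m$exclusion_spheres,
                 tolerance = 1e-6)
  }
})

test_that("malformed PHORE files error with a line number", {
  path <- withr::local_tempfile(fileext = ".phore")
  writeLines(c("MODEL m", "WEIGHT 1", "FEATURE HBA 0 0", "END"), path)
  expect_error(read_pharmacophore(path), "line 3")
  writeLines(c("MODEL empty", "WEIGHT 1", "END"), path)
  expect_error(read_pharmacophore(path), "empty FEATURE")
  writeLines(c("MODEL m", "BOGUS 1"), path)
  expect_error(read_pharmacophore(path), "BOGUS")
})

test_that("mapping enumeration is injective and type-respecting", {
  model_ab <- pharmacophore_model("m", 1, list(pf("HBA", c(0, 0, 0)),
                                               pf("HBD", c(3, 0, 0))))
  expect_length(enumerate_mappings(list(lf("HBA", c(0, 0, 0))), model_ab,
                                   require_all = TRUE), 0L)
  model_aa <- pharmacophore_model("m", 1, list(pf("HBA", c(0, 0, 0)),
                                               pf("HBA", c(3, 0, 0))))
  two <- enumerate_mappings(list(lf("HBA", c(0, 0, 0)),
                                 lf("HBA", c(1, 0, 0))), model_aa,
                            require_all = TRUE)
  expect_length(two, 2L)
  for (mp in two) expect_equal(anyDuplicated(mp[, "ligand"]), 0L)
  model_h <- pharmacophore_model("m", 1, list(pf("Hbic", c(0, 0, 0))))
  expect_length(enumerate_mappings(list(lf("HBA", c(0, 0, 0))), model_h,
                                   require_all = TRUE), 0L)
  # partial mode enumerates subsets too
  partial <- enumerate_mappings(list(lf("HBA", c(0, 0, 0))), model_ab,
                                require_all = FALSE)
  expect_length(partial, 1L)
  expect_equal(nrow(partial[[1]]), 1L)
})

test_that("Kabsch superposition recovers rigid motions, rejects mirrors", {
  set.seed(4)
  P <- matrix(rnorm(15), 5, 3)
  expect_equal(superpose(P, P)$rmsd, 0, tolerance = 1e-10)
  expect_equal(superpose(P, P)$rotation, diag(3), tolerance = 1e-8)
  for (seed in 1:4) {
    mo <- rigid_motion(seed)
    Q <- sweep(P %*% mo$R, 2, mo$t, "+")
    tf <- superpose(Q, P)
    expect_equal(tf$rmsd, 0, tolerance = 1e-9)
    expect_equal(apply_transform(Q, tf), P, tolerance = 1e-9)
    expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
  }
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  mirror <- tet %*% diag(c(-1, 1, 1))
  expect_gt(superpose(mirror, tet)$rmsd, 0.5)
  expect_error(superpose(P[1:3, ], P), "differ in size")
})

test_that("fit value implements the printed formula literally", {
  no_proj <- function(n) rep(NA_real_, n)
  expect_equal(fit_value(list(origin = rep(0, 4), projection = no_proj(4)),
                         list(origin = rep(1.6, 4), projection = no_proj(4)),
                         1), 4)
  expect_equal(fit_value(list(origin = 1.6, projection = NA_real_),
                         list(origin = 1.6, projection = NA_real_), 1), 0)
  expect_equal(fit_value(list(origin = c(0.8, 0.5, 0),
                              projection = no_proj(3)),
                         list(origin = c(1, 1, 1), projection = no_proj(3)),
                         1), 3 * (1 - 0.89))
  # per-feature alternative cannot go below -W per feature and sums terms
  expect_equal(fit_value(list(origin = c(0, 1), projection = no_proj(2)),
                         list(origin = c(1, 1), projection = no_proj(2)),
                         2, formula = "per_feature_sum"), 2)
})

test_that("best_fit reaches N*W on exactly coincident point features", {
  model <- pharmacophore_model("tri", 2.26,
    list(pf("Hbic", c(0, 0, 0)), pf("Hbic", c(4, 0, 0)),
         pf("Hbic", c(0, 5, 1))))
  feats <- list(lf("Hbic", c(0, 0, 0)), lf("Hbic", c(4, 0, 0)),
                lf("Hbic", c(0, 5, 1)))
  res <- phoreqsar:::.best_fit_features(feats, model, require_all = TRUE)
  expect_equal(res$fit, 3 * 2.26, tolerance = 1e-9)
  expect_equal(max(res$disps$origin), 0, tolerance = 1e-9)

  # single-point model: alignment can always zero the displacement
  one <- pharmacophore_model("one", 1.5, list(pf("Hbic", c(7, -2, 3))))
  res1 <- phoreqsar:::.best_fit_features(list(lf("Hbic", c(0, 0, 0))), one,
                                         require_all = TRUE)
  expect_equal(res1$fit, 1.5, tolerance = 1e-9)

  # perturbing one origin by 0.5 A under a fixed frame costs (0.5/1.6)^2
  pert <- list(lf("Hbic", c(0.5, 0, 0)), lf("Hbic", c(4, 0, 0)),
               lf("Hbic", c(0, 5, 1)))
  resp <- phoreqsar:::.best_fit_features(pert, model, require_all = TRUE)
  expect_lt(resp$fit, res$fit)
  expect_gte(resp$fit, 3 * 2.26 * (1 - (0.5 / 1.6)^2) - 1e-9)
})

test_that("best_fit equals a brute-force mapping oracle on small cases", {
  # independent oracle: enumerate all injective kind-matched assignments
  # directly and score each with one superposition
  oracle <- function(feats, model, require_all) {
    mk <- vapply(model$features, `[[`, "", "kind")
    lk <- vapply(feats, `[[`, "", "kind")
    subsets <- if (require_all) list(seq_along(mk)) else
      unlist(lapply(seq_along(mk), function(s)
        utils::combn(seq_along(mk), s, simplify = FALSE)), recursive = FALSE)
    best <- -Inf
    perms <- function(v) if (length(v) <= 1L) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    for (sub in subsets) {
      cand <- which(lk %in% mk[sub])
      if (length(cand) < length(sub)) next
      for (choice in utils::combn(cand, length(sub), simplify = FALSE))
        for (ord in perms(choice)) {
          if (any(lk[ord] != mk[sub])) next
          mov <- do.call(rbind, lapply(feats[ord], `[[`, "origin"))
          ref <- do.call(rbind, lapply(model$features[sub], `[[`, "origin"))
          tf <- superpose(mov, ref)
          placed <- apply_transform(mov, tf)
          d <- sqrt(rowSums((placed - ref)^2))
          tol <- vapply(model$features[sub], `[[`, numeric(1), "origin_tol")
          if (any(d > tol)) next
          fit <- length(sub) * model$weight * (1 - sum((d / tol)^2))
          best <- max(best, fit)
        }
    }
    if (is.infinite(best)) NULL else best
  }
  set.seed(11)
  kinds <- c("HBA", "Hbic", "HBD", "RingArom")
  for (trial in 1:8) {
    nm <- sample(2:3, 1)
    nl <- sample(2:4, 1)
    model <- pharmacophore_model("m", runif(1, 0.5, 2.5),
      lapply(seq_len(nm), function(i)
        pf(sample(kinds, 1), rnorm(3, sd = 2), tol = runif(1, 1.2, 2))))
    feats <- lapply(seq_len(nl), function(i)
      lf(sample(kinds, 1), rnorm(3, sd = 2)))
    for (ra in c(TRUE, FALSE)) {
      got <- phoreqsar:::.best_fit_features(feats, model, require_all = ra)
      want <- oracle(feats, model, ra)
      if (is.null(want)) expect_null(got)
      else expect_equal(got$fit, want, tolerance = 1e-8)
    }
  }
})

test_that("best_fit is invariant under rigid motion of the ligand", {
  model <- read_pharmacophore(shipped_phore("5-R2-08"))
  lig <- gen_ligands(sim_config(seed = 21, n_compounds = 1), model, 1)[[1]]
  ref <- best_fit(lig, model, require_all = TRUE)$fit
  for (seed in 1:3) {
    moved <- move_molecule(lig, rigid_motion(seed + 30))
    expect_equal(best_fit(moved, model, require_all = TRUE)$fit, ref,
                 tolerance = 1e-6)
  }
})

test_that("fit never exceeds N*W and missing feature types yield absent", {
  model <- read_pharmacophore(shipped_phore("6-R2-07"))
  ligs <- gen_ligands(sim_config(seed = 31, n_compounds = 6), model, 0.5)
  for (m in ligs[1:3]) {
    bf <- best_fit(m, model, require_all = TRUE)
    expect_false(is.null(bf))
    expect_lte(bf$fit, length(model$features) * model$weight + 1e-9)
  }
  for (m in ligs[4:6])     # alkane decoys: no HBA/HBD -> no full mapping
    expect_null(best_fit(m, model, require_all = TRUE))
  expect_equal(unname(fit_descriptors(ligs[4:6], model,
                                      require_all = TRUE)), rep(0, 3))
})

test_that("screening honours exclusion spheres (metamorphic)", {
  model <- read_pharmacophore(shipped_phore("8-R3-08"))
  lig <- gen_ligands(sim_config(seed = 41, n_compounds = 1), model, 1)[[1]]
  res <- screen_molecule(lig, model)
  expect_true(res$hit)
  # plant an exclusion sphere on an occupied heavy-atom position
  bf <- res$mapping
  heavy <- lig$atoms$element != "H"
  aligned <- apply_transform(lig$conformers[[bf$conformer]]$coords[heavy, ],
                             bf$transform)
  occupied <- aligned[1, ]
  model2 <- model
  model2$exclusion_spheres <- data.frame(x = occupied[1], y = occupied[2],
                                         z = occupied[3], radius = 0.6)
  expect_false(screen_molecule(lig, model2)$hit)
  # a decoy mapping only part of the model is never a hit
  decoy <- gen_ligands(sim_config(seed = 42, n_compounds = 2), model, 0)[[1]]
  expect_false(screen_molecule(decoy, model)$hit)
})

test_that("f_score matches the lm F statistic and handles degeneracy", {
  set.seed(8)
  x <- rnorm(12); y <- 0.6 * x + rnorm(12, sd = 0.8)
  want <- unname(summary(stats::lm(y ~ x))$fstatistic["value"])
  expect_equal(f_score(x, y), want, tolerance = 1e-9)
  expect_equal(f_score(x, 2 * x + 1), 1e12)
  expect_error(f_score(rep(1, 5), rnorm(5)), "variance")
  expect_error(f_score(x[1:2], y[1:2]))
})
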