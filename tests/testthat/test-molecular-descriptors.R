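test_that("feature perception applies the documented rule table", {
  f <- perceive_features(fix_water())
  kinds <- vapply(f, `[[`, "", "kind")
  expect_equal(sum(kinds == "HBA"), 1L)
  expect_equal(sum(kinds == "HBD"), 2L)
  expect_equal(sum(kinds %in% c("Hbic", "RingArom")), 0L)
  # HBD projection is the hydrogen position
  hbd <- f[[which(kinds == "HBD")[1]]]
  expect_equal(hbd$projection, c(0.7572, 0.5865, 0))
  # HBA projection sits 1.9 A from the oxygen along the lone-pair bisector
  hba <- f[[which(kinds == "HBA")]]
  expect_equal(sqrt(sum((hba$projection - hba$origin)^2)), 1.9)
  expect_lt(hba$projection[2], 0)    # away from both hydrogens

  f <- perceive_features(fix_benzene())
  kinds <- vapply(f, `[[`, "", "kind")
  expect_equal(sort(kinds), c("Hbic", "RingArom"))
  rar <- f[[which(kinds == "RingArom")]]
  expect_equal(rar$origin, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(abs(rar$projection[3]), 2.0, tolerance = 1e-10)
  hbic <- f[[which(kinds == "Hbic")]]
  expect_equal(hbic$origin, c(0, 0, 0), tolerance = 1e-10)

  f <- perceive_features(fix_ethane())
  expect_equal(vapply(f, `[[`, "", "kind"), "Hbic")
  expect_equal(f[[1]]$origin, c(0.77, 0, 0))

  expect_error(perceive_features(fix_ethane(), 2L), "ethane")
})

test_that("feature perception is bit-identical across runs", {
  a <- perceive_features(fix_water())
  b <- perceive_features(fix_water())
  expect_identical(a, b)
})

test_that("chi2 matches brute-force path enumeration", {
  expect_equal(chi2_index(mol_from_smiles("CC")), 0)
  expect_equal(chi2_index(mol_from_smiles("CCC")), 1 / sqrt(2))
  expect_equal(chi2_index(mol_from_smiles("CC(C)C")), 3 / sqrt(3))
  # hydrogens are excluded: explicit H must not change the index
  expect_equal(chi2_index(add_hydrogens(mol_from_smiles("CCC"))),
               chi2_index(mol_from_smiles("CCC")))
})

test_that("kappa3 follows the odd/even closed forms", {
  expect_equal(kappa3_index(mol_from_smiles("CCCCC")), 4)     # A=5, P3=2
  expect_equal(kappa3_index(mol_from_smiles("CCCCCC")), 48 / 9)
  expect_equal(kappa3_index(mol_from_smiles("CCC")), 0)       # P3=0
})

test_that("ring counts come from the SSSR", {
  expect_equal(ring_count(fix_benzene(), 6L), 1L)
  expect_equal(ring_count(mol_from_smiles("c1ccc2ccccc2c1"), 6L), 2L)
  expect_equal(ring_count(mol_from_smiles("C1CCCC1"), 6L), 0L)
  expect_equal(ring_count(mol_from_smiles("C1CCCC1"), 5L), 1L)
  expect_error(ring_count(fix_benzene(), 2L))
})

test_that("topological indices are invariant under atom relabelling", {
  for (seed in 1:5) {
    m <- fix_random_mol(seed)
    p <- permute_molecule(m, seed + 50)
    expect_equal(chi2_index(p), chi2_index(m))
    expect_equal(kappa3_index(p), kappa3_index(m))
  }
  m <- mol_from_smiles("c1ccc2ccccc2c1")
  p <- permute_molecule(m, 99)
  expect_equal(ring_count(p, 6L), 2L)
})

test_that("dipole component is the charge-weighted coordinate sum", {
  cf <- conformer(matrix(c(0, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE))
  expect_equal(dipole_component(cf, c(0.5, -0.5), "y"), -2.401605)
  # mirror symmetry about the origin cancels
  cf2 <- conformer(matrix(c(0, -1, 0, 0, 1, 0), 2, 3, byrow = TRUE))
  expect_equal(dipole_component(cf2, c(0.3, 0.3), "y"), 0)
  expect_equal(dipole_component(cf, c(0, 0), "y"), 0)
  expect_error(dipole_component(cf, c(0.1), "y"), "length")
})

test_that("principal moments match analytic diatomic values", {
  cf <- conformer(matrix(c(-1, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(principal_moment(cf, c(1, 1), 1L), 0)
  expect_equal(principal_moment(cf, c(1, 1), 2L), 2)
  expect_equal(principal_moment(cf, c(1, 1), 3L), 2)
  cf1 <- conformer(matrix(c(3, -2, 5), 1, 3))
  expect_equal(principal_moment(cf1, 12, 3L), 0)
})

test_that("principal moments are invariant under rigid motion", {
  m <- fix_random_mol(3)
  masses <- rep(12.011, n_atoms(m))
  ref <- vapply(1:3, function(k)
    principal_moment(m$conformers[[1]], masses, k), numeric(1))
  for (seed in 1:4) {
    mm <- move_molecule(m, rigid_motion(seed))
    got <- vapply(1:3, function(k)
      principal_moment(mm$conformers[[1]], masses, k), numeric(1))
    expect_equal(got, ref, tolerance = 1e-8)
  }
})

test_that("shadow fraction behaves like a disk-in-box area ratio", {
  one <- conformer(matrix(0, 1, 3))
  expect_equal(shadow_xy_fraction(one, 1.5, 0.02), pi / 4, tolerance = 0.01)
  # two far-apart disks shrink the ratio below pi/4
  two <- conformer(matrix(c(0, 0, 0, 12, 0, 0), 2, 3, byrow = TRUE))
  expect_lt(shadow_xy_fraction(two, c(1.5, 1.5), 0.05, align = FALSE),
            pi / 4)
  # grid refinement converges
  a <- shadow_xy_fraction(two, c(1.5, 1.5), 0.05, align = FALSE)
  b <- shadow_xy_fraction(two, c(1.5, 1.5), 0.025, align = FALSE)
  expect_lt(abs(a - b), 0.02)
  # always in (0, 1]
  for (seed in 1:4) {
    m <- fix_random_mol(seed)
    v <- shadow_xy_fraction(m$conformers[[1]], rep(1.7, n_atoms(m)), 0.1)
    expect_gt(v, 0); expect_lte(v, 1)
  }
})

test_that("pIC50 conversion and monotonicity", {
  expect_equal(log_inverse_ic50(1), 0)
  expect_equal(log_inverse_ic50(5.7e-8), 7.2441, tolerance = 1e-4)
  expect_equal(log_inverse_ic50(0.5e-6), 6.3010, tolerance = 1e-4)
  x <- sort(10^runif(20, -9, -3))
  expect_true(all(diff(log_inverse_ic50(x)) < 0))
  expect_error(log_inverse_ic50(0), "positive")
})

test_that("SDF writer/reader round-trips multi-conformer molecules", {
  m <- fix_random_mol(1)
  m$conformers <- c(m$conformers,
                    list(conformer(m$conformers[[1]]$coords + 1)))
  m$activity <- activity_record(5.7e-8)
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(list(m), path)
  back <- read_sdf(path)
  expect_length(back, 1L)
  expect_length(back[[1]]$conformers, 2L)
  expect_equal(back[[1]]$atoms$element, m$atoms$element)
  expect_equal(back[[1]]$conformers[[2]]$coords,
               m$conformers[[2]]$coords, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(back[[1]]$activity$ic50, 5.7e-8)
})

test_that("descriptor table carries the canonical column names", {
  mols <- list(b = fix_benzene(), e = fix_ethane())
  tab <- descriptor_table(mols)
  expect_equal(names(tab), c("compound_id", "CHI_2", "Kappa_3",
                             "Num_Rings5", "Num_Rings6", "Dipole_Y",
                             "PMI_x", "Shadow_XYfrac"))
  expect_equal(tab$Num_Rings6, c(1L, 0L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_compound_tsv(tab, path)
  expect_equal(read_compound_tsv(path)$CHI_2, tab$CHI_2, tolerance = 1e-6)
})

test_that("conformer ensemble filter enforces window and cap", {
  m <- fix_random_mol(2)
  cfs <- lapply(c(0, 5, 25, NA), function(e)
    conformer(m$conformers[[1]]$coords,
              if (is.na(e)) NULL else e))
  m$conformers <- cfs
  out <- filter_conformers(m)
  expect_length(out$conformers, 3L)     # 25 kcal/mol pruned, NA kept
  m$conformers <- rep(m$conformers[1], 300)
  expect_length(filter_conformers(m)$conformers, 250L)
})
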