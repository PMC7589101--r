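test_that("frame NOE matches closed forms and the brute-force oracle", {
  # exactly two non-exchangeable protons -> 0.5 at any distance
  atoms2 <- atom_table(c("H1", "H2", "HO1", "O1"),
                       c("H", "H", "H", "O"), c(1, 2, 2, 2),
                       exchangeable = c(FALSE, FALSE, TRUE, FALSE))
  frame2 <- rbind(c(0, 0, 0), c(3.7, 0, 0), c(9, 0, 0), c(8.2, 0, 0))
  expect_equal(frame_noe(frame2, atoms2, a = 0, b = 1), 0.5)

  # three protons with r_ab = r_ac -> 0.25
  atoms3 <- atom_table(c("Ha", "Hb", "Hc"), rep("H", 3), c(1, 1, 1))
  frame3 <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  expect_equal(frame_noe(frame3, atoms3, a = 0, b = 1), 0.25)

  # general case against the independent oracle
  atoms <- fix_atoms5(); frame <- fix_frame5()
  for (a in 1:4) for (b in setdiff(1:4, a)) {
    expect_equal(frame_noe(frame, atoms, a, b), oracle_noe(frame, atoms, a, b))
  }
  # bounded by the two-proton limit
  expect_true(all(vapply(2:4, function(b)
    frame_noe(frame, atoms, 1, b), 1) <= 0.5))
  expect_error(frame_noe(frame, atoms, a = 5, b = 1), "non-exchangeable")
  clash <- frame; clash[3, ] <- frame[2, ] + c(0.05, 0, 0)
  expect_error(frame_noe(clash, atoms, a = 1, b = 2), "oincident")
})

test_that("adding an exchangeable proton changes no NOE value", {
  atoms <- fix_atoms5(); frame <- fix_frame5()
  before <- frame_noe(frame, atoms, 1, 2)
  atoms_plus <- atom_table(c(atoms$name, "HO9"), c(atoms$element, "H"),
                           c(atoms$residue_index, 2),
                           exchangeable = c(atoms$exchangeable, TRUE))
  frame_plus <- rbind(frame, c(0.9, 0.9, 0.2))  # close to everything
  expect_equal(frame_noe(frame_plus, atoms_plus, 1, 2), before)
})

test_that("ensemble averaging is a frame mean with the right invariances", {
  atoms <- fix_atoms5()
  sc <- saturation_scheme("H1", c("H2", "H3", "H4"), atoms)
  f1 <- fix_frame5()
  set.seed(3)
  f2 <- fix_frame5() + matrix(rnorm(21, sd = 0.3), 7, 3)
  ens1 <- ensemble(atoms, list(f1))
  tab1 <- ensemble_noe(ens1, sc)
  expect_equal(tab1$value,
               vapply(2:4, function(a) frame_noe(f1, atoms, a, 1), 1))
  # mean of two frames
  tab12 <- ensemble_noe(ensemble(atoms, list(f1, f2)), sc)
  tab2 <- ensemble_noe(ensemble(atoms, list(f2)), sc)
  expect_equal(tab12$value, (tab1$value + tab2$value) / 2)
  # frame permutation and per-frame rigid motion change nothing
  tab21 <- ensemble_noe(ensemble(atoms, list(f2, f1)), sc)
  expect_equal(tab21$value, tab12$value)
  moved <- ensemble(atoms, list(random_rigid(f1, 1), random_rigid(f2, 2)))
  expect_equal(ensemble_noe(moved, sc)$value, tab12$value)
  # transglycosidic flags from residue indices (H1 res1; H3,H4 res2)
  expect_equal(tab1$transglycosidic, c(FALSE, TRUE, TRUE))
})

test_that("normalization makes per-saturation sums exactly one", {
  atoms <- fix_atoms5()
  schemes <- list(saturation_scheme("H1", c("H2", "H3", "H4"), atoms),
                  saturation_scheme("H2", c("H1", "H3"), atoms))
  ens <- ensemble(atoms, list(fix_frame5()))
  norm <- normalize_noe(ensemble_noe(ens, schemes))
  sums <- tapply(norm$value, norm$saturated, sum)
  expect_equal(as.numeric(sums), c(1, 1))
  # arithmetic spot checks
  t <- data.frame(saturated = "Hb", observed = c("H1", "H2", "H3"),
                  value = c(0.3, 0.1, 0.1), transglycosidic = FALSE)
  class(t) <- c("noe_table", "data.frame")
  expect_equal(normalize_noe(t)$value, c(0.6, 0.2, 0.2))
  t$value <- c(0, 0, 0)
  expect_error(normalize_noe(t), "Hb")
})

test_that("Boltzmann weighting reduces to known weights and the oracle", {
  atoms <- fix_atoms5()
  sc <- saturation_scheme("H1", c("H2", "H3"), atoms)
  set.seed(8)
  confs <- lapply(1:3, function(i) fix_frame5() +
                    matrix(rnorm(21, sd = 0.2), 7, 3))
  # equal free energies -> plain ensemble mean
  bz <- boltzmann_noe(confs, c(5, 5, 5), sc, atoms = atoms)
  plain <- normalize_noe(ensemble_noe(ensemble(atoms, confs), sc))
  expect_equal(bz$value, plain$value)
  # two conformers with dG = RT ln 2 -> weights (2/3, 1/3)
  rt <- R_KCAL * 300
  g <- c(0, rt * log(2))
  per <- lapply(confs[1:2], function(f)
    vapply(2:3, function(a) frame_noe(f, atoms, a, 1), 1))
  manual <- (2 / 3) * per[[1]] + (1 / 3) * per[[2]]
  manual <- manual / sum(manual)
  bz2 <- boltzmann_noe(confs[1:2], g, sc, atoms = atoms)
  expect_equal(bz2$value, manual)
  # three stated G values against a hand-rolled weighted sum
  g3 <- c(0.0, 0.4, 1.1)
  w <- exp(-g3 / rt); w <- w / sum(w)
  manual3 <- Reduce(`+`, Map(function(p, wi) wi * p, per <- lapply(confs,
    function(f) vapply(2:3, function(a) frame_noe(f, atoms, a, 1), 1)), w))
  manual3 <- manual3 / sum(manual3)
  expect_equal(boltzmann_noe(confs, g3, sc, atoms = atoms)$value, manual3)
  expect_error(boltzmann_noe(confs, c(1, 2), sc, atoms = atoms),
               "one free energy per conformer")
})

test_that("NOE tables round-trip through delimited text", {
  atoms <- fix_atoms5()
  sc <- saturation_scheme("H1", c("H2", "H3"), atoms)
  tab <- normalize_noe(ensemble_noe(ensemble(atoms, list(fix_frame5())), sc))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_noe_table(tab, path)
  back <- read_noe_table(path, atoms = atoms)
  expect_equal(back$value, tab$value)
  expect_equal(back$transglycosidic, tab$transglycosidic)
})
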