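test_that("geometry construction is deterministic and set-then-measure exact", {
  for (tpl in list(template_toy(), template_disaccharide())) {
    ref <- reference_torsions(tpl)
    g1 <- build_geometry(tpl)
    g2 <- build_geometry(tpl)
    expect_identical(g1, g2)
    # measured torsions equal the set values across the circle
    for (lab in names(tpl$free_torsions)) {
      for (t in seq(-150, 180, by = 55)) {
        tv <- ref; tv[lab] <- t
        g <- suppressWarnings(build_geometry(tpl, tv))
        q <- tpl$free_torsions[[lab]]$quad
        expect_equal(abs(glynoe:::circ_diff(dihedral(g, q), t)), 0,
                     tolerance = 1e-6)
      }
    }
    # no clash at the reference torsions
    expect_gt(min(dist(g1)), 0.5)
  }
})

test_that("a 180-degree chain torsion gives the hand-computed geometry", {
  # 4-atom chain, all bonds 1.5, angles 109.47, torsion 180 (anti):
  # planar zig-zag; position of atom 4 computed by hand from the
  # internal-coordinate definitions
  atoms <- atom_table(paste0("C", 1:4), rep("C", 4), rep(1, 4))
  z <- data.frame(parent = c(NA, 0, 1, 2), grandparent = c(NA, NA, 0, 1),
                  greatgrand = c(NA, NA, NA, 0),
                  bond = c(NA, 1.5, 1.5, 1.5),
                  angle = c(NA, NA, 109.47, 109.47),
                  torsion = c(NA, NA, NA, 180))
  tpl <- molecular_template(atoms, z, list())
  g <- build_geometry(tpl)
  th <- 109.47 * pi / 180
  # C3 at C2 + 1.5*(cos(th)*u + sin(th)*perp) with u = unit(C1 - C2) =
  # (-1, 0, 0) and the in-plane perpendicular (-u2, u1, 0) = (0, -1, 0)
  expect_equal(g[3, ], c(1.5 - 1.5 * cos(th), -1.5 * sin(th), 0),
               tolerance = 1e-9)
  # anti torsion keeps the chain planar and extends it
  expect_equal(g[4, 3], 0, tolerance = 1e-9)
  expect_equal(dihedral(g, 0:3), 180 - 360)  # wrapped to -180
  d34 <- sqrt(sum((g[4, ] - g[3, ])^2))
  expect_equal(d34, 1.5, tolerance = 1e-9)
})

test_that("Metropolis sampling has flat and always-accept limits", {
  flat <- torsional_potential(list())  # no wells anywhere: dE = 0 always
  ang <- sample_torsions(flat, "phi", n_frames = 20000, seed = 17)
  expect_equal(ang$acceptance_rate, 1)
  h <- hist(ang$values[, 1], breaks = seq(-180, 180, by = 30),
            plot = FALSE)$counts
  expect_lt(max(abs(h / 20000 - 1 / 12)), 5 * sqrt((1 / 12) / 20000))
})

test_that("two-well populations follow the Boltzmann ratio", {
  de <- 0.8
  pot <- torsional_potential(
    list(phi = list(center = c(-60, 120), depth = c(3, 3 - de),
                    width = c(15, 15))))
  tpl <- template_toy()
  ens <- sample_ensemble(tpl, pot, n_frames = 30000, seed = 29)
  ang <- attr(ens, "torsions")
  wins <- list(c(-120, 0), c(60, 180))
  got <- vapply(wins, function(w) mean(glynoe:::in_window(ang[, 1], w)),
                numeric(1))
  gt <- ground_truth(tpl, pot, scheme = NULL, grid_step = 1)
  want <- gt_populations(gt, "phi", wins)
  # equal widths: population ratio is governed by exp(de/kT) with a
  # width correction that grid integration captures exactly
  se <- sqrt(want * (1 - want) / nrow(ang))
  expect_lt(max(abs(got - want) / se), 15)
  expect_lt(max(abs(got - want)), 0.02)
})

test_that("ground truth has the delta and flat limits", {
  tpl <- template_toy()
  # near-delta well: ground-truth NOE equals the rigid-geometry NOE
  narrow <- torsional_potential(
    list(phi = list(center = 75, depth = 30, width = 1)))
  sc <- saturation_scheme("H21", c("H11", "H12", "H13"), tpl$atoms)
  gt <- ground_truth(tpl, narrow, sc, grid_step = 1)
  rigid <- normalize_noe(ensemble_noe(
    ensemble(tpl$atoms, list(build_geometry(tpl, c(phi = 75)))), sc))
  expect_equal(gt$noe$value, rigid$value, tolerance = 1e-4)
  # flat potential: uniform grid density
  flat <- torsional_potential(list())
  gtf <- ground_truth(tpl, flat, scheme = NULL, grid_step = 5)
  expect_equal(gtf$grid$phi$density, rep(1 / 72, 72))
})

test_that("sampled NOE converges to the grid oracle as frames grow", {
  tpl <- template_toy()
  pot <- torsional_potential(
    list(phi = list(center = c(50, -70), depth = c(2.5, 2.0),
                    width = c(20, 25))))
  sc <- saturation_scheme("H21", c("H11", "H12", "H13"), tpl$atoms)
  gt <- ground_truth(tpl, pot, sc, grid_step = 2)
  err_at <- function(n, seed) {
    ens <- sample_ensemble(tpl, pot, n_frames = n, seed = seed)
    sim <- normalize_noe(ensemble_noe(ens, sc))
    max(abs(sim$value - gt$noe$value))
  }
  e_small <- median(vapply(1:3, function(s) err_at(500, s), numeric(1)))
  e_large <- median(vapply(1:3, function(s) err_at(8000, s), numeric(1)))
  expect_lt(e_large, e_small)   # error shrinks with sample size
  expect_lt(e_large, 0.02)
})

test_that("two-basin ensemble NOE equals the population-weighted mixture", {
  tpl <- template_toy()
  pot <- torsional_potential(
    list(phi = list(center = c(60, -60), depth = c(3.2, 2.6),
                    width = c(8, 8))))
  sc <- saturation_scheme("H21", c("H11", "H12", "H13"), tpl$atoms)
  ens <- sample_ensemble(tpl, pot, n_frames = 20000, seed = 37)
  sim <- ensemble_noe(ens, sc)
  # narrow wells: mixture of the two rigid per-basin values weighted by
  # the sampled populations (analytic mixture from the sampler's truth)
  ang <- attr(ens, "torsions")[, 1]
  p1 <- mean(glynoe:::in_window(ang, c(0, 120)))
  v1 <- vapply(c("H11", "H12", "H13"), function(a)
    frame_noe(build_geometry(tpl, c(phi = 60)), tpl$atoms,
              glynoe:::resolve_atoms(tpl$atoms, a),
              glynoe:::resolve_atoms(tpl$atoms, "H21")), numeric(1))
  v2 <- vapply(c("H11", "H12", "H13"), function(a)
    frame_noe(build_geometry(tpl, c(phi = -60)), tpl$atoms,
              glynoe:::resolve_atoms(tpl$atoms, a),
              glynoe:::resolve_atoms(tpl$atoms, "H21")), numeric(1))
  mix <- p1 * v1 + (1 - p1) * v2
  expect_lt(max(abs(sim$value - mix)), 0.01)
})
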