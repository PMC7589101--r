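test_that("superposition recovers identity and known rigid motions", {
  f <- fix_frame5()
  s <- superpose(f, f)
  expect_equal(s$rotation, diag(3), tolerance = 1e-10)
  expect_equal(s$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  # known rotation + shift
  set.seed(31)
  qr_ <- qr(matrix(rnorm(9), 3)); R0 <- qr.Q(qr_)
  if (det(R0) < 0) R0[, 1] <- -R0[, 1]
  shift <- c(2, -1, 4)
  moved <- f %*% t(R0) + matrix(shift, nrow(f), 3, byrow = TRUE)
  s2 <- superpose(moved, f)
  expect_equal(s2$rotation %*% R0, diag(3), tolerance = 1e-6)
  expect_equal(s2$rmsd, 0, tolerance = 1e-8)
  # cross-check the residual against bio3d's fitting on noisy data
  sigma <- 0.1
  noisy <- moved + matrix(rnorm(21, sd = sigma), 7, 3)
  s3 <- superpose(noisy, f)
  fit <- suppressWarnings(
    bio3d::fit.xyz(as.vector(t(f)), as.vector(t(noisy))))
  rmsd_bio3d <- sqrt(mean(rowSums(
    (matrix(fit, ncol = 3, byrow = TRUE) - f)^2)))
  expect_equal(s3$rmsd, rmsd_bio3d, tolerance = 1e-6)
  # expected residual RMSD for N(0, sigma): around sigma * sqrt(3) before
  # fitting; fitted residual is below that but within a 3 sigma-ish band
  expect_lt(abs(s3$rmsd - sigma * sqrt(3)), 3 * sigma)
  expect_error(superpose(f[1:3, ] * 0, f[1:3, ]), "degenerate")
})

test_that("superposition RMSD is symmetric and rigid-motion invariant", {
  set.seed(32)
  a <- matrix(rnorm(18), 6, 3)
  b <- a + matrix(rnorm(18, sd = 0.2), 6, 3)
  expect_equal(superpose(a, b)$rmsd, superpose(b, a)$rmsd, tolerance = 1e-9)
  g <- random_rigid(a, 5); h <- random_rigid(b, 5)
  expect_equal(superpose(g, h)$rmsd, superpose(a, b)$rmsd, tolerance = 1e-9)
})

test_that("silhouette selection finds the generative cluster count", {
  bl <- blob_ensemble(c(12, 12, 12))
  sel <- cluster_frames(bl$ens, heavy_only = FALSE, k_range = 2:5, seed = 4)
  expect_equal(sel$k, 3)
  # assignments match generation labels up to permutation
  tab <- table(sel$assignment, bl$labels)
  expect_equal(sum(apply(tab, 1, max)), length(bl$labels))
  # reproducibility for a fixed seed
  sel2 <- cluster_frames(bl$ens, heavy_only = FALSE, k_range = 2:5, seed = 4)
  expect_identical(sel$assignment, sel2$assignment)
  expect_identical(sel$silhouette, sel2$silhouette)
})

test_that("degenerate and trivial clustering cases behave", {
  atoms <- atom_table(paste0("C", 1:4), rep("C", 4), rep(1, 4))
  same <- ensemble(atoms, replicate(10, matrix(1:12, 4, 3), simplify = FALSE))
  expect_error(cluster_frames(same, heavy_only = FALSE, k_range = 2:3,
                              seed = 1), "degenerate")
  bl2 <- blob_ensemble(c(8, 8), seed = 23)
  sel <- cluster_frames(bl2$ens, heavy_only = FALSE, k_range = 2:2, seed = 2)
  expect_equal(sel$k, 2)
  expect_equal(sort(unique(sel$assignment[sel$medoid_frames])), 1:2)
  tab <- table(sel$assignment, bl2$labels)
  expect_equal(sum(apply(tab, 1, max)), 16)
  expect_error(cluster_frames(bl2$ens, k_range = 2:40, seed = 1),
               "exceeds")
})

test_that("medoids equal the exhaustive nearest-to-centroid search", {
  bl <- blob_ensemble(c(10, 14, 9), seed = 25)
  sel <- cluster_frames(bl$ens, heavy_only = FALSE, k_range = 3:3, seed = 6)
  meds <- medoids(sel, bl$ens)
  for (cl in seq_len(sel$k)) {
    members <- which(sel$assignment == cl)
    d <- vapply(members, function(i)
      sum((sel$coords[i, ] - sel$centers[cl, ])^2), numeric(1))
    expect_equal(meds[cl], members[which.min(d)])
    expect_equal(sel$assignment[meds[cl]], cl)
  }
  # singleton cluster returns its only member
  sub <- list(k = 2L,
              assignment = c(1L, 1L, 2L),
              centers = rbind(c(0, 0), c(9, 9)),
              coords = rbind(c(0, 0), c(1, 1), c(9.5, 9)))
  atoms1 <- atom_table("C1", "C", 1)
  e3 <- ensemble(atoms1, replicate(3, matrix(rnorm(3), 1), simplify = FALSE))
  expect_equal(medoids(sub, e3)[2], 3)
})

test_that("medoid Boltzmann NOE approximates the full-ensemble NOE", {
  # well-separated torsional basins: medoid-per-basin with free energies
  # -kT log(population) should reproduce the ensemble average
  tpl <- template_toy()
  pot <- torsional_potential(
    list(phi = list(center = c(60, -60), depth = c(3.5, 2.8),
                    width = c(10, 10))))
  ens <- sample_ensemble(tpl, pot, n_frames = 3000, seed = 41)
  sc <- saturation_scheme("H21", c("H11", "H12", "H13"), ens$atoms)
  full <- normalize_noe(ensemble_noe(ens, sc))
  sel <- cluster_frames(ens, heavy_only = TRUE, k_range = 2:2, seed = 3,
                        silhouette_max_n = 500)
  meds <- sel$medoid_frames
  pops <- tabulate(sel$assignment, sel$k) / length(sel$assignment)
  g <- -R_KCAL * 300 * log(pops)
  bz <- boltzmann_noe(ens$frames[meds], g, sc, atoms = ens$atoms)
  expect_lt(max(abs(bz$value - full$value)), 0.05)
})
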