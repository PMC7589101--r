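rodrigues <- function(v, u, ang) {
  a <- ang * pi / 180
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  v * cos(a) + cr * sin(a) + u * sum(u * v) * (1 - cos(a))
}

test_that("dihedral matches planar references and a rotation construction", {
  A <- c(0, 0, 0); B <- c(1, 0, 0); C <- c(1, 1, 0)
  expect_equal(dihedral(rbind(A, B, C, c(0, 1, 0)), 0:3), 0)
  expect_equal(dihedral(rbind(A, B, C, c(2, 1, 0)), 0:3), -180)  # wrapped
  # rotate D about the b->c axis from cis by a known angle (right-hand rule
  # about b->c, i.e. clockwise seen from b towards c = positive IUPAC)
  u <- (C - B) / sqrt(sum((C - B)^2))
  D0 <- c(0, 1, 0)
  for (ang in c(-170, -90, -30, 30, 90, 144)) {
    D <- C + rodrigues(D0 - C, u, ang)
    expect_equal(dihedral(rbind(A, B, C, D), 0:3), ang, tolerance = 1e-9)
  }
  expect_error(dihedral(rbind(A, B, c(2, 0, 0), c(3, 0, 0)), 0:3),
               "collinear")
})

test_that("dihedral is rigid-motion invariant and mirror-antisymmetric", {
  set.seed(7)
  for (s in 1:20) {
    frame <- matrix(rnorm(12), 4)
    val <- tryCatch(dihedral(frame, 0:3), error = function(e) NULL)
    if (is.null(val)) next
    moved <- random_rigid(frame, seed = s)
    expect_equal(dihedral(moved, 0:3), val, tolerance = 1e-9)
    mirrored <- frame %*% diag(c(1, 1, -1))
    expect_equal(dihedral(mirrored, 0:3), -val, tolerance = 1e-9)
  }
})

test_that("pro-S selection agrees with a worked CIP assignment", {
  # ideal tetrahedral CH2(O)(C): center at origin, substituents on the
  # body-diagonal directions. With the dummy outranking O > C > (other H),
  # viewing away from the lowest-priority substituent, dummy->O->C runs
  # counterclockwise for the H on (-1,1,-1): manual CIP gives S there.
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  frame <- rbind(c(0, 0, 0), v)  # center, O, C, Ha, Hb
  proS <- select_pro_s(frame, center = 0, candidates = c(3, 4),
                       priority_neighbors = c(1, 2, 4))
  expect_equal(proS, 3L)
  # mirror reflection flips the assignment
  expect_equal(select_pro_s(frame %*% diag(c(1, 1, -1)), 0, c(3, 4),
                            c(1, 2, 4)), 4L)
  # planar centre degenerates
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0),
                c(0, 1, 0), c(0, -1, 0))
  expect_error(select_pro_s(flat, 0, c(3, 4), c(1, 2, 4)), "planar")
})

test_that("torsion series reproduces per-frame dihedrals and constants", {
  tpl <- template_toy()
  g <- build_geometry(tpl, c(phi = 60))
  ens <- ensemble(tpl$atoms, list(g))
  def <- torsion_definition("phi", tpl$free_torsions$phi$quad)
  ts <- torsion_series(ens, def)
  expect_equal(nrow(ts$values), 1)
  expect_equal(ts$values[1, "phi"], dihedral(g, def), ignore_attr = TRUE)
  # rigid ensemble at a fixed torsion
  frames <- replicate(25, build_geometry(tpl, c(phi = 60)),
                      simplify = FALSE)
  ts <- torsion_series(ensemble(tpl$atoms, frames), def)
  expect_equal(max(abs(ts$values[, "phi"] - 60)), 0, tolerance = 1e-9)
})

test_that("sampled torsion histogram matches the target Boltzmann density", {
  pot <- torsional_potential(
    list(phi = list(center = c(-60, 120), depth = c(2.5, 1.8),
                    width = c(18, 18))))
  ang <- sample_torsions(pot, "phi", n_frames = 30000, seed = 3)
  # grid-normalized Boltzmann density of the same potential
  theta <- seq(-180, 179, by = 1)
  e <- glynoe:::energy_1d(pot, "phi", theta)
  p <- exp(-e / (R_KCAL * 300)); p <- p / sum(p)
  wins <- list(c(-120, 0), c(60, 180))
  target <- vapply(wins, function(w) sum(p[glynoe:::in_window(theta, w)]),
                   numeric(1))
  # correlated Metropolis draws: batch-means standard errors
  for (k in seq_along(wins)) {
    ind <- glynoe:::in_window(ang$values[, 1], wins[[k]])
    m <- matrix(ind[1:30000], ncol = 50)
    se <- sd(colMeans(m)) / sqrt(50)
    expect_lt(abs(mean(ind) - target[k]), 3 * se)
    expect_lt(abs(mean(ind) - target[k]), 0.03)
  }
})

test_that("conformation maps normalize, zero their minimum and wrap", {
  set.seed(1)
  vals <- cbind(phi = runif(20000, -180, 180))
  cm <- conformation_map(fake_series(vals), "phi", bin_width = 10)
  expect_equal(sum(cm$density), 1)
  expect_lt(max(abs(cm$density - 1 / 36)), 4 * sqrt((1 / 36) / 20000))
  # delta map
  cm1 <- conformation_map(fake_series(cbind(phi = rep(42.2, 50))), "phi")
  expect_equal(max(cm1$density), 1)
  expect_equal(min(cm1$energy, na.rm = TRUE), 0)
  expect_equal(sum(!is.na(cm1$energy)), 1)
  # 2D map sums to 1 and its energy minimum is exactly zero
  vals2 <- cbind(phi = runif(5000, -180, 180), psi = runif(5000, -180, 180))
  cm2 <- conformation_map(fake_series(vals2), c("phi", "psi"),
                          bin_width = 30)
  expect_equal(sum(cm2$density), 1)
  expect_equal(min(cm2$energy, na.rm = TRUE), 0)
  expect_error(conformation_map(fake_series(vals), "psi"), "not in series")
  expect_error(conformation_map(fake_series(vals), "phi", bin_width = 7),
               "divide 360")
})

test_that("basin energy differences reflect well-depth differences", {
  dd <- 0.7  # kcal/mol between the two well floors
  pot <- torsional_potential(
    list(phi = list(center = c(-60, 100), depth = c(3, 3 - dd),
                    width = c(15, 15))))
  ang <- sample_torsions(pot, "phi", n_frames = 40000, seed = 5)
  cm <- conformation_map(fake_series(ang$values), "phi", bin_width = 5,
                         temperature = 300)
  ctr <- cm$breaks + 2.5
  e1 <- min(cm$energy[abs(glynoe:::circ_diff(ctr, -60)) <= 20], na.rm = TRUE)
  e2 <- min(cm$energy[abs(glynoe:::circ_diff(ctr, 100)) <= 20], na.rm = TRUE)
  expect_equal(e2 - e1, dd, tolerance = 0.2)
})

test_that("basin summary recovers circular means, SDs and populations", {
  x <- c(rep(60, 30))
  bs <- basin_summary(fake_series(cbind(psi = x)), "psi", list(c(0, 120)))
  expect_equal(bs$mean, 60)
  expect_equal(bs$sd, 0)
  expect_equal(bs$population, 1)
  # wrap-straddling window: clusters at +170 and -170
  x <- c(rep(170, 50), rep(-170, 50))
  bs <- basin_summary(fake_series(cbind(psi = x)), "psi",
                      list(c(120, -120)))
  # brute-force mean of unit vectors
  expected <- atan2(mean(sin(x * pi / 180)), mean(cos(x * pi / 180))) * 180 / pi
  expect_equal(abs(bs$mean), 180)
  expect_equal(abs(glynoe:::circ_diff(bs$mean, expected)), 0,
               tolerance = 1e-9)
  expect_equal(bs$population, 1)
  expect_error(basin_summary(fake_series(cbind(psi = x)), "psi",
                             list(c(0, 120), c(100, 200))), "overlap")
})

test_that("transition counts follow the basin assignment sequence", {
  wins <- list(c(0, 120), c(-120, 0))
  expect_equal(transition_count(fake_series(cbind(x = rep(60, 10))), "x",
                                wins), 0)
  expect_equal(transition_count(
    fake_series(cbind(x = c(60, -60, 60, -60))), "x", wins), 3)
  # frames outside all windows are skipped, not transitions
  expect_equal(transition_count(
    fake_series(cbind(x = c(60, 150, 60, -60))), "x", wins), 1)
  # two-state chain with known switching probability
  set.seed(9)
  n <- 20000; p_sw <- 0.2
  state <- cumsum(c(1, runif(n - 1) < p_sw)) %% 2
  x <- ifelse(state == 0, 60, -60)
  cnt <- transition_count(fake_series(cbind(x = x)), "x", wins)
  expect_lt(abs(cnt - p_sw * (n - 1)),
            3 * sqrt((n - 1) * p_sw * (1 - p_sw)))
})
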