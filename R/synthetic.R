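# Synthetic disaccharide-like ensembles with exact ground truth.
#
# A rigid covalent template (internal coordinates: bond to parent, angle to
# grandparent, torsion to great-grandparent) carries one or more free
# glycosidic torsions. Conformers are generated by substituting torsion
# values into the template and rebuilding Cartesians (NeRF chain
# construction), so the only degrees of freedom are the glycosidic angles
# and every downstream statistic has a grid-integrable oracle. Sampling is
# Metropolis Monte Carlo on the free torsions under a user-defined
# multi-well periodic potential.

#' Construct a rigid molecular template
#'
#' @param atoms an \code{\link{atom_table}}.
#' @param zmat data frame with one row per atom in build order: columns
#'   \code{parent}, \code{grandparent}, \code{greatgrand} (0-based atom ids,
#'   NA for the first three atoms as applicable), \code{bond} (Angstrom),
#'   \code{angle}, \code{torsion} (degrees).
#' @param free_torsions named list; each element is a list with \code{rows}
#'   (0-based atom ids whose z-matrix torsion entries are driven by this
#'   torsion), \code{offsets} (degrees added to the torsion value, one per
#'   row) and \code{quad} (the 4 atom ids measuring the torsion, order
#'   a-b-c-d). The torsion value applies to the first row directly
#'   (offset 0), sibling substituents follow at fixed offsets, so each free
#'   torsion rotates one rigid group about one bond.
#' @return An object of class \code{"molecular_template"}.
#' @export
molecular_template <- function(atoms, zmat, free_torsions) {
  stopifnot(inherits(atoms, "atom_table"), nrow(zmat) == nrow(atoms))
  need <- c("parent", "grandparent", "greatgrand", "bond", "angle", "torsion")
  miss <- setdiff(need, names(zmat))
  if (length(miss)) stop("zmat missing column(s): ", paste(miss, collapse = ", "))
  for (lab in names(free_torsions)) {
    ft <- free_torsions[[lab]]
    if (length(ft$rows) != length(ft$offsets)) {
      stop("free torsion '", lab, "': rows/offsets length mismatch")
    }
    if (length(ft$quad) != 4) stop("free torsion '", lab, "': quad must have 4 atoms")
  }
  # free torsions must drive disjoint z-matrix rows (independent bonds)
  all_rows <- unlist(lapply(free_torsions, `[[`, "rows"))
  if (anyDuplicated(all_rows)) {
    stop("free torsions must drive disjoint z-matrix rows")
  }
  structure(list(atoms = atoms, zmat = zmat, free_torsions = free_torsions),
            class = "molecular_template")
}

#' Reference torsion values of a template
#'
#' The torsion entries stored in the template's z-matrix for each free
#' torsion's primary row.
#'
#' @param template a \code{\link{molecular_template}}.
#' @return Named numeric vector, degrees.
#' @export
reference_torsions <- function(template) {
  vapply(template$free_torsions, function(ft) {
    template$zmat$torsion[ft$rows[1] + 1L]
  }, numeric(1))
}

# NeRF placement: position of atom D given ancestors A (great-grandparent),
# B (grandparent), C (parent), bond r = |DC|, angle theta = D-C-B, and
# torsion tau = dihedral(A, B, C, D), IUPAC convention.
place_atom <- function(A, B, C, r, theta, tau) {
  th <- theta * pi / 180
  ta <- tau * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("collinear ancestors in template construction")
  n <- n / nn
  m <- cross3(n, bc)
  d2 <- r * c(-cos(th), sin(th) * cos(ta), sin(th) * sin(ta))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build Cartesian coordinates from a template
#'
#' Substitutes the given free-torsion values into the template's z-matrix
#' (primary row plus fixed sibling offsets) and reconstructs Cartesians atom
#' by atom. Deterministic. Emits a warning (not an error) if the resulting
#' geometry has an interatomic clash below 0.5 Angstrom.
#'
#' @param template a \code{\link{molecular_template}}.
#' @param torsion_values named numeric vector (degrees), one value per free
#'   torsion; omitted torsions stay at their template reference values.
#' @return n x 3 coordinate matrix (Angstrom).
#' @export
build_geometry <- function(template, torsion_values = NULL) {
  z <- template$zmat
  if (!is.null(torsion_values)) {
    bad <- setdiff(names(torsion_values), names(template$free_torsions))
    if (length(bad)) stop("unknown free torsion(s): ", paste(bad, collapse = ", "))
    for (lab in names(torsion_values)) {
      ft <- template$free_torsions[[lab]]
      z$torsion[ft$rows + 1L] <- wrap_angle(torsion_values[[lab]] + ft$offsets)
    }
  }
  n <- nrow(z)
  xyz <- matrix(NA_real_, n, 3)
  xyz[1, ] <- c(0, 0, 0)
  if (n >= 2) xyz[2, ] <- c(z$bond[2], 0, 0)
  if (n >= 3) {
    p <- z$parent[3] + 1L; g <- z$grandparent[3] + 1L
    u <- xyz[g, ] - xyz[p, ]
    u <- u / sqrt(sum(u^2))
    th <- z$angle[3] * pi / 180
    # in-plane placement; perpendicular chosen in the xy-plane
    perp <- c(-u[2], u[1], 0)
    if (sum(perp^2) < 1e-12) perp <- c(0, 1, 0)
    perp <- perp / sqrt(sum(perp^2))
    xyz[3, ] <- xyz[p, ] + z$bond[3] * (cos(th) * u + sin(th) * perp)
  }
  if (n >= 4) {
    for (i in 4:n) {
      xyz[i, ] <- place_atom(xyz[z$greatgrand[i] + 1L, ],
                             xyz[z$grandparent[i] + 1L, ],
                             xyz[z$parent[i] + 1L, ],
                             z$bond[i], z$angle[i], z$torsion[i])
    }
  }
  d <- stats::dist(xyz)
  if (min(d) < 0.5) {
    warning("geometry clash: minimum interatomic distance ",
            format(min(d), digits = 3), " A")
  }
  xyz
}

#' Multi-well periodic torsional potential
#'
#' Energy of a free-torsion vector as a sum over torsions of independent
#' 1D terms; each 1D term is a sum of periodic Gaussian wells,
#' E(theta) = -sum_w depth_w * exp(-0.5 * (d(theta, center_w)/width_w)^2)
#' with d the circular difference in degrees. Finite and 360-periodic
#' everywhere; depths in kcal/mol.
#'
#' @param wells named list (one element per free-torsion label); each
#'   element a data frame or list with \code{center}, \code{depth},
#'   \code{width} vectors (degrees, kcal/mol, degrees).
#' @param temperature temperature in K used for sampling and grid
#'   densities (default 300).
#' @return An object of class \code{"torsional_potential"} that can be
#'   called by \code{\link{potential_energy}}.
#' @export
torsional_potential <- function(wells, temperature = 300) {
  for (lab in names(wells)) {
    w <- wells[[lab]]
    if (!length(w$center) || length(w$center) != length(w$depth) ||
        length(w$center) != length(w$width)) {
      stop("wells for '", lab, "' need matching center/depth/width vectors")
    }
    if (any(w$width <= 0)) stop("well widths must be positive")
  }
  structure(list(wells = wells, temperature = temperature),
            class = "torsional_potential")
}

circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# 1D energy of one torsion label at angles theta (vectorized)
energy_1d <- function(potential, label, theta) {
  w <- potential$wells[[label]]
  if (is.null(w)) return(rep(0, length(theta)))
  e <- rep(0, length(theta))
  for (k in seq_along(w$center)) {
    e <- e - w$depth[k] * exp(-0.5 * (circ_diff(theta, w$center[k]) /
                                        w$width[k])^2)
  }
  e
}

#' Potential energy of a torsion-value vector
#'
#' @param potential a \code{\link{torsional_potential}}.
#' @param torsion_values named numeric vector, degrees.
#' @return Energy in kcal/mol.
#' @export
potential_energy <- function(potential, torsion_values) {
  sum(vapply(names(torsion_values), function(lab) {
    energy_1d(potential, lab, torsion_values[[lab]])
  }, numeric(1)))
}

#' Sample an ensemble by Metropolis Monte Carlo on the free torsions
#'
#' Symmetric proposals on every free torsion — a Gaussian step of the given
#' size, replaced with probability \code{jump_prob} by a uniform draw on
#' the whole circle so that well-separated basins exchange efficiently —
#' accepted with probability min(1, exp(-dE/kBT)); after burn-in, the
#' geometry at every step (including rejected-move repeats) becomes a
#' frame. Both proposal components are symmetric, so detailed balance
#' holds and the chain targets the Boltzmann density of the potential
#' exactly. Deterministic for a fixed seed. The chain starts at the
#' deepest well of each torsion (or the template reference when a torsion
#' has no wells).
#'
#' @param template a \code{\link{molecular_template}}.
#' @param potential a \code{\link{torsional_potential}}.
#' @param n_frames number of frames to record.
#' @param step_size local-proposal standard deviation, degrees (default 30).
#' @param jump_prob probability of a whole-circle uniform proposal in
#'   place of the local step (default 0.3; 0 gives a pure random walk).
#' @param burn_in discarded initial steps (default 1000).
#' @param seed integer seed (mandatory; no hidden global randomness).
#' @return An \code{\link{ensemble}} with attributes
#'   \code{"torsions"} (the sampled frames x torsions angle matrix) and
#'   \code{"acceptance_rate"}.
#' @export
sample_ensemble <- function(template, potential, n_frames, step_size = 30,
                            jump_prob = 0.3, burn_in = 1000, seed) {
  ang <- sample_torsions(potential, labels = names(template$free_torsions),
                         n_frames = n_frames, step_size = step_size,
                         jump_prob = jump_prob,
                         burn_in = burn_in, seed = seed,
                         start = reference_torsions(template))
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    tv <- ang$values[i, ]
    names(tv) <- colnames(ang$values)
    frames[[i]] <- suppressWarnings(build_geometry(template, tv))
  }
  ens <- ensemble(template$atoms, frames)
  attr(ens, "torsions") <- ang$values
  attr(ens, "acceptance_rate") <- ang$acceptance_rate
  ens
}

#' Metropolis chain on torsion angles only
#'
#' The angular core of \code{\link{sample_ensemble}}, exposed for density
#' checks that need no Cartesian geometry.
#'
#' @inheritParams sample_ensemble
#' @param labels free-torsion labels to sample.
#' @param start named starting angles; defaults to each label's deepest
#'   well centre.
#' @return List with \code{values} (n_frames x labels matrix, degrees in
#'   [-180, 180)) and \code{acceptance_rate}.
#' @export
sample_torsions <- function(potential, labels, n_frames, step_size = 30,
                            jump_prob = 0.3, burn_in = 1000, seed,
                            start = NULL) {
  if (missing(seed)) stop("seed is required")
  if (n_frames < 1) stop("n_frames must be >= 1")
  set.seed(as.integer(seed))
  cur <- vapply(labels, function(lab) {
    w <- potential$wells[[lab]]
    if (!is.null(w)) w$center[which.max(w$depth)]
    else if (!is.null(start) && lab %in% names(start)) start[[lab]] else 0
  }, numeric(1))
  names(cur) <- labels
  e_cur <- sum(vapply(labels, function(l) energy_1d(potential, l, cur[[l]]),
                      numeric(1)))
  beta <- 1 / kT(potential$temperature)
  nl <- length(labels)
  total <- burn_in + n_frames
  jump <- stats::runif(total) < jump_prob
  step <- matrix(stats::rnorm(total * nl, 0, step_size), total, nl)
  unif <- matrix(stats::runif(total * nl, -180, 180), total, nl)
  us <- stats::runif(total)
  out <- matrix(NA_real_, n_frames, nl, dimnames = list(NULL, labels))
  acc <- 0L
  for (s in seq_len(total)) {
    cand <- if (jump[s]) unif[s, ] else wrap_angle(cur + step[s, ])
    names(cand) <- labels
    e_cand <- sum(vapply(labels, function(l) energy_1d(potential, l, cand[[l]]),
                         numeric(1)))
    if (us[s] <= exp(-beta * (e_cand - e_cur))) {
      cur <- cand
      e_cur <- e_cand
      acc <- acc + 1L
    }
    if (s > burn_in) out[s - burn_in, ] <- cur
  }
  list(values = out, acceptance_rate = acc / total)
}

#' Grid-integration ground truth for a template + potential
#'
#' Boltzmann density of each free torsion on a regular grid (the potential
#' is separable over torsions, so the joint density is the product), basin
#' populations by window integration, and the reference NOE table as the
#' density-weighted average of single-frame NOEs over all grid geometries,
#' normalized per saturated proton. This is the independent oracle the
#' sampled pipeline is checked against.
#'
#' @param template a \code{\link{molecular_template}}.
#' @param potential a \code{\link{torsional_potential}}.
#' @param scheme a \code{\link{saturation_scheme}} or list of them; NULL to
#'   skip the NOE oracle.
#' @param grid_step grid spacing in degrees; must divide 360 (default 5).
#' @return An object of class \code{"ground_truth"}: list with
#'   \code{grid} (per-label data frame: theta, density summing to 1),
#'   \code{noe} (normalized \code{"noe_table"} or NULL), \code{grid_step},
#'   \code{temperature}.
#' @export
ground_truth <- function(template, potential, scheme = NULL, grid_step = 5) {
  if (abs(360 / grid_step - round(360 / grid_step)) > 1e-9) {
    stop("grid_step must divide 360 evenly")
  }
  labels <- names(template$free_torsions)
  theta <- seq(-180, 180 - grid_step, by = grid_step)
  beta <- 1 / kT(potential$temperature)
  grid <- lapply(labels, function(lab) {
    w <- exp(-beta * energy_1d(potential, lab, theta))
    data.frame(theta = theta, density = w / sum(w))
  })
  names(grid) <- labels
  noe <- NULL
  if (!is.null(scheme)) {
    pts <- do.call(expand.grid, lapply(grid, function(g) g$theta))
    names(pts) <- labels
    wts <- Reduce(`*`, lapply(labels, function(lab) {
      grid[[lab]]$density[match(pts[[lab]], grid[[lab]]$theta)]
    }))
    if (nrow(pts) > 25000) {
      stop("grid too fine (", nrow(pts), " points); increase grid_step")
    }
    schemes <- if (inherits(scheme, "saturation_scheme")) list(scheme)
               else scheme
    sat <- integer(0); obs <- integer(0); val <- numeric(0)
    geoms <- lapply(seq_len(nrow(pts)), function(i) {
      tv <- as.numeric(pts[i, ]); names(tv) <- labels
      suppressWarnings(build_geometry(template, tv))
    })
    for (sc in schemes) {
      acc <- numeric(length(sc$observed))
      for (i in seq_along(geoms)) {
        acc <- acc + wts[i] * frame_noe_scheme(geoms[[i]], template$atoms, sc)
      }
      sat <- c(sat, rep(sc$saturated, length(sc$observed)))
      obs <- c(obs, sc$observed)
      val <- c(val, acc)
    }
    noe <- normalize_noe(new_noe_table(template$atoms, sat, obs, val, FALSE))
  }
  structure(list(grid = grid, noe = noe, grid_step = grid_step,
                 temperature = potential$temperature),
            class = "ground_truth")
}

#' Basin populations of a ground-truth density
#'
#' Integrates the grid density of one torsion over periodic windows.
#'
#' @param gt a \code{\link{ground_truth}}.
#' @param label free-torsion label.
#' @param basin_windows list of \code{c(lo, hi)} windows as in
#'   \code{\link{basin_summary}}.
#' @return Numeric vector of populations, one per window.
#' @export
gt_populations <- function(gt, label, basin_windows) {
  g <- gt$grid[[label]]
  if (is.null(g)) stop("no grid for torsion '", label, "'")
  check_windows(basin_windows)
  vapply(basin_windows, function(w) sum(g$density[in_window(g$theta, w)]),
         numeric(1))
}
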