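# Glycosidic dihedral angles, periodic conformation/energy maps, basin
# statistics and transition counting.
#
# Angle convention: IUPAC signed torsion. For the quadruple a-b-c-d, looking
# along b -> c, a clockwise rotation carrying a onto d is positive. All
# angles live in [-180, 180) degrees.

#' Define a named torsion by an atom quadruple
#'
#' Glycosidic torsions are conventionally labelled phi (anomeric H/C through
#' the bridging O), psi (across the aglycone carbon) and omega (the exocyclic
#' C5-C6 rotation of 1-6 linkages), but the labels here are semantic tags
#' only: the geometry is fully determined by the explicit quadruple, so any
#' convention for phi/psi/omega can be expressed without ambiguity.
#'
#' @param label one of \code{"phi"}, \code{"psi"}, \code{"omega"} or a custom
#'   tag.
#' @param atom_quad four distinct atom ids (0-based) or atom names, in order
#'   a-b-c-d.
#' @param atoms optional \code{\link{atom_table}} used to resolve names and
#'   validate ids.
#' @return An object of class \code{"torsion_definition"}.
#' @export
torsion_definition <- function(label, atom_quad, atoms = NULL) {
  if (length(atom_quad) != 4) stop("atom_quad must have 4 entries")
  if (!is.null(atoms)) atom_quad <- resolve_atoms(atoms, atom_quad)
  atom_quad <- as.integer(atom_quad)
  if (anyDuplicated(atom_quad)) stop("atom_quad entries must be distinct")
  structure(list(label = as.character(label), atom_quad = atom_quad),
            class = "torsion_definition")
}

#' Signed dihedral angle of four points
#'
#' IUPAC convention: looking from b towards c, positive when the rotation
#' carrying the projection of a onto that of d is clockwise. Invariant under
#' rigid rotation and translation of the frame; negated by mirror reflection.
#'
#' @param frame n x 3 coordinate matrix (Angstrom).
#' @param quad a \code{\link{torsion_definition}} or 4 atom ids (0-based).
#' @return Angle in degrees in [-180, 180).
#' @export
dihedral <- function(frame, quad) {
  if (inherits(quad, "torsion_definition")) quad <- quad$atom_quad
  frame <- as_frame(frame)
  p <- frame[as.integer(quad) + 1L, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9) {
    stop("degenerate geometry: collinear atoms in torsion quadruple")
  }
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2 / sqrt(sum(b2^2)))
  wrap_angle(atan2(y, x) * 180 / pi)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# wrap degrees into [-180, 180)
wrap_angle <- function(x) {
  ((x + 180) %% 360) - 180
}

#' Select the pro-S proton of a geminal pair
#'
#' Of two hydrogens on the same (prochiral) carbon, the pro-S one is the
#' candidate whose replacement by a dummy group outranking all other
#' substituents gives the S configuration at the centre. With the dummy as
#' CIP rank 1 and the supplied neighbours as ranks 2-4, the configuration is
#' read off the sign of the signed volume det[v_h, v_p1, v_p2] of the
#' candidate and the two highest-priority neighbour vectors from the centre:
#' positive means S. Substituent priorities are supplied explicitly (full CIP
#' ranking is out of proportion for fixed molecular templates).
#'
#' @param frame n x 3 coordinate matrix.
#' @param center atom id of the prochiral carbon.
#' @param candidates the two geminal hydrogen atom ids.
#' @param priority_neighbors the three remaining substituent atom ids in
#'   descending CIP priority.
#' @param tol degeneracy guard on the normalized signed volume.
#' @return The pro-S candidate's atom id.
#' @export
select_pro_s <- function(frame, center, candidates, priority_neighbors,
                         tol = 1e-6) {
  if (length(candidates) != 2) stop("exactly two candidate hydrogens required")
  if (length(priority_neighbors) != 3) stop("three priority neighbors required")
  frame <- as_frame(frame)
  ctr <- frame[as.integer(center) + 1L, ]
  vols <- vapply(as.integer(candidates), function(h) {
    vh <- frame[h + 1L, ] - ctr
    v1 <- frame[as.integer(priority_neighbors[1]) + 1L, ] - ctr
    v2 <- frame[as.integer(priority_neighbors[2]) + 1L, ] - ctr
    det(rbind(vh, v1, v2)) /
      (sqrt(sum(vh^2)) * sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  }, numeric(1))
  if (any(abs(vols) < tol)) {
    stop("degenerate (near-planar) centre: signed volume below tolerance")
  }
  if (all(vols > 0) || all(vols < 0)) {
    stop("candidates classify identically; check centre/neighbour geometry")
  }
  as.integer(candidates)[which(vols > 0)]
}

#' Per-frame torsion angles of an ensemble
#'
#' @param ens an \code{\link{ensemble}}.
#' @param defs a list of \code{\link{torsion_definition}} objects (or a
#'   single one).
#' @return An object of class \code{"torsion_series"}: a list with
#'   \code{definitions} and \code{values}, a frames x torsions numeric matrix
#'   in degrees with columns named by label.
#' @export
torsion_series <- function(ens, defs) {
  if (inherits(defs, "torsion_definition")) defs <- list(defs)
  labels <- vapply(defs, function(d) d$label, "")
  if (anyDuplicated(labels)) stop("torsion labels must be unique")
  for (d in defs) {
    if (any(d$atom_quad >= nrow(ens$atoms))) {
      stop("torsion '", d$label, "' references atoms outside the atom table")
    }
  }
  vals <- matrix(NA_real_, length(ens$frames), length(defs),
                 dimnames = list(NULL, labels))
  for (i in seq_along(ens$frames)) {
    for (j in seq_along(defs)) {
      vals[i, j] <- tryCatch(dihedral(ens$frames[[i]], defs[[j]]),
        error = function(e) stop("frame ", i, ", torsion '", labels[j], "': ",
                                 conditionMessage(e), call. = FALSE))
    }
  }
  structure(list(definitions = defs, values = vals), class = "torsion_series")
}

#' Periodic conformation and free-energy map
#'
#' Bins a torsion series into a 1D or 2D periodic histogram over
#' [-180, 180) and converts relative density to a free-energy scale,
#' E = -kB*T*ln(p / p_max) in kcal/mol, so the densest bin is exactly 0 and
#' a basin boundary can be drawn at, e.g., +2 kcal/mol from the global
#' minimum. Empty bins carry NA energy (not infinity).
#'
#' @param series a \code{\link{torsion_series}}.
#' @param axes one or two torsion labels present in the series.
#' @param bin_width bin width in degrees; must divide 360 evenly (default 5).
#' @param temperature temperature in K for the energy scale (default 300).
#' @return An object of class \code{"conformation_map"}: list with
#'   \code{axes}, \code{breaks} (per-axis left bin edges), \code{density}
#'   (vector or matrix summing to 1), \code{energy} (same shape),
#'   \code{bin_width}, \code{temperature}.
#' @export
conformation_map <- function(series, axes, bin_width = 5, temperature = 300) {
  if (!inherits(series, "torsion_series")) stop("series must be a torsion_series")
  if (!(length(axes) %in% 1:2)) stop("axes must name one or two torsions")
  miss <- setdiff(axes, colnames(series$values))
  if (length(miss)) stop("axis label(s) not in series: ",
                         paste(miss, collapse = ", "))
  if (abs(360 / bin_width - round(360 / bin_width)) > 1e-9) {
    stop("bin_width must divide 360 evenly")
  }
  nb <- as.integer(round(360 / bin_width))
  edges <- -180 + bin_width * (seq_len(nb) - 1L)
  bin_of <- function(x) {
    pmin(nb, as.integer(floor((wrap_angle(x) + 180) / bin_width)) + 1L)
  }
  n <- nrow(series$values)
  if (length(axes) == 1) {
    counts <- tabulate(bin_of(series$values[, axes]), nbins = nb)
    density <- counts / n
  } else {
    i <- bin_of(series$values[, axes[1]])
    j <- bin_of(series$values[, axes[2]])
    counts <- matrix(tabulate((j - 1L) * nb + i, nbins = nb * nb), nb, nb)
    density <- counts / n
    dimnames(density) <- list(format(edges), format(edges))
  }
  pmax_ <- max(density)
  energy <- -kT(temperature) * log(density / pmax_)
  energy[density == 0] <- NA_real_
  structure(list(axes = axes, breaks = edges, density = density,
                 energy = energy, bin_width = bin_width,
                 temperature = temperature),
            class = "conformation_map")
}

#' Export a conformation map as delimited text
#'
#' One row per bin with the axis bin centres, density and energy.
#'
#' @param map a \code{\link{conformation_map}}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_conformation_map <- function(map, path) {
  ctr <- map$breaks + map$bin_width / 2
  if (length(map$axes) == 1) {
    df <- data.frame(ctr, density = as.vector(map$density),
                     energy = as.vector(map$energy))
    names(df)[1] <- map$axes[1]
  } else {
    g <- expand.grid(a1 = ctr, a2 = ctr)
    df <- data.frame(g$a1, g$a2, density = as.vector(map$density),
                     energy = as.vector(map$energy))
    names(df)[1:2] <- map$axes
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Normalize a window to c(lo, hi) in [-180, 180); membership is the periodic
# arc from lo (inclusive) counterclockwise to hi (exclusive); lo > hi wraps.
in_window <- function(x, w) {
  x <- wrap_angle(x)
  lo <- wrap_angle(w[1]); hi <- wrap_angle(w[2])
  if (lo <= hi) x >= lo & x < hi else x >= lo | x < hi
}

check_windows <- function(windows) {
  if (!length(windows)) stop("at least one basin window required")
  grid <- seq(-180, 179.75, by = 0.25)
  cover <- rowSums(vapply(windows, function(w) in_window(grid, w),
                          logical(length(grid))))
  if (any(cover > 1)) stop("basin windows overlap on the circle")
  invisible(TRUE)
}

# per-frame basin index (NA outside all windows)
assign_basins <- function(x, windows) {
  out <- rep(NA_integer_, length(x))
  for (k in seq_along(windows)) out[in_window(x, windows[[k]])] <- k
  out
}

#' Basin populations and circular statistics of a torsion
#'
#' Assigns frames to user-specified periodic windows on one torsion axis and
#' reports, per window, the circular mean (degrees), circular standard
#' deviation (degrees, sqrt(-2 ln Rbar) of the mean resultant length) and
#' the population fraction of frames, plus the unassigned remainder. This is
#' the quantitative form of statements like "56.5 +/- 16.5 (88%)" for a
#' rotamer distribution.
#'
#' @param series a \code{\link{torsion_series}}.
#' @param axis torsion label.
#' @param basin_windows list of length-2 numeric vectors \code{c(lo, hi)} in
#'   degrees; a window with lo > hi wraps through 180/-180. Windows must not
#'   overlap.
#' @return A data frame of class \code{"basin_summary"} with one row per
#'   window (columns \code{mean}, \code{sd}, \code{population}) and an
#'   attribute \code{unassigned} with the leftover fraction.
#' @export
basin_summary <- function(series, axis, basin_windows) {
  if (!axis %in% colnames(series$values)) stop("axis not in series: ", axis)
  check_windows(basin_windows)
  x <- series$values[, axis]
  b <- assign_basins(x, basin_windows)
  rows <- lapply(seq_along(basin_windows), function(k) {
    xs <- x[!is.na(b) & b == k]
    if (!length(xs)) {
      return(data.frame(mean = NA_real_, sd = NA_real_, population = 0))
    }
    rad <- xs * pi / 180
    s <- mean(sin(rad)); c_ <- mean(cos(rad))
    rbar <- sqrt(s^2 + c_^2)
    data.frame(mean = wrap_angle(atan2(s, c_) * 180 / pi),
               sd = sqrt(max(0, -2 * log(rbar))) * 180 / pi,
               population = length(xs) / length(x))
  })
  out <- do.call(rbind, rows)
  out$window_lo <- vapply(basin_windows, `[`, 0, 1)
  out$window_hi <- vapply(basin_windows, `[`, 0, 2)
  attr(out, "unassigned") <- mean(is.na(b))
  class(out) <- c("basin_summary", "data.frame")
  out
}

#' Count inter-basin transitions along a trajectory
#'
#' Counts changes of basin assignment between consecutive assigned frames;
#' frames outside every window are skipped (they neither count as a
#' transition nor break the sequence).
#'
#' @inheritParams basin_summary
#' @return Integer transition count.
#' @export
transition_count <- function(series, axis, basin_windows) {
  if (!axis %in% colnames(series$values)) stop("axis not in series: ", axis)
  check_windows(basin_windows)
  b <- assign_basins(series$values[, axis], basin_windows)
  b <- b[!is.na(b)]
  if (length(b) < 2) return(0L)
  sum(diff(b) != 0L)
}
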