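# Steady-state NOE prediction from conformational ensembles.
#
# Per frame, the NOE observed on proton a upon saturation of proton b is
#
#   NOE_a(b) = r_ab^-6 / (2 * sum_{i != a} r_ai^-6)
#
# with the sum over all non-exchangeable hydrogens i of the molecule
# (including b). Exchangeable protons (-OH, -NH2, -COOH) are excluded from
# both the numerator and the sum. Frame values are arithmetically averaged
# over the ensemble, and predicted tables are normalized per saturated
# proton so simulated and experimental intensities are compared on the same
# scale. Spin diffusion and correlation-function treatments are deliberately
# out of scope.

#' Define a saturation scheme
#'
#' One saturated proton and the list of protons whose NOE response is
#' reported experimentally. All must be non-exchangeable hydrogens.
#'
#' @param saturated atom id or name of the saturated proton b.
#' @param observed atom ids or names of the observed protons a.
#' @param atoms optional \code{\link{atom_table}} for name resolution and
#'   validation.
#' @return An object of class \code{"saturation_scheme"}.
#' @export
saturation_scheme <- function(saturated, observed, atoms = NULL) {
  if (!is.null(atoms)) {
    saturated <- resolve_atoms(atoms, saturated)
    observed <- resolve_atoms(atoms, observed)
    ids <- c(saturated, observed)
    bad <- ids[atoms$element[ids + 1L] != "H" | atoms$exchangeable[ids + 1L]]
    if (length(bad)) {
      stop("saturation scheme atoms must be non-exchangeable hydrogens: ",
           paste(atoms$name[bad + 1L], collapse = ", "))
    }
  }
  saturated <- as.integer(saturated)
  observed <- as.integer(observed)
  if (length(saturated) != 1) stop("exactly one saturated proton")
  if (!length(observed)) stop("at least one observed proton")
  if (saturated %in% observed) stop("saturated proton cannot be observed")
  structure(list(saturated = saturated, observed = observed),
            class = "saturation_scheme")
}

#' Single-frame steady-state NOE
#'
#' @param frame n x 3 coordinate matrix (Angstrom).
#' @param atoms an \code{\link{atom_table}}.
#' @param a observed proton atom id.
#' @param b saturated proton atom id.
#' @return Raw NOE value in (0, 0.5]; 0.5 exactly when b is the only other
#'   non-exchangeable proton.
#' @export
frame_noe <- function(frame, atoms, a, b) {
  frame <- as_frame(frame, nrow(atoms))
  a <- as.integer(a); b <- as.integer(b)
  if (a == b) stop("observed and saturated protons must differ")
  for (id in c(a, b)) {
    if (atoms$element[id + 1L] != "H" || atoms$exchangeable[id + 1L]) {
      stop("atom ", atoms$name[id + 1L],
           " is not a non-exchangeable hydrogen")
    }
  }
  h <- atoms$atom_id[atoms$element == "H" & !atoms$exchangeable]
  others <- setdiff(h, a)
  d2 <- colSums((t(frame[others + 1L, , drop = FALSE]) - frame[a + 1L, ])^2)
  if (any(d2 < 0.01)) {
    stop("coincident protons (r < 0.1 A) involving atom ",
         atoms$name[a + 1L])
  }
  inv6 <- d2^(-3)
  inv6[match(b, others)] / (2 * sum(inv6))
}

# Vectorized helper: raw NOE of every observed proton of one scheme for one
# frame. Equivalent to frame_noe per pair but computes the distance rows once.
frame_noe_scheme <- function(frame, atoms, scheme) {
  h <- atoms$atom_id[atoms$element == "H" & !atoms$exchangeable]
  vapply(scheme$observed, function(a) {
    others <- setdiff(h, a)
    d2 <- colSums((t(frame[others + 1L, , drop = FALSE]) - frame[a + 1L, ])^2)
    if (any(d2 < 0.01)) {
      stop("coincident protons (r < 0.1 A) involving atom ",
           atoms$name[a + 1L])
    }
    inv6 <- d2^(-3)
    inv6[match(scheme$saturated, others)] / (2 * sum(inv6))
  }, numeric(1))
}

new_noe_table <- function(atoms, saturated, observed, value, normalized) {
  stopifnot(length(saturated) == length(observed),
            length(value) == length(observed))
  out <- data.frame(
    saturated = atoms$name[saturated + 1L],
    observed = atoms$name[observed + 1L],
    value = value,
    transglycosidic = atoms$residue_index[saturated + 1L] !=
      atoms$residue_index[observed + 1L],
    stringsAsFactors = FALSE
  )
  attr(out, "normalized") <- normalized
  class(out) <- c("noe_table", "data.frame")
  out
}

#' Ensemble-averaged NOE table
#'
#' Computes the raw per-frame NOE for every (saturated, observed) pair of the
#' scheme(s) and averages arithmetically over frames. Entries are flagged
#' transglycosidic when the two protons sit in different residues.
#'
#' @param ens an \code{\link{ensemble}}.
#' @param scheme a \code{\link{saturation_scheme}} or a list of them.
#' @param weights optional per-frame weights (non-negative, summing to
#'   anything positive); default uniform. Used internally for Boltzmann
#'   averaging.
#' @return A \code{"noe_table"} data frame with columns \code{saturated},
#'   \code{observed}, \code{value} (raw), \code{transglycosidic}.
#' @export
ensemble_noe <- function(ens, scheme, weights = NULL) {
  if (!inherits(ens, "ensemble")) stop("ens must be an ensemble")
  schemes <- if (inherits(scheme, "saturation_scheme")) list(scheme) else scheme
  nf <- length(ens$frames)
  if (is.null(weights)) {
    weights <- rep(1 / nf, nf)
  } else {
    if (length(weights) != nf) stop("one weight per frame required")
    if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
    weights <- weights / sum(weights)
  }
  sat <- integer(0); obs <- integer(0); val <- numeric(0)
  for (sc in schemes) {
    acc <- numeric(length(sc$observed))
    for (i in seq_len(nf)) {
      v <- tryCatch(frame_noe_scheme(ens$frames[[i]], ens$atoms, sc),
        error = function(e) stop("frame ", i, ": ", conditionMessage(e),
                                 call. = FALSE))
      acc <- acc + weights[i] * v
    }
    sat <- c(sat, rep(sc$saturated, length(sc$observed)))
    obs <- c(obs, sc$observed)
    val <- c(val, acc)
  }
  new_noe_table(ens$atoms, sat, obs, val, normalized = FALSE)
}

#' Normalize an NOE table per saturated proton
#'
#' Divides each entry by the sum of raw values over the observed set of its
#' saturated proton, so normalized intensities sum to 1 within each
#' saturation group. Experimental tables are normalized the same way before
#' comparison.
#'
#' @param table a \code{"noe_table"} (raw values).
#' @return The table with \code{value} replaced by normalized values.
#' @export
normalize_noe <- function(table) {
  if (!all(c("saturated", "observed", "value") %in% names(table))) {
    stop("not an NOE table")
  }
  if (any(table$value < 0)) stop("NOE values must be non-negative")
  sums <- tapply(table$value, table$saturated, sum)
  zero <- names(sums)[sums <= 0]
  if (length(zero)) {
    stop("zero NOE sum for saturated proton(s): ",
         paste(zero, collapse = ", "))
  }
  table$value <- table$value / as.numeric(sums[table$saturated])
  attr(table, "normalized") <- TRUE
  table
}

#' Boltzmann-weighted NOE over discrete conformers
#'
#' For conformers with free energies G_j (kcal/mol), weights are
#' w_j = exp(-(G_j - G_min)/RT) normalized to 1; the NOE is the weighted
#' average of per-conformer values, then normalized per saturated proton.
#' This is the averaging mode used with cluster-medoid conformers whose free
#' energies come from quantum-chemical calculations.
#'
#' @param conformers list of coordinate matrices, or an
#'   \code{\link{ensemble}} whose frames are the conformers.
#' @param free_energies numeric vector, kcal/mol, one per conformer.
#' @param scheme a \code{\link{saturation_scheme}} or list of them.
#' @param atoms an \code{\link{atom_table}}; not needed when
#'   \code{conformers} is an ensemble.
#' @param temperature temperature in K (default 300).
#' @return A normalized \code{"noe_table"}.
#' @export
boltzmann_noe <- function(conformers, free_energies, scheme, atoms = NULL,
                          temperature = 300) {
  if (inherits(conformers, "ensemble")) {
    ens <- conformers
  } else {
    if (is.null(atoms)) stop("atoms required when conformers is a list")
    ens <- ensemble(atoms, conformers)
  }
  if (length(free_energies) != length(ens$frames)) {
    stop("need one free energy per conformer (",
         length(ens$frames), " conformers, ", length(free_energies),
         " energies)")
  }
  w <- exp(-(free_energies - min(free_energies)) / kT(temperature))
  normalize_noe(ensemble_noe(ens, scheme, weights = w))
}

#' Read or write an NOE table as delimited text
#'
#' Columns \code{saturated}, \code{observed}, \code{value} and (on write,
#' and optionally on read) \code{transglycosidic}. Used both for
#' experimental input tables and for exporting predictions.
#'
#' @param path file path.
#' @param atoms optional \code{\link{atom_table}}; when given, the
#'   transglycosidic flag is (re)derived from residue indices.
#' @return \code{read_noe_table}: a \code{"noe_table"}.
#' @export
read_noe_table <- function(path, atoms = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("saturated", "observed", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("NOE table file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.null(atoms)) {
    s <- resolve_atoms(atoms, df$saturated)
    o <- resolve_atoms(atoms, df$observed)
    df$transglycosidic <- atoms$residue_index[s + 1L] !=
      atoms$residue_index[o + 1L]
  } else if (is.null(df$transglycosidic)) {
    df$transglycosidic <- NA
  }
  df <- df[, c("saturated", "observed", "value", "transglycosidic")]
  attr(df, "normalized") <- FALSE
  class(df) <- c("noe_table", "data.frame")
  df
}

#' @rdname read_noe_table
#' @param table a \code{"noe_table"}.
#' @return \code{write_noe_table}: the path, invisibly.
#' @export
write_noe_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
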