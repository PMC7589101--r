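# Atom metadata table shared by all frames of an ensemble.

# Element symbols accepted by the parsers. Covers everything occurring in
# carbohydrate work plus the common heteroatoms.
.known_elements <- c(
  "H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "B", "Si", "Se", "Na",
  "K", "Mg", "Ca", "Zn", "Fe"
)

#' Construct an atom metadata table
#'
#' An \code{atom_table} stores per-atom metadata shared by every frame of an
#' ensemble: the atom name (e.g. \code{"H1"}, \code{"C1"}, \code{"O5"}), the
#' chemical element, the 1-based residue ordinal within the molecule, and
#' whether the atom is an exchangeable proton (bonded to O or N, e.g. hydroxyl
#' or amine hydrogens). Exchangeable protons exchange with solvent on the NMR
#' timescale and are excluded from every NOE summation.
#'
#' @param name character vector of atom labels.
#' @param element character vector of element symbols.
#' @param residue_index integer vector of 1-based residue ordinals.
#' @param exchangeable logical vector; \code{TRUE} only allowed for hydrogens.
#'   Use \code{\link{infer_exchangeable}} to derive it from geometry.
#' @return A data frame of class \code{"atom_table"} with columns
#'   \code{atom_id} (0-based, contiguous), \code{name}, \code{element},
#'   \code{residue_index}, \code{exchangeable}.
#' @examples
#' atom_table(c("C1", "H1", "O1", "HO1"), c("C", "H", "O", "H"),
#'            residue_index = c(1, 1, 1, 1),
#'            exchangeable = c(FALSE, FALSE, FALSE, TRUE))
#' @export
atom_table <- function(name, element, residue_index,
                       exchangeable = rep(FALSE, length(name))) {
  n <- length(name)
  stopifnot(length(element) == n, length(residue_index) == n,
            length(exchangeable) == n)
  element <- as.character(element)
  if (any(!nzchar(element))) {
    stop("atom_table: empty element symbol at atom(s) ",
         paste(which(!nzchar(element)) - 1L, collapse = ", "))
  }
  bad <- setdiff(unique(element), .known_elements)
  if (length(bad)) {
    stop("atom_table: unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  exchangeable <- as.logical(exchangeable)
  if (any(exchangeable & element != "H")) {
    stop("atom_table: exchangeable=TRUE requires element H (atom ",
         paste(which(exchangeable & element != "H") - 1L, collapse = ", "), ")")
  }
  out <- data.frame(
    atom_id = seq_len(n) - 1L,
    name = as.character(name),
    element = element,
    residue_index = as.integer(residue_index),
    exchangeable = exchangeable,
    stringsAsFactors = FALSE
  )
  class(out) <- c("atom_table", "data.frame")
  out
}

#' Infer exchangeable-proton flags from a reference geometry
#'
#' A hydrogen is flagged exchangeable when its nearest non-hydrogen atom in
#' the supplied frame lies within \code{cutoff} and is oxygen or nitrogen
#' (hydroxyl, amine, carboxyl protons). Trajectories carry no bond table, so
#' covalent attachment is read off the geometry; 1.2 Angstrom comfortably
#' covers O-H (~0.96) and N-H (~1.01) bonds while excluding any non-bonded
#' contact.
#'
#' @param atoms an \code{\link{atom_table}} (its \code{exchangeable} column is
#'   ignored and recomputed).
#' @param frame numeric n x 3 coordinate matrix (Angstrom), typically the
#'   first frame of the ensemble.
#' @param cutoff bond-detection distance in Angstrom (default 1.2).
#' @return The atom table with the \code{exchangeable} column replaced.
#' @export
infer_exchangeable <- function(atoms, frame, cutoff = 1.2) {
  frame <- as_frame(frame, nrow(atoms))
  is_h <- atoms$element == "H"
  heavy <- which(!is_h)
  exch <- rep(FALSE, nrow(atoms))
  if (length(heavy)) {
    for (h in which(is_h)) {
      d2 <- colSums((t(frame[heavy, , drop = FALSE]) - frame[h, ])^2)
      j <- heavy[which.min(d2)]
      if (sqrt(min(d2)) < cutoff && atoms$element[j] %in% c("O", "N")) {
        exch[h] <- TRUE
      }
    }
  }
  atoms$exchangeable <- exch
  atoms
}

#' Read or write an atom-metadata override table
#'
#' Delimited-text representation of an \code{\link{atom_table}} with columns
#' \code{atom_id}, \code{name}, \code{element}, \code{residue_index},
#' \code{exchangeable}, used to override metadata inferred from a trajectory
#' file.
#'
#' @param path file path.
#' @return \code{read_atom_table}: an \code{\link{atom_table}}.
#' @export
read_atom_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("atom_id", "name", "element", "residue_index", "exchangeable")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("atom table file missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[order(df$atom_id), ]
  if (!identical(as.integer(df$atom_id), seq_len(nrow(df)) - 1L)) {
    stop("atom table file: atom_id must be 0-based and contiguous")
  }
  atom_table(df$name, df$element, df$residue_index, as.logical(df$exchangeable))
}

#' @rdname read_atom_table
#' @param atoms an \code{\link{atom_table}}.
#' @return \code{write_atom_table}: the path, invisibly.
#' @export
write_atom_table <- function(atoms, path) {
  utils::write.table(as.data.frame(atoms), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Resolve atom names or ids to 0-based atom ids against an atom table.
# Numeric input is taken as atom_id; character input is matched against name
# (must be unambiguous).
resolve_atoms <- function(atoms, x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    bad <- setdiff(x, atoms$atom_id)
    if (length(bad)) stop("unknown atom_id(s): ", paste(bad, collapse = ", "))
    return(x)
  }
  idx <- match(x, atoms$name)
  if (anyNA(idx)) stop("unknown atom name(s): ",
                       paste(x[is.na(idx)], collapse = ", "))
  dup <- x[x %in% atoms$name[duplicated(atoms$name)]]
  if (length(dup)) stop("ambiguous atom name(s): ",
                        paste(unique(dup), collapse = ", "))
  atoms$atom_id[idx]
}

# Coerce a frame to an n x 3 numeric matrix and validate.
as_frame <- function(frame, n_atoms = NULL) {
  frame <- as.matrix(frame)
  if (ncol(frame) != 3) stop("frame must have 3 columns (x, y, z)")
  if (!is.null(n_atoms) && nrow(frame) != n_atoms) {
    stop("frame has ", nrow(frame), " atoms, expected ", n_atoms)
  }
  if (!all(is.finite(frame))) stop("frame contains non-finite coordinates")
  storage.mode(frame) <- "double"
  frame
}
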