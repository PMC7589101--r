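# Built-in molecular templates: a 10-atom two-residue toy for fast tests and
# a 37-atom disaccharide-like template (two pyranose-style rings with
# explicit hydrogens and hydroxyls joined by a glycosidic oxygen, free phi
# and psi). Bond lengths/angles are idealized (C-C 1.54, C-O 1.43, C-H 1.09,
# O-H 0.96 Angstrom, tetrahedral angles); rings are built as near-closing
# chair-like chains. The templates are deliberately generic: the point is a
# rigid covalent scaffold with known free torsions, not any specific sugar.

# row constructor for the z-matrix tables below (ids are 0-based)
zrow <- function(name, element, res, parent = NA, gp = NA, ggp = NA,
                 bond = NA, angle = NA, torsion = NA) {
  data.frame(name = name, element = element, res = res, parent = parent,
             grandparent = gp, greatgrand = ggp, bond = bond, angle = angle,
             torsion = torsion, stringsAsFactors = FALSE)
}

finish_template <- function(rows, free_torsions, exchangeable_names) {
  z <- do.call(rbind, rows)
  atoms <- atom_table(z$name, z$element, z$res,
                      exchangeable = z$name %in% exchangeable_names)
  id <- function(nm) atoms$atom_id[match(nm, atoms$name)]
  ft <- lapply(free_torsions, function(f) {
    list(rows = id(f$rows), offsets = f$offsets, quad = id(f$quad))
  })
  molecular_template(atoms,
                     z[, c("parent", "grandparent", "greatgrand",
                           "bond", "angle", "torsion")],
                     ft)
}

#' Minimal two-residue toy template
#'
#' Ten atoms: a methyl group (residue 1) joined through an ether oxygen to a
#' CH2-OH carbon (residue 2). One free torsion \code{"phi"} =
#' C1-O-C2-H21 rotating the residue-2 group about the O-C2 bond. The
#' hydroxyl proton HO2 is exchangeable, so NOE sums run over the five
#' methyl/methylene protons only.
#'
#' @return A \code{\link{molecular_template}}.
#' @export
template_toy <- function() {
  tet <- 109.47
  rows <- list(
    zrow("C1", "C", 1),
    zrow("O",  "O", 1, parent = 0, bond = 1.43),
    zrow("C2", "C", 2, parent = 1, gp = 0, bond = 1.43, angle = 112),
    zrow("H11", "H", 1, parent = 0, gp = 1, ggp = 2, bond = 1.09,
         angle = tet, torsion = 60),
    zrow("H12", "H", 1, parent = 0, gp = 1, ggp = 2, bond = 1.09,
         angle = tet, torsion = -60),
    zrow("H13", "H", 1, parent = 0, gp = 1, ggp = 2, bond = 1.09,
         angle = tet, torsion = 180),
    zrow("H21", "H", 2, parent = 2, gp = 1, ggp = 0, bond = 1.09,
         angle = tet, torsion = 60),
    zrow("H22", "H", 2, parent = 2, gp = 1, ggp = 0, bond = 1.09,
         angle = tet, torsion = -60),
    zrow("O2", "O", 2, parent = 2, gp = 1, ggp = 0, bond = 1.43,
         angle = tet, torsion = 180),
    zrow("HO2", "H", 2, parent = 8, gp = 2, ggp = 1, bond = 0.96,
         angle = tet, torsion = 180)
  )
  ft <- list(phi = list(rows = c("H21", "H22", "O2"),
                        offsets = c(0, -120, 120),
                        quad = c("C1", "O", "C2", "H21")))
  finish_template(rows, ft, exchangeable_names = "HO2")
}

#' Disaccharide-like two-ring template
#'
#' Thirty-seven atoms in two residues: two pentopyranose-style rings with
#' explicit hydrogens and hydroxyl groups (exchangeable protons) joined
#' anomeric-to-anomeric through a glycosidic oxygen OG (a trehalose-type
#' 1-1' linkage). Two free torsions: \code{"phi"} = H1-C1-OG-C1B (rotation
#' about the residue-1 anomeric bond) and \code{"psi"} = C1-OG-C1B-H1B
#' (rotation about the residue-2 anomeric bond), the classic glycosidic
#' pair. Residue-2 atom names carry a \code{B} suffix.
#'
#' @return A \code{\link{molecular_template}}.
#' @export
template_disaccharide <- function() {
  tet <- 109.47
  rows <- list(
    # residue 1 ring: C1 -> O5 -> C5 -> C4 -> C3 -> C2 (chair-like chain,
    # closure C2~C1 arrives near torsion -64 about C1-O5)
    zrow("C1", "C", 1),
    zrow("O5", "O", 1, parent = 0, bond = 1.43),
    zrow("C5", "C", 1, parent = 1, gp = 0, bond = 1.43, angle = 112),
    zrow("C4", "C", 1, parent = 2, gp = 1, ggp = 0, bond = 1.54,
         angle = 110, torsion = 60),
    zrow("C3", "C", 1, parent = 3, gp = 2, ggp = 1, bond = 1.54,
         angle = 111, torsion = -55),
    zrow("C2", "C", 1, parent = 4, gp = 3, ggp = 2, bond = 1.54,
         angle = 111, torsion = 55),
    # anomeric substituents about C1-O5 (closure occupies ~ -64)
    zrow("H1", "H", 1, parent = 0, gp = 1, ggp = 2, bond = 1.09,
         angle = tet, torsion = 178),
    zrow("OG", "O", 1, parent = 0, gp = 1, ggp = 2, bond = 1.43,
         angle = tet, torsion = 57),
    # ring-carbon substituents, residue 1
    zrow("H5A", "H", 1, parent = 2, gp = 1, ggp = 0, bond = 1.09,
         angle = tet, torsion = 180),
    zrow("H5B", "H", 1, parent = 2, gp = 1, ggp = 0, bond = 1.09,
         angle = tet, torsion = -60),
    zrow("H4", "H", 1, parent = 3, gp = 2, ggp = 1, bond = 1.09,
         angle = tet, torsion = -175),
    zrow("O4", "O", 1, parent = 3, gp = 2, ggp = 1, bond = 1.43,
         angle = tet, torsion = 65),
    zrow("HO4", "H", 1, parent = 11, gp = 3, ggp = 2, bond = 0.96,
         angle = 108, torsion = 180),
    zrow("H3", "H", 1, parent = 4, gp = 3, ggp = 2, bond = 1.09,
         angle = tet, torsion = 175),
    zrow("O3", "O", 1, parent = 4, gp = 3, ggp = 2, bond = 1.43,
         angle = tet, torsion = -65),
    zrow("HO3", "H", 1, parent = 14, gp = 4, ggp = 3, bond = 0.96,
         angle = 108, torsion = 60),
    zrow("H2", "H", 1, parent = 5, gp = 4, ggp = 3, bond = 1.09,
         angle = tet, torsion = 65),
    zrow("O2", "O", 1, parent = 5, gp = 4, ggp = 3, bond = 1.43,
         angle = tet, torsion = -175),
    zrow("HO2", "H", 1, parent = 17, gp = 5, ggp = 4, bond = 0.96,
         angle = 108, torsion = 180),
    # glycosidic link: C1B placed by phi, its substituents by psi
    zrow("C1B", "C", 2, parent = 7, gp = 0, ggp = 6, bond = 1.43,
         angle = 116, torsion = -60),           # phi row (ggp = H1)
    zrow("H1B", "H", 2, parent = 19, gp = 7, ggp = 0, bond = 1.09,
         angle = tet, torsion = 60),            # psi row
    zrow("O5B", "O", 2, parent = 19, gp = 7, ggp = 0, bond = 1.43,
         angle = tet, torsion = -60),           # psi - 120 (offset)
    # residue 2 ring: O5B -> C5B -> C4B -> C3B -> C2B (closure C2B~C1B)
    zrow("C5B", "C", 2, parent = 21, gp = 19, ggp = 7, bond = 1.43,
         angle = 112, torsion = 175),
    zrow("C4B", "C", 2, parent = 22, gp = 21, ggp = 19, bond = 1.54,
         angle = 110, torsion = 60),
    zrow("C3B", "C", 2, parent = 23, gp = 22, ggp = 21, bond = 1.54,
         angle = 111, torsion = -55),
    zrow("C2B", "C", 2, parent = 24, gp = 23, ggp = 22, bond = 1.54,
         angle = 111, torsion = 55),
    # ring-carbon substituents, residue 2
    zrow("H5BA", "H", 2, parent = 22, gp = 21, ggp = 19, bond = 1.09,
         angle = tet, torsion = 180),
    zrow("H5BB", "H", 2, parent = 22, gp = 21, ggp = 19, bond = 1.09,
         angle = tet, torsion = -60),
    zrow("H4B", "H", 2, parent = 23, gp = 22, ggp = 21, bond = 1.09,
         angle = tet, torsion = -175),
    zrow("O4B", "O", 2, parent = 23, gp = 22, ggp = 21, bond = 1.43,
         angle = tet, torsion = 65),
    zrow("HO4B", "H", 2, parent = 29, gp = 23, ggp = 22, bond = 0.96,
         angle = 108, torsion = 180),
    zrow("H3B", "H", 2, parent = 24, gp = 23, ggp = 22, bond = 1.09,
         angle = tet, torsion = 175),
    zrow("O3B", "O", 2, parent = 24, gp = 23, ggp = 22, bond = 1.43,
         angle = tet, torsion = -65),
    zrow("HO3B", "H", 2, parent = 32, gp = 24, ggp = 23, bond = 0.96,
         angle = 108, torsion = 180),
    zrow("H2B", "H", 2, parent = 25, gp = 24, ggp = 23, bond = 1.09,
         angle = tet, torsion = 65),
    zrow("O2B", "O", 2, parent = 25, gp = 24, ggp = 23, bond = 1.43,
         angle = tet, torsion = -175),
    zrow("HO2B", "H", 2, parent = 35, gp = 25, ggp = 24, bond = 0.96,
         angle = 108, torsion = 60)
  )
  ft <- list(
    phi = list(rows = "C1B", offsets = 0,
               quad = c("H1", "C1", "OG", "C1B")),
    psi = list(rows = c("H1B", "O5B"), offsets = c(0, -120),
               quad = c("C1", "OG", "C1B", "H1B"))
  )
  finish_template(rows, ft,
                  exchangeable_names = c("HO4", "HO3", "HO2", "HO4B",
                                         "HO3B", "HO2B"))
}

#' Default three-state glycosidic potential
#'
#' A single-well phi torsion (centre -60 deg, depth 3 kcal/mol, width 20
#' deg) and a three-well psi torsion with wells at 60, -60 and 180 deg
#' (width 25 deg) whose depths are calibrated by grid integration so the
#' Boltzmann populations of the windows (0, 120), (-120, 0) and
#' (120, -120) at 300 K are 0.85, 0.12 and 0.03 — a dominant rotamer, a
#' minor one and a sparsely visited third, the typical population pattern
#' of a glycosidic linkage.
#'
#' @param temperature temperature in K (default 300).
#' @return A \code{\link{torsional_potential}}.
#' @export
potential_three_state <- function(temperature = 300) {
  torsional_potential(list(
    phi = list(center = -60, depth = 3, width = 20),
    psi = list(center = c(60, -60, 180),
               depth = .psi_depths,
               width = c(25, 25, 25))
  ), temperature = temperature)
}

# psi well depths (kcal/mol) giving window populations 0.85/0.12/0.03 at
# 300 K on a 1-degree grid; solved once by fixed-point iteration on the
# grid integrals and frozen.
.psi_depths <- c(3.5, 2.14382939, 1.04514377)

#' Standard basin windows of the three-state psi torsion
#'
#' @return List of \code{c(lo, hi)} windows matching
#'   \code{\link{potential_three_state}}: (0, 120), (-120, 0),
#'   (120, -120) degrees.
#' @export
psi_windows <- function() {
  list(c(0, 120), c(-120, 0), c(120, -120))
}
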