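# Multi-frame trajectory container and file I/O (multi-frame XYZ,
# multi-model PDB). Coordinates are Angstrom throughout the package.

#' Construct a conformational ensemble
#'
#' An \code{ensemble} ties an ordered list of Cartesian coordinate frames
#' (Angstrom) to one shared \code{\link{atom_table}}.
#'
#' @param atoms an \code{\link{atom_table}}.
#' @param frames list of n_atoms x 3 numeric matrices, one per frame.
#' @param frame_interval optional time between stored frames (ps).
#' @return An object of class \code{"ensemble"} with elements \code{atoms},
#'   \code{frames}, \code{frame_interval}.
#' @export
ensemble <- function(atoms, frames, frame_interval = NA_real_) {
  if (!inherits(atoms, "atom_table")) stop("atoms must be an atom_table")
  if (!is.list(frames) || length(frames) < 1) {
    stop("ensemble requires at least one frame")
  }
  n <- nrow(atoms)
  frames <- lapply(seq_along(frames), function(i) {
    tryCatch(as_frame(frames[[i]], n),
             error = function(e) stop("frame ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
  structure(list(atoms = atoms, frames = frames,
                 frame_interval = as.numeric(frame_interval)),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble:", length(x$frames), "frame(s),", nrow(x$atoms), "atoms,",
      sum(x$atoms$element == "H" & !x$atoms$exchangeable),
      "non-exchangeable protons\n")
  if (!is.na(x$frame_interval)) {
    cat("frame interval:", x$frame_interval, "ps\n")
  }
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens an \code{\link{ensemble}}.
#' @return integer frame count.
#' @export
n_frames <- function(ens) length(ens$frames)

#' Read a multi-frame trajectory
#'
#' Two plain-text dialects are supported. \emph{Multi-frame XYZ}: repeated
#' blocks of an atom-count line, a comment line, then one
#' \code{Element x y z} record per atom. \emph{Multi-model PDB}:
#' MODEL/ENDMDL-delimited standard PDB, parsed via \pkg{bio3d}; atom names,
#' elements and 1-based residue numbers are taken from the ATOM/HETATM
#' records. XYZ files carry no residue or name metadata, so all atoms land in
#' residue 1 with names \code{<El><ordinal>} unless \code{metadata} supplies
#' an \code{\link{atom_table}} override. Exchangeable-proton flags are
#' inferred from the first frame with \code{\link{infer_exchangeable}} unless
#' overridden.
#'
#' @param path file path.
#' @param format \code{"xyz"} or \code{"pdb"}; default guesses from the file
#'   extension.
#' @param metadata optional \code{\link{atom_table}} overriding all metadata
#'   (its row count must match the file).
#' @return An \code{\link{ensemble}}.
#' @export
read_ensemble <- function(path, format = c("auto", "xyz", "pdb"),
                          metadata = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- if (format == "xyz") read_xyz_frames(path) else read_pdb_frames(path)
  atoms <- parsed$atoms
  if (!is.null(metadata)) {
    if (!inherits(metadata, "atom_table")) stop("metadata must be an atom_table")
    if (nrow(metadata) != nrow(atoms)) {
      stop("metadata has ", nrow(metadata), " atoms but file has ", nrow(atoms))
    }
    atoms <- metadata
  } else {
    atoms <- infer_exchangeable(atoms, parsed$frames[[1]])
  }
  ensemble(atoms, parsed$frames)
}

read_xyz_frames <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (!length(lines)) stop("empty XYZ file: ", path)
  frames <- list()
  i <- 1L
  fidx <- 0L
  n0 <- NA_integer_
  elements0 <- NULL
  while (i <= length(lines)) {
    fidx <- fidx + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) {
      stop("XYZ parse error in frame ", fidx, ": bad atom-count line ", i)
    }
    if (is.na(n0)) n0 <- n
    if (n != n0) {
      stop("XYZ parse error: frame ", fidx, " lists ", n,
           " atoms while frame 1 lists ", n0)
    }
    if (i + 1L + n > length(lines)) {
      stop("XYZ parse error: frame ", fidx, " truncated")
    }
    rec <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(rec), "[[:space:]]+")
    nt <- lengths(tok)
    if (any(nt < 4)) {
      stop("XYZ parse error in frame ", fidx, ": malformed record(s)")
    }
    el <- vapply(tok, `[[`, "", 1L)
    if (is.null(elements0)) {
      elements0 <- el
      bad <- setdiff(unique(el), .known_elements)
      if (length(bad)) {
        stop("XYZ parse error in frame ", fidx, ": unknown element symbol(s) ",
             paste(bad, collapse = ", "))
      }
    } else if (!identical(el, elements0)) {
      stop("XYZ parse error: frame ", fidx,
           " element order differs from frame 1")
    }
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (!all(is.finite(xyz))) {
      stop("XYZ parse error in frame ", fidx, ": non-numeric coordinates")
    }
    frames[[fidx]] <- xyz
    i <- i + 2L + n
  }
  el <- elements0
  ord <- stats::ave(seq_along(el), el, FUN = seq_along)
  atoms <- atom_table(paste0(el, ord), el, residue_index = rep(1L, length(el)))
  list(atoms = atoms, frames = frames)
}

read_pdb_frames <- function(path) {
  # cheap structural pre-check so a malformed model is reported by index
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(model_starts)) {
      stop("PDB parse error: MODEL/ENDMDL records unbalanced")
    }
    counts <- mapply(function(s, e) sum(grepl("^(ATOM  |HETATM)", lines[s:e])),
                     model_starts, ends)
    if (length(unique(counts)) != 1) {
      bad <- which(counts != counts[1])[1]
      stop("PDB parse error: frame ", bad, " lists ", counts[bad],
           " atoms while frame 1 lists ", counts[1])
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  el <- trimws(pdb$atom$elesy)
  noel <- !nzchar(el) | is.na(el)
  if (any(noel)) {
    # fall back on the first letter of the atom name
    el[noel] <- toupper(substr(trimws(pdb$atom$elety[noel]), 1, 1))
  }
  atoms <- atom_table(trimws(pdb$atom$elety), el,
                      residue_index = as.integer(pdb$atom$resno))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  })
  list(atoms = atoms, frames = frames)
}

#' Write a multi-frame trajectory
#'
#' Inverse of \code{\link{read_ensemble}}: XYZ coordinates are printed at
#' 1e-6 Angstrom precision, PDB at the fixed 1e-3 precision of the format, so
#' a read/write round trip reproduces coordinates within text precision and
#' metadata exactly (XYZ keeps only elements; use an atom-table override to
#' restore names/residues).
#'
#' @param ens an \code{\link{ensemble}}.
#' @param path output file path.
#' @param format \code{"xyz"} or \code{"pdb"}; default guesses from the
#'   extension.
#' @return The path, invisibly.
#' @export
write_ensemble <- function(ens, path, format = c("auto", "xyz", "pdb")) {
  if (!inherits(ens, "ensemble")) stop("ens must be an ensemble")
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  if (format == "xyz") {
    con <- file(path, "w")
    on.exit(close(con))
    n <- nrow(ens$atoms)
    for (i in seq_along(ens$frames)) {
      writeLines(c(as.character(n), paste("frame", i)), con)
      f <- ens$frames[[i]]
      writeLines(sprintf("%-2s %14.6f %14.6f %14.6f", ens$atoms$element,
                         f[, 1], f[, 2], f[, 3]), con)
    }
  } else {
    xyz <- do.call(rbind, lapply(ens$frames, function(f) as.vector(t(f))))
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = ens$atoms$residue_index,
                     resid = sprintf("R%02d", ens$atoms$residue_index),
                     elety = ens$atoms$name,
                     elesy = ens$atoms$element)
  }
  invisible(path)
}

#' Subsample an ensemble by a fixed frame stride
#'
#' Keeps frames 1, 1+stride, 1+2*stride, ... (the first frame always
#' retained) and multiplies the frame interval by the stride. Used to check
#' that ensemble-averaged observables are insensitive to the trajectory
#' writing stride.
#'
#' @param ens an \code{\link{ensemble}}.
#' @param stride positive integer.
#' @return An \code{\link{ensemble}} sharing the atom table.
#' @export
subsample <- function(ens, stride) {
  if (!inherits(ens, "ensemble")) stop("ens must be an ensemble")
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1) stop("stride must be a positive integer")
  keep <- seq(1L, length(ens$frames), by = stride)
  ensemble(ens$atoms, ens$frames[keep],
           frame_interval = ens$frame_interval * stride)
}
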