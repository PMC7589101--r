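# Published benchmark of NOE prediction accuracy: per-molecule absolute
# RMSD between ensemble-predicted and experimental normalized NOEs for
# eleven disaccharides under eleven ensemble-generation protocols (six
# force fields with implicit or explicit solvent, plus a DFT
# cluster-medoid reference track). Shipped as plain text under
# inst/extdata; the aggregate rows of such a table (per-method means over
# molecules) and the per-molecule best-method comparisons are what
# aggregate_table() and benchmark_summary() reproduce.

#' Load the shipped NOE-RMSD benchmark
#'
#' @return A list with \code{rmsd} (11 x 11 numeric matrix, molecules x
#'   methods), \code{molecules} (data frame: molecule, description) and
#'   \code{methods} (data frame: method, force_field, solvation,
#'   solvent_class in \{implicit, explicit, dft\}, temperature).
#' @export
benchmark_rmsd <- function() {
  f1 <- system.file("extdata", "benchmark_noe_rmsd.tsv", package = "glynoe",
                    mustWork = TRUE)
  f2 <- system.file("extdata", "benchmark_methods.tsv", package = "glynoe",
                    mustWork = TRUE)
  df <- utils::read.delim(f1, check.names = FALSE, stringsAsFactors = FALSE)
  methods <- utils::read.delim(f2, stringsAsFactors = FALSE)
  m <- as.matrix(df[, methods$method])
  rownames(m) <- as.character(df$molecule)
  storage.mode(m) <- "double"
  list(rmsd = m,
       molecules = df[, c("molecule", "description")],
       methods = methods)
}

#' Aggregate statistics of an RMSD benchmark by solvent class
#'
#' Computes per-method column means (arithmetic over molecules, full
#' precision), the min/max of those means within each solvent class, and
#' the number of molecules for which at least one explicit-solvent method
#' strictly beats the reference (DFT) method.
#'
#' @param bench a \code{\link{benchmark_rmsd}}-style list, or NULL to load
#'   the shipped benchmark.
#' @return List with \code{means} (named per-method vector),
#'   \code{class_range} (data frame: solvent_class, min, max of column
#'   means), and \code{n_explicit_beats_dft} (integer count of molecules
#'   whose best explicit-solvent RMSD is strictly below the dft-class
#'   column).
#' @export
benchmark_summary <- function(bench = NULL) {
  if (is.null(bench)) bench <- benchmark_rmsd()
  means <- aggregate_table(bench$rmsd)$means
  cls <- bench$methods$solvent_class[match(names(means),
                                           bench$methods$method)]
  rng <- do.call(rbind, lapply(unique(cls), function(k) {
    data.frame(solvent_class = k, min = min(means[cls == k]),
               max = max(means[cls == k]))
  }))
  expl <- bench$rmsd[, cls == "explicit", drop = FALSE]
  ref <- bench$rmsd[, cls == "dft", drop = FALSE]
  if (ncol(ref) != 1) stop("expected exactly one dft-class method")
  beats <- apply(expl, 1, min) < ref[, 1]
  list(means = means, class_range = rng,
       n_explicit_beats_dft = sum(beats),
       beats_by_molecule = beats)
}
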