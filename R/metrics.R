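# Scoring simulated against experimental NOE tables: absolute and relative
# RMSD, per molecule and aggregated over molecules, with a
# transglycosidic-only variant (the conformation-informative subset) and
# pooled error distributions.

# Pair two normalized tables on (saturated, observed); returns a data frame
# with sim/exp values and the transglycosidic flag.
pair_noe <- function(sim, exp, subset = c("all", "transglycosidic")) {
  subset <- match.arg(subset)
  key <- function(t) paste(t$saturated, t$observed, sep = "|")
  ks <- key(sim); ke <- key(exp)
  common <- intersect(ks, ke)
  if (!length(common)) {
    stop("no matching (saturated, observed) keys; simulated has {",
         paste(ks, collapse = ", "), "}, experimental has {",
         paste(ke, collapse = ", "), "}")
  }
  i <- match(common, ks); j <- match(common, ke)
  tg <- sim$transglycosidic[i]
  if (subset == "transglycosidic") {
    if (any(is.na(tg))) tg <- exp$transglycosidic[j]
    keep <- which(!is.na(tg) & tg)
    if (!length(keep)) stop("no transglycosidic pairs in the intersection")
    i <- i[keep]; j <- j[keep]; common <- common[keep]; tg <- tg[keep]
  }
  data.frame(key = common, sim = sim$value[i], exp = exp$value[j],
             transglycosidic = tg, stringsAsFactors = FALSE)
}

#' Absolute RMSD between simulated and experimental NOE tables
#'
#' sqrt(mean((NOE_i - NOE_i^exp)^2)) over entries paired exactly on
#' (saturated, observed) keys. Both tables should be normalized (see
#' \code{\link{normalize_noe}}); every paired entry contributes one term with
#' equal weight regardless of its saturation group.
#'
#' @param sim,exp \code{"noe_table"} objects.
#' @param subset \code{"all"} or \code{"transglycosidic"} (only pairs whose
#'   protons sit in different residues).
#' @return Non-negative scalar.
#' @export
rmsd_abs <- function(sim, exp, subset = c("all", "transglycosidic")) {
  p <- pair_noe(sim, exp, subset)
  sqrt(mean((p$sim - p$exp)^2))
}

#' Relative RMSD between simulated and experimental NOE tables
#'
#' sqrt(mean(((NOE_i - NOE_i^exp) / NOE_i^exp)^2)); each deviation is scaled
#' by the experimental value, so weak contacts count as much as strong ones.
#' Not symmetric in its arguments. Requires strictly positive experimental
#' values in the subset.
#'
#' @inheritParams rmsd_abs
#' @return Non-negative scalar.
#' @export
rmsd_rel <- function(sim, exp, subset = c("all", "transglycosidic")) {
  p <- pair_noe(sim, exp, subset)
  bad <- p$key[p$exp <= 0]
  if (length(bad)) {
    stop("experimental NOE <= 0 for pair(s): ", paste(bad, collapse = ", "))
  }
  sqrt(mean(((p$sim - p$exp) / p$exp)^2))
}

#' Full comparison of one simulated table against experiment
#'
#' @inheritParams rmsd_abs
#' @param molecule molecule identifier carried into reports.
#' @return An object of class \code{"noe_comparison"}: list with
#'   \code{molecule}, \code{pairs} (per-pair simulated/experimental values,
#'   absolute and relative errors), \code{rmsd_abs}, \code{rmsd_rel},
#'   \code{subset}, \code{n}.
#' @export
compare_noe <- function(sim, exp, molecule = "molecule",
                        subset = c("all", "transglycosidic")) {
  subset <- match.arg(subset)
  p <- pair_noe(sim, exp, subset)
  p$abs_error <- p$sim - p$exp
  p$rel_error <- ifelse(p$exp > 0, (p$sim - p$exp) / p$exp, NA_real_)
  structure(list(
    molecule = molecule, pairs = p,
    rmsd_abs = sqrt(mean(p$abs_error^2)),
    rmsd_rel = if (all(p$exp > 0)) sqrt(mean(p$rel_error^2)) else NA_real_,
    subset = subset, n = nrow(p)
  ), class = "noe_comparison")
}

#' Aggregate per-molecule RMSDs over methods
#'
#' Given a molecules x methods matrix of per-molecule RMSD values, computes
#' the per-method arithmetic mean over molecules — the "average" rows of a
#' benchmark table. Under the default strict policy a missing cell is an
#' error; with \code{policy = "skip"} missing cells are dropped from that
#' method's mean and reported.
#'
#' @param rmsd_matrix numeric matrix, rows molecules, columns methods
#'   (dimnames used in the report).
#' @param policy \code{"strict"} or \code{"skip"}.
#' @return A list with \code{means} (named per-method vector, full
#'   precision), \code{n_molecules} per method, and \code{missing} (data
#'   frame of absent cells). Rounding to 2 decimals is left to the
#'   presentation layer (\code{\link{render_benchmark_table}}).
#' @export
aggregate_table <- function(rmsd_matrix, policy = c("strict", "skip")) {
  policy <- match.arg(policy)
  m <- as.matrix(rmsd_matrix)
  if (is.null(colnames(m))) colnames(m) <- paste0("method", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("mol", seq_len(nrow(m)))
  miss <- which(is.na(m), arr.ind = TRUE)
  if (nrow(miss) && policy == "strict") {
    stop("missing RMSD cell(s): ",
         paste(rownames(m)[miss[, 1]], colnames(m)[miss[, 2]],
               sep = "/", collapse = ", "))
  }
  list(
    means = colMeans(m, na.rm = TRUE),
    n_molecules = colSums(!is.na(m)),
    missing = data.frame(molecule = rownames(m)[miss[, 1]],
                         method = colnames(m)[miss[, 2]],
                         stringsAsFactors = FALSE)
  )
}

#' Pooled distribution of individual NOE errors
#'
#' Pools per-pair errors across molecules for one method and summarizes them
#' (mean, SD, RMSD), for both the absolute and the relative error variant.
#'
#' @param comparisons list of \code{"noe_comparison"} objects (one method,
#'   several molecules).
#' @return List with \code{errors} (data frame: molecule, key, abs_error,
#'   rel_error) and \code{summary} (data frame with rows "abs"/"rel":
#'   mean, sd, rmsd, n).
#' @export
error_distribution <- function(comparisons) {
  if (!length(comparisons)) stop("at least one comparison required")
  err <- do.call(rbind, lapply(comparisons, function(cmp) {
    data.frame(molecule = cmp$molecule, key = cmp$pairs$key,
               abs_error = cmp$pairs$abs_error,
               rel_error = cmp$pairs$rel_error, stringsAsFactors = FALSE)
  }))
  summ <- function(x) {
    x <- x[!is.na(x)]
    data.frame(mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else 0,
               rmsd = sqrt(mean(x^2)), n = length(x))
  }
  list(errors = err,
       summary = rbind(abs = summ(err$abs_error), rel = summ(err$rel_error)))
}
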