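# Rank competing ensemble-generation methods by per-molecule RMSD and
# combine ranks into overall scores. Each molecule "votes" by ranking the
# methods; rank positions are converted to points and points summed over
# molecules. Two point scales are provided: quadratic (64, 32, 16, 8, 4, 2,
# 1 for ranks 1-7 — the top rank outweighs all others together) and linear
# with progression 9 (63, 54, 45, 36, 27, 18, 9). Ranks 8 and beyond score
# zero in both.

#' Rank-to-points mapping
#'
#' @param rank positive integer rank(s), 1 = best (lowest RMSD).
#' @param scheme \code{"quadratic"} (2^(7-rank) for ranks 1-7) or
#'   \code{"linear"} (9*(8-rank) for ranks 1-7); zero for rank >= 8.
#' @return Numeric point value(s).
#' @export
rank_points <- function(rank, scheme = c("quadratic", "linear")) {
  scheme <- match.arg(scheme)
  rank <- as.numeric(rank)
  if (any(is.na(rank) | rank < 1)) stop("rank must be >= 1")
  if (scheme == "quadratic") {
    ifelse(rank <= 7, 2^(7 - rank), 0)
  } else {
    ifelse(rank <= 7, 9 * (8 - rank), 0)
  }
}

# Points for possibly tied ranks: tied methods share the arithmetic mean of
# the points their occupied integer rank positions would carry (two-way tie
# for 1st under the quadratic scale -> (64+32)/2 = 48 each). This conserves
# the points distributed per molecule and is order-independent.
points_for_row <- function(rmsd_row, scheme) {
  r <- rank(rmsd_row, ties.method = "min")
  pts <- numeric(length(r))
  for (v in unique(r)) {
    idx <- which(r == v)
    positions <- v:(v + length(idx) - 1L)
    pts[idx] <- mean(rank_points(positions, scheme))
  }
  pts
}

#' Rank methods across molecules by RMSD
#'
#' Per molecule, methods are ranked ascending by RMSD (1 = most accurate);
#' rank points are summed over molecules and methods ordered by descending
#' total. Ties in a molecule's row share the mean points of their occupied
#' positions; ties in the overall total are broken by mean per-molecule RMSD
#' and then by column order, and reported.
#'
#' @param rmsd_matrix numeric matrix, rows molecules, columns methods, no
#'   missing values.
#' @param scheme \code{"quadratic"} or \code{"linear"}.
#' @return An object of class \code{"ranking_result"}: list with
#'   \code{ranks} (molecules x methods matrix of per-molecule ranks,
#'   ties.method "min"), \code{total_points} (named vector),
#'   \code{overall_rank} (named integer vector, 1 = winner), \code{order}
#'   (method labels best to worst), \code{tied} (logical, any overall
#'   point tie), \code{scheme}.
#' @export
rank_methods <- function(rmsd_matrix, scheme = c("quadratic", "linear")) {
  scheme <- match.arg(scheme)
  m <- as.matrix(rmsd_matrix)
  if (ncol(m) < 2) stop("at least two methods required")
  if (anyNA(m)) stop("missing RMSD values; fill or filter the matrix first")
  if (is.null(colnames(m))) colnames(m) <- paste0("method", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("mol", seq_len(nrow(m)))
  ranks <- t(apply(m, 1, rank, ties.method = "min"))
  pts <- t(apply(m, 1, points_for_row, scheme = scheme))
  total <- colSums(pts)
  names(total) <- colnames(m)
  mean_rmsd <- colMeans(m)
  ord <- order(-total, mean_rmsd, seq_along(total))
  overall <- integer(length(total))
  overall[ord] <- seq_along(ord)
  # shared overall rank for exact point ties (annotated, order still total)
  tied <- any(duplicated(total))
  names(overall) <- colnames(m)
  structure(list(ranks = ranks, points = pts, total_points = total,
                 overall_rank = overall, order = colnames(m)[ord],
                 tied = tied, scheme = scheme),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat("method ranking (", x$scheme, " points)\n", sep = "")
  df <- data.frame(method = names(x$total_points),
                   total_points = x$total_points,
                   overall_rank = x$overall_rank)
  print(df[order(df$overall_rank), ], row.names = FALSE)
  if (x$tied) cat("note: tie in total points (broken by mean RMSD)\n")
  invisible(x)
}

#' Top-k methods of a ranking
#'
#' @param result a \code{\link{rank_methods}} result.
#' @param k number of methods to return.
#' @return Character vector of method labels, best first. Methods tied in
#'   total points with the k-th are included, so the result can exceed k.
#' @export
top_k <- function(result, k) {
  if (!inherits(result, "ranking_result")) stop("result must be a ranking_result")
  if (k < 1 || k > length(result$order)) stop("k out of range")
  labs <- result$order[seq_len(k)]
  kth <- result$total_points[labs[k]]
  extra <- setdiff(names(result$total_points)[result$total_points == kth], labs)
  c(labs, result$order[result$order %in% extra])
}

#' Read an RMSD matrix from delimited text
#'
#' Rows are molecules (first column the molecule label), remaining columns
#' methods.
#'
#' @param path file path.
#' @return Numeric matrix with dimnames.
#' @export
read_rmsd_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}
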