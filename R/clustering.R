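# Representative-conformer selection: Kabsch superposition of frames,
# k-means clustering of flattened aligned coordinates over a range of
# cluster counts with silhouette-based selection, and medoid extraction.
# The medoids are the geometries handed to (external) quantum-chemical
# refinement; their free energies come back into boltzmann_noe().

#' Least-squares superposition of two coordinate sets (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' selected atoms of \code{mobile} onto \code{reference}, via SVD of the
#' cross-covariance with the usual determinant correction (no reflections).
#'
#' @param mobile,reference n x 3 coordinate matrices.
#' @param atom_subset atom ids (0-based) used for the fit (e.g. all heavy
#'   atoms); default all atoms. At least 3 non-collinear atoms.
#' @return List of class \code{"superposition"} with \code{rotation}
#'   (3 x 3, det +1), \code{translation} (length 3; the fit is
#'   \code{coords \%*\% t(R) + t}), \code{rmsd} (post-fit RMSD over the
#'   subset, Angstrom) and \code{fitted} (all mobile atoms transformed).
#' @export
superpose <- function(mobile, reference, atom_subset = NULL) {
  mobile <- as_frame(mobile)
  reference <- as_frame(reference, nrow(mobile))
  idx <- if (is.null(atom_subset)) seq_len(nrow(mobile)) else
    as.integer(atom_subset) + 1L
  if (length(idx) < 3) stop("superposition needs at least 3 atoms")
  A <- mobile[idx, , drop = FALSE]
  B <- reference[idx, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sv <- svd(crossprod(A0, B0))  # 3x3 covariance A0' B0
  if (sv$d[2] < 1e-10) {
    stop("degenerate atom subset (collinear or coincident points)")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cb - as.vector(R %*% ca)
  fit_sub <- A %*% t(R) + matrix(trans, nrow(A), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fit_sub - B)^2)))
  fitted <- mobile %*% t(R) + matrix(trans, nrow(mobile), 3, byrow = TRUE)
  structure(list(rotation = R, translation = trans, rmsd = rmsd,
                 fitted = fitted), class = "superposition")
}

# Align every frame to the first on the chosen subset; returns a frames x
# (3*natoms) matrix of flattened aligned coordinates.
align_frames <- function(ens, atom_subset) {
  ref <- ens$frames[[1]]
  t(vapply(ens$frames, function(f) {
    as.vector(t(superpose(f, ref, atom_subset)$fitted))
  }, numeric(3 * nrow(ens$atoms))))
}

#' Cluster trajectory frames and choose k by silhouette
#'
#' Frames are superposed on the first frame (heavy atoms by default, as
#' hydrogens add noise without information), flattened to 3N-vectors and
#' clustered with k-means for every candidate cluster count; the k with the
#' largest mean silhouette width (Euclidean distance) wins. Deterministic
#' for a fixed seed.
#'
#' @param ens an \code{\link{ensemble}} with at least \code{max(k_range)+1}
#'   frames.
#' @param heavy_only superpose and cluster on non-hydrogen atoms only
#'   (default TRUE).
#' @param k_range integer vector of candidate cluster counts (default
#'   25:50, suitable for tens of thousands of frames; tests use small
#'   ranges).
#' @param seed integer seed controlling k-means restarts and the silhouette
#'   subsample.
#' @param nstart k-means restarts per candidate k (default 10).
#' @param silhouette_max_n silhouette is computed on all frames up to this
#'   many, else on a seeded subsample (the O(n^2) distance matrix is the
#'   bottleneck).
#' @return An object of class \code{"cluster_selection"}: list with
#'   \code{k}, \code{assignment} (per-frame cluster), \code{silhouette}
#'   (named per-k mean widths), \code{medoid_frames} (per-cluster frame
#'   index, see \code{\link{medoids}}), \code{centers}, \code{coords}
#'   (flattened aligned coordinates used), \code{atom_subset}.
#' @export
cluster_frames <- function(ens, heavy_only = TRUE, k_range = 25:50,
                           seed = 1L, nstart = 10L, silhouette_max_n = 5000L) {
  if (!inherits(ens, "ensemble")) stop("ens must be an ensemble")
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range) || any(k_range < 2)) {
    stop("k_range must contain integers >= 2")
  }
  nf <- length(ens$frames)
  if (max(k_range) > nf - 1L) {
    stop("k_range maximum ", max(k_range), " exceeds usable frame count ",
         nf - 1L)
  }
  subset_ids <- if (heavy_only) {
    ens$atoms$atom_id[ens$atoms$element != "H"]
  } else ens$atoms$atom_id
  X <- align_frames(ens, subset_ids)
  keep_cols <- as.vector(t(outer(subset_ids, 0:2,
                                 function(a, k) 3L * a + k + 1L)))
  Xc <- X[, keep_cols, drop = FALSE]
  if (max(apply(Xc, 2, stats::sd)) < 1e-8) {
    stop("degenerate ensemble: all frames identical after alignment; ",
         "silhouette is undefined")
  }
  sil_idx <- seq_len(nf)
  if (nf > silhouette_max_n) {
    set.seed(seed + 7L)
    sil_idx <- sort(sample.int(nf, silhouette_max_n))
  }
  dsub <- stats::dist(Xc[sil_idx, , drop = FALSE])
  sil <- stats::setNames(numeric(length(k_range)), k_range)
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    set.seed(seed + k)
    fits[[i]] <- stats::kmeans(Xc, centers = k, nstart = nstart,
                               iter.max = 100)
    cl_sub <- fits[[i]]$cluster[sil_idx]
    if (length(unique(cl_sub)) < 2) {
      sil[i] <- -Inf  # subsample collapsed into one cluster
    } else {
      sil[i] <- mean(cluster::silhouette(cl_sub, dsub)[, "sil_width"])
    }
  }
  best <- which.max(sil)
  fit <- fits[[best]]
  sel <- structure(list(k = k_range[best], assignment = fit$cluster,
                        silhouette = sil, centers = fit$centers,
                        coords = Xc, atom_subset = subset_ids),
                   class = "cluster_selection")
  sel$medoid_frames <- medoids(sel, ens)
  sel
}

#' Medoid frame of every cluster
#'
#' The medoid is the actual ensemble member closest (Euclidean distance in
#' flattened aligned coordinates) to its cluster's centroid — the
#' representative geometry used downstream.
#'
#' @param selection a \code{\link{cluster_frames}} result.
#' @param ens the clustered \code{\link{ensemble}} (frame count must match).
#' @return Integer vector of frame indices (1-based), one per cluster.
#' @export
medoids <- function(selection, ens) {
  if (length(selection$assignment) != length(ens$frames)) {
    stop("selection does not match the ensemble frame count")
  }
  vapply(seq_len(selection$k), function(cl) {
    members <- which(selection$assignment == cl)
    ctr <- selection$centers[cl, ]
    d2 <- colSums((t(selection$coords[members, , drop = FALSE]) - ctr)^2)
    members[which.min(d2)]
  }, integer(1))
}

#' Export a cluster selection as delimited text
#'
#' One row per frame: \code{frame_index}, \code{cluster}, \code{is_medoid}.
#'
#' @param selection a \code{\link{cluster_frames}} result.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_cluster_selection <- function(selection, path) {
  df <- data.frame(frame_index = seq_along(selection$assignment),
                   cluster = selection$assignment,
                   is_medoid = seq_along(selection$assignment) %in%
                     selection$medoid_frames)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
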