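#' Pairwise ligand RMSD matrix in the receptor-aligned frame
#'
#' Every frame is first superposed onto a common reference by a Kabsch fit
#' over `align_sel` (the receptor), then ligand RMSD is computed pairwise
#' *without* refitting the ligand, so displacement of the ligand relative
#' to the pocket counts. This is the distance on which the Gromos pose
#' clustering operates.
#'
#' @param trajs an [md_trajectory] or list of them (same topology).
#' @param align_sel receptor selection used for superposition (>= 3 atoms).
#' @param ligand_sel ligand selection; hydrogens are dropped.
#' @param reference reference for alignment: `NULL` (frame 1 of the first
#'   trajectory) or an [md_structure] with the same atom table.
#' @return a `ligand_rmsd_matrix`: list with `values` (n x n symmetric
#'   matrix, Angstrom), `frame_map` (data.frame `copy`, `frame`),
#'   `aligned_coords` (n x atoms x 3 array of receptor-aligned full-system
#'   coordinates) and the selections used.
#' @export
ligand_rmsd_matrix <- function(trajs, align_sel, ligand_sel,
                               reference = NULL) {
  trajs <- as_traj_list(trajs)
  top <- trajs[[1]]$topology
  a_idx <- resolve_selection(top, align_sel)
  l_idx <- resolve_selection(top, ligand_sel)
  l_idx <- l_idx[top$atoms$elem[l_idx] != "H"]
  if (length(a_idx) < 3L) stop("alignment selection needs at least 3 atoms")
  if (length(l_idx) == 0L) stop("ligand selection matched no heavy atoms")

  ref_xyz <- if (is.null(reference)) {
    trajs[[1]]$coords[1, a_idx, , drop = TRUE]
  } else {
    stopifnot(inherits(reference, "md_structure"))
    reference$xyz[a_idx, , drop = FALSE]
  }
  dim(ref_xyz) <- c(length(a_idx), 3L)

  bounds <- traj_boundaries(trajs)
  n <- bounds$total
  nat <- nrow(top$atoms)
  aligned <- array(NA_real_, dim = c(n, nat, 3L))
  frame_map <- data.frame(copy = character(n), frame = integer(n),
                          stringsAsFactors = FALSE)
  row <- 0L
  for (tr in trajs) {
    for (i in seq_len(n_frames(tr))) {
      row <- row + 1L
      fr <- tr$coords[i, , , drop = TRUE]
      dim(fr) <- c(nat, 3L)
      tfm <- kabsch_fit(fr[a_idx, , drop = FALSE], ref_xyz)
      aligned[row, , ] <- apply_transform(tfm, fr)
      frame_map$copy[row] <- tr$source_id
      frame_map$frame[row] <- i
    }
  }

  # pairwise RMSD over the ligand atoms via the Gram-matrix identity:
  # sum_k |a_ik - a_jk|^2 = s_i + s_j - 2 G_ij with G the frame Gram matrix
  m <- length(l_idx)
  lig <- matrix(NA_real_, nrow = n, ncol = 3L * m)
  for (k in 1:3) lig[, seq.int(k, by = 3L, length.out = m)] <- aligned[, l_idx, k]
  s <- rowSums(lig^2)
  g <- tcrossprod(lig)
  d2 <- (outer(s, s, "+") - 2 * g) / m
  d2[d2 < 0] <- 0
  values <- sqrt(d2)
  values <- (values + t(values)) / 2
  diag(values) <- 0
  structure(list(values = values, frame_map = frame_map,
                 aligned_coords = aligned,
                 align_indices = a_idx, ligand_indices = l_idx),
            class = "ligand_rmsd_matrix")
}

#' @export
print.ligand_rmsd_matrix <- function(x, ...) {
  cat("ligand_rmsd_matrix: ", nrow(x$values), " frames, ",
      length(x$ligand_indices), " ligand atoms\n", sep = "")
  invisible(x)
}

as_distance_values <- function(x) {
  if (inherits(x, "ligand_rmsd_matrix")) x <- x$values
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) stop("distance matrix must be square")
  if (max(abs(x - t(x))) > 1e-9) stop("distance matrix must be symmetric")
  if (any(x < 0)) stop("distances must be non-negative")
  if (any(abs(diag(x)) > 1e-9)) stop("distance matrix diagonal must be zero")
  x
}

#' Gromos (Daura) conformational clustering
#'
#' Greedy neighbour-count clustering: among unassigned frames, the frame
#' with the most neighbours within `cutoff` (boundary inclusive, itself
#' included) becomes the next cluster centroid; it and its unassigned
#' neighbours form the cluster and are removed; repeat until no frame
#' remains. Neighbour-count ties are broken by the lowest frame index, so
#' the result is deterministic. Clusters are emitted in formation order,
#' which is non-increasing in size.
#'
#' @param dmat a `ligand_rmsd_matrix` or plain symmetric distance matrix.
#' @param cutoff neighbour cutoff in Angstrom (default 3, the ligand-pose
#'   cutoff used throughout).
#' @return a `gromos_clustering`: list with `clusters` (list of
#'   `list(centroid, members)`, frame indices into the matrix order),
#'   `cutoff`, `n`.
#' @export
gromos_cluster <- function(dmat, cutoff = 3.0) {
  values <- as_distance_values(dmat)
  n <- nrow(values)
  adj <- values <= cutoff          # includes self (diagonal 0)
  unassigned <- rep(TRUE, n)
  clusters <- list()
  while (any(unassigned)) {
    idx <- which(unassigned)
    counts <- colSums(adj[idx, idx, drop = FALSE])
    centroid <- idx[which.max(counts)]   # which.max takes the first maximum
    members <- idx[adj[centroid, idx]]
    clusters[[length(clusters) + 1L]] <-
      list(centroid = centroid, members = members)
    unassigned[members] <- FALSE
  }
  structure(list(clusters = clusters, cutoff = cutoff, n = n),
            class = "gromos_clustering")
}

#' @export
print.gromos_clustering <- function(x, ...) {
  sizes <- cluster_sizes(x)
  cat("gromos_clustering: ", length(x$clusters), " cluster(s) over ",
      x$n, " frames (cutoff ", x$cutoff, " A)\n", sep = "")
  show <- utils::head(sizes, 6L)
  cat("  sizes (%): ", paste(format(show, digits = 3), collapse = ", "),
      if (length(sizes) > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Cluster sizes as percentages of the trajectory
#' @param clustering a `gromos_clustering`.
#' @return numeric vector, 100 * members / n per cluster, formation order.
#' @export
cluster_sizes <- function(clustering) {
  stopifnot(inherits(clustering, "gromos_clustering"))
  vapply(clustering$clusters,
         function(cl) 100 * length(cl$members) / clustering$n, numeric(1))
}

#' Cluster membership per frame
#' @param clustering a `gromos_clustering`.
#' @return integer vector of cluster ids (1 = first-formed), one per frame.
#' @export
cluster_membership <- function(clustering) {
  out <- integer(clustering$n)
  for (k in seq_along(clustering$clusters)) {
    out[clustering$clusters[[k]]$members] <- k
  }
  out
}

#' Centroid structure of a cluster
#'
#' Returns the full-system coordinates of cluster `k`'s centroid frame in
#' the receptor-aligned frame, ready to write out as the representative
#' binding pose.
#'
#' @param trajs the trajectories the matrix was built from.
#' @param clustering a `gromos_clustering`.
#' @param k cluster number (1-based, formation order).
#' @param dmat the `ligand_rmsd_matrix` used for clustering (provides the
#'   aligned coordinates and frame map).
#' @return an [md_structure].
#' @export
centroid_structure <- function(trajs, clustering, k, dmat) {
  stopifnot(inherits(clustering, "gromos_clustering"),
            inherits(dmat, "ligand_rmsd_matrix"))
  if (k < 1L || k > length(clustering$clusters)) {
    stop("cluster ", k, " out of range (", length(clustering$clusters),
         " clusters)")
  }
  trajs <- as_traj_list(trajs)
  top <- trajs[[1]]$topology
  row <- clustering$clusters[[k]]$centroid
  xyz <- dmat$aligned_coords[row, , , drop = TRUE]
  dim(xyz) <- c(nrow(top$atoms), 3L)
  md_structure(top$atoms, xyz, box = top$box)
}

#' Cluster table
#' @param clustering a `gromos_clustering`.
#' @param dmat optional `ligand_rmsd_matrix` to translate centroid rows
#'   into (copy, frame) labels.
#' @return data.frame with `cluster_id`, `centroid_frame`, `size`,
#'   `size_pct` (and `centroid_copy` if `dmat` is given).
#' @export
cluster_table <- function(clustering, dmat = NULL) {
  sizes <- vapply(clustering$clusters, function(cl) length(cl$members),
                  integer(1))
  out <- data.frame(
    cluster_id = seq_along(clustering$clusters),
    centroid_frame = vapply(clustering$clusters, `[[`, integer(1), "centroid"),
    size = sizes,
    size_pct = 100 * sizes / clustering$n
  )
  if (!is.null(dmat)) {
    out$centroid_copy <- dmat$frame_map$copy[out$centroid_frame]
    out$centroid_source_frame <- dmat$frame_map$frame[out$centroid_frame]
  }
  out
}
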