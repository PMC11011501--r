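# Independent oracles and fixture builders shared across the suite.
# These deliberately re-derive results by different algorithms than the
# package (quaternion vs SVD superposition; direct greedy recount vs the
# package's vectorised clustering) so agreement is evidence, not tautology.

# Horn's closed-form quaternion superposition: returns the proper rotation
# (3x3) and translation mapping `mobile` onto `reference`.
quaternion_fit <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  Sxx <- sum(A[, 1] * B[, 1]); Sxy <- sum(A[, 1] * B[, 2])
  Sxz <- sum(A[, 1] * B[, 3]); Syx <- sum(A[, 2] * B[, 1])
  Syy <- sum(A[, 2] * B[, 2]); Syz <- sum(A[, 2] * B[, 3])
  Szx <- sum(A[, 3] * B[, 1]); Szy <- sum(A[, 3] * B[, 2])
  Szz <- sum(A[, 3] * B[, 3])
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  # Horn's rotation acts on column vectors of the mobile-centred set
  list(rotation = R, translation = as.numeric(cr - R %*% cm))
}

# Plain greedy Daura reference: explicit loops, recounting neighbours from
# scratch each round.
daura_reference <- function(d, cutoff) {
  n <- nrow(d)
  unassigned <- seq_len(n)
  clusters <- list()
  while (length(unassigned) > 0) {
    best <- -1L; best_count <- -1L
    for (i in unassigned) {
      count <- 0L
      for (j in unassigned) if (d[i, j] <= cutoff) count <- count + 1L
      if (count > best_count) { best_count <- count; best <- i }
    }
    members <- unassigned[vapply(unassigned, function(j) d[best, j] <= cutoff,
                                 logical(1))]
    clusters[[length(clusters) + 1L]] <- list(centroid = best,
                                              members = members)
    unassigned <- setdiff(unassigned, members)
  }
  clusters
}

# Random symmetric distance matrix with zero diagonal.
random_distance_matrix <- function(n, scale = 6) {
  d <- matrix(stats::runif(n * n, 0, scale), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

# Random proper rotation from a normalised quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

default_mode_points_for_test <- function() synthetic_spec()$mode_points

# Plain squared cross-distance for oracle-side computations.
cross_dist2_for_test <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Distinct anchors referenced by a mode profile (mirrors the package's
# internal bookkeeping for use in tests).
profile_anchors_for_test <- function(defs) {
  anchors <- list()
  for (d in defs) for (cc in d$conditions) anchors[[cc$anchor$label]] <- cc$anchor
  anchors
}

# A tiny structure with arbitrary residues for I/O and geometry tests.
# Coordinates are multiples of 0.01 A so GRO (nm, 3 decimals) can
# represent them exactly.
tiny_structure <- function() {
  atoms <- data.frame(
    name = c("N", "CA", "C"), elem = c("N", "C", "C"),
    resname = "ALA", resno = 7L, chain = "A", occ = 1,
    stringsAsFactors = FALSE)
  md_structure(atoms, rbind(c(1.25, 2.50, 3.75),
                            c(2.00, 3.10, 4.20),
                            c(3.40, 1.90, 5.60)))
}

# Manually assembled trajectory: one ligand atom approaching/leaving a
# fixed single-atom residue, for brute-force contact checks.
two_atom_trajectory <- function(distances) {
  atoms <- data.frame(
    name = c("CA", "P"), elem = c("C", "P"),
    resname = c("GLY", "G3P"), resno = c(1L, 2L), chain = "A", occ = 1,
    stringsAsFactors = FALSE)
  topo <- md_structure(atoms, rbind(c(0, 0, 0), c(1, 0, 0)))
  coords <- array(0, dim = c(length(distances), 2, 3))
  coords[, 2, 1] <- distances
  md_trajectory(topo, coords, source_id = "manual")
}
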