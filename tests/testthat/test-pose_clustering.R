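test_that("receptor-aligned ligand RMSD matrix matches per-pair recomputation", {
  pb <- make_pose_blobs(2, 5, sigma = 0.8, separation = 10, seed = 31)
  dm <- ligand_rmsd_matrix(pb$trajectory, "name CA", "resname G3P")
  n <- nrow(dm$values)
  expect_equal(dm$values, t(dm$values), tolerance = 1e-9)
  expect_equal(diag(dm$values), rep(0, n))
  # independent oracle: explicit Kabsch per frame, explicit pair loop
  tr <- pb$trajectory
  a_idx <- select_atoms(tr$topology, "name CA")$indices
  l_idx <- select_atoms(tr$topology, "heavy and resname G3P")$indices
  ref <- tr$coords[1, a_idx, ]
  lig <- lapply(seq_len(n), function(i) {
    fr <- tr$coords[i, , ]
    fit <- kabsch_fit(fr[a_idx, ], ref)
    apply_transform(fit, fr)[l_idx, ]
  })
  for (i in 1:n) for (j in 1:n) {
    expect_equal(dm$values[i, j], rmsd_no_fit(lig[[i]], lig[[j]]),
                 tolerance = 1e-9)
  }
})

test_that("a rigid whole-system motion does not create ligand RMSD", {
  pb <- make_pose_blobs(1, 4, sigma = 0, seed = 32)
  tr <- pb$trajectory
  R <- random_rotation()
  for (i in 2:4) {
    fr <- tr$coords[i, , ]
    tr$coords[i, , ] <- sweep(fr %*% t(R), 2, c(3, -2, 8), "+")
  }
  dm <- ligand_rmsd_matrix(tr, "name CA", "resname G3P")
  expect_lt(max(dm$values), 1e-6)
})

test_that("ligand translation with fixed receptor shows up at full size", {
  pb <- make_pose_blobs(1, 2, sigma = 0, seed = 33)
  tr <- pb$trajectory
  l_idx <- select_atoms(tr$topology, "resname G3P")$indices
  tr$coords[2, l_idx, 1] <- tr$coords[2, l_idx, 1] + 4
  dm <- ligand_rmsd_matrix(tr, "name CA", "resname G3P")
  expect_equal(dm$values[1, 2], 4.0, tolerance = 1e-9)
})

test_that("greedy neighbour-count clustering handles hand-built cases", {
  # identical frames: one cluster holding 100%
  z <- matrix(0, 6, 6)
  cl <- gromos_cluster(z, cutoff = 3)
  expect_length(cl$clusters, 1)
  expect_equal(cluster_sizes(cl), 100)

  # frames {1,2,3} mutually close, {4,5} close, groups far apart
  d <- matrix(50, 5, 5); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 1; d[1, 3] <- d[3, 1] <- 1.5; d[2, 3] <- d[3, 2] <- 1
  d[4, 5] <- d[5, 4] <- 2
  cl <- gromos_cluster(d, cutoff = 3)
  expect_equal(lapply(cl$clusters, `[[`, "members"),
               list(1:3, 4:5))
  ref <- daura_reference(d, 3)
  expect_equal(lapply(cl$clusters, `[[`, "members"),
               lapply(ref, `[[`, "members"))
})

test_that("clustering equals the brute-force Daura oracle on random matrices", {
  set.seed(99)
  for (rep in 1:40) {
    d <- random_distance_matrix(10)
    cutoff <- runif(1, 1, 5)
    cl <- gromos_cluster(d, cutoff)
    ref <- daura_reference(d, cutoff)
    expect_equal(lapply(cl$clusters, `[[`, "centroid"),
                 lapply(ref, `[[`, "centroid"))
    expect_equal(lapply(cl$clusters, `[[`, "members"),
                 lapply(ref, `[[`, "members"))
    # every member within cutoff of its centroid; sizes partition the set
    for (c_ in cl$clusters) {
      expect_true(all(d[c_$centroid, c_$members] <= cutoff))
    }
    expect_equal(sort(unlist(lapply(cl$clusters, `[[`, "members"))), 1:10)
    expect_equal(sum(cluster_sizes(cl)), 100, tolerance = 1e-9)
    sizes <- vapply(cl$clusters, function(c_) length(c_$members), integer(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("removing the first cluster leaves the remaining clusters unchanged", {
  set.seed(17)
  d <- random_distance_matrix(12)
  cl <- gromos_cluster(d, 2.5)
  first <- cl$clusters[[1]]$members
  keep <- setdiff(1:12, first)
  cl2 <- gromos_cluster(d[keep, keep, drop = FALSE], 2.5)
  remapped <- lapply(cl2$clusters, function(c_) keep[c_$members])
  expect_equal(lapply(cl$clusters[-1], `[[`, "members"), remapped)
})

test_that("designed pose splits and centroids are recovered", {
  pb <- make_pose_blobs(2, c(275, 725), sigma = 0, seed = 34)
  dm <- ligand_rmsd_matrix(pb$trajectory, "name CA", "resname G3P")
  cl <- gromos_cluster(dm, 3)
  expect_equal(cluster_sizes(cl), c(72.5, 27.5))

  pb3 <- make_pose_blobs(3, 60, sigma = 0.3, separation = 12, seed = 35)
  dm3 <- ligand_rmsd_matrix(pb3$trajectory, "name CA", "resname G3P")
  cl3 <- gromos_cluster(dm3, 3)
  expect_length(cl3$clusters, 3)
  mem <- cluster_membership(cl3)
  # cluster labels agree with ground-truth pose ids up to relabelling
  expect_equal(length(unique(paste(mem, pb3$truth$pose_id))), 3)

  # centroid frame is a member of its own cluster with maximal neighbour
  # count at formation
  cent <- cl3$clusters[[1]]
  expect_true(cent$centroid %in% cent$members)
  counts <- rowSums(dm3$values[, , drop = FALSE] <= 3)
  expect_true(counts[cent$centroid] == max(counts))
})

test_that("centroid structures carry the aligned centroid coordinates", {
  pb <- make_pose_blobs(2, 10, sigma = 0.2, separation = 12, seed = 36)
  dm <- ligand_rmsd_matrix(pb$trajectory, "name CA", "resname G3P")
  cl <- gromos_cluster(dm, 3)
  st <- centroid_structure(pb$trajectory, cl, 1, dm)
  expect_s3_class(st, "md_structure")
  row <- cl$clusters[[1]]$centroid
  expect_equal(st$xyz, dm$aligned_coords[row, , ], tolerance = 1e-9)
  expect_error(centroid_structure(pb$trajectory, cl, 99, dm), "out of range")
  tab <- cluster_table(cl, dm)
  expect_equal(sum(tab$size_pct), 100, tolerance = 1e-9)
})
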