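test_that("generators are pure functions of their seed", {
  w1 <- simulate_mode_walk(default_transition_matrix(), 500, seed = 9)
  w2 <- simulate_mode_walk(default_transition_matrix(), 500, seed = 9)
  expect_identical(w1, w2)
  expect_false(identical(
    w1, simulate_mode_walk(default_transition_matrix(), 500, seed = 10)))

  rec <- make_reference_receptor(1)
  spec <- synthetic_spec()
  e1 <- emit_trajectory(rec, w1, spec, seed = 3)
  e2 <- emit_trajectory(rec, w1, spec, seed = 3)
  expect_identical(e1$trajectory$coords, e2$trajectory$coords)

  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_mode_walk(default_transition_matrix(),
                                              100, seed = 4))
  expect_identical(rnorm(1), before)
})

test_that("the reference receptor is deterministic and rewrites identically", {
  rec <- make_reference_receptor(1)
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(rec, p1)
  write_structure(make_reference_receptor(1), p2)
  expect_identical(readLines(p1), readLines(p2))
  # anchors co-occurring in one mode are mutually reachable (within 8 A)
  idx <- function(resno, nm) which(rec$atoms$resno == resno &
                                     rec$atoms$name == nm)
  d <- function(i, j) sqrt(sum((rec$xyz[i, ] - rec$xyz[j, ])^2))
  expect_lt(d(idx(427, "CZ"), idx(426, "NZ")), 8)
  expect_lt(d(idx(427, "CZ"), idx(365, "NZ")), 8)
  expect_lt(d(idx(296, "NZ"), idx(292, "CZ")), 8)
  expect_lt(d(idx(148, "CZ"), idx(374, "CZ")), 8)
})

test_that("spec validation enforces the mode-geometry invariants", {
  expect_s3_class(synthetic_spec(), "synthetic_spec")
  expect_true(min(synthetic_spec()$margins) >= 1)

  # a mode-2 point placed at the mode-1 hotspot satisfies mode 1's
  # conditions and must be rejected
  pts <- default_mode_points_for_test()
  pts["2", ] <- pts["1", ]
  expect_error(synthetic_spec(mode_points = pts), "mode geometry invalid")

  # malformed transition matrices are rejected
  bad <- default_transition_matrix(); bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(synthetic_spec(transition_matrix = bad), "sum to 1")
  expect_error(simulate_mode_walk(bad, 10), "sum")
  expect_error(synthetic_spec(jitter_sigma = -1), ">= 0")
})

test_that("an absorbing chain stays put and a fair coin balances", {
  const <- simulate_mode_walk(diag(6), 200, seed = 5, start = 1)
  expect_true(all(const == 1L))
  coin <- matrix(0.5, 2, 2)
  w <- simulate_mode_walk(coin, 10000, seed = 6)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(w == 1) - 0.5), 3 * se)
})

test_that("noise-free emission is recovered exactly; sigma 0.5 almost surely", {
  rec <- make_reference_receptor()
  n <- 10000
  labs <- simulate_mode_walk(default_transition_matrix(), n, seed = 61)
  em0 <- emit_trajectory(rec, labs, synthetic_spec(jitter_sigma = 0),
                         seed = 62)
  tr0 <- assign_modes(compute_distance_table(em0$trajectory))
  expect_equal(mean(tr0$labels == labs), 1)
  em5 <- emit_trajectory(rec, labs, synthetic_spec(jitter_sigma = 0.5),
                         seed = 63)
  tr5 <- assign_modes(compute_distance_table(em5$trajectory))
  expect_gte(mean(tr5$labels == labs), 0.99)
})

test_that("oversized jitter triggers the misassignment warning", {
  rec <- make_reference_receptor()
  expect_warning(
    emit_trajectory(rec, c(1L, 2L, 3L), synthetic_spec(jitter_sigma = 1.5),
                    seed = 7),
    "misassignment")
})

test_that("pose blobs encode their design: counts, sites, ground truth", {
  pb <- make_pose_blobs(3, c(10, 20, 30), sigma = 0, separation = 12,
                        seed = 71)
  expect_equal(n_frames(pb$trajectory), 60)
  expect_equal(pb$truth$pose_id, rep(1:3, times = c(10, 20, 30)))
  # sigma = 0: frames of one pose are identical; distinct poses 12 A apart
  p_idx <- select_atoms(pb$trajectory$topology,
                        "resname G3P and name P")$indices
  p1 <- pb$trajectory$coords[1, p_idx, ]
  p11 <- pb$trajectory$coords[11, p_idx, ]
  expect_equal(pb$trajectory$coords[2, p_idx, ], p1)
  expect_equal(sqrt(sum((p11 - p1)^2)), 12)
  # single blob clusters into one cluster
  one <- make_pose_blobs(1, 20, sigma = 0.3, seed = 72)
  dm <- ligand_rmsd_matrix(one$trajectory, "name CA", "resname G3P")
  expect_length(gromos_cluster(dm, 3)$clusters, 1)
})

test_that("multi-copy studies pool into boundary-aware analyses", {
  spec <- synthetic_spec(jitter_sigma = 0)
  study <- simulate_hotspot_study(spec, n_copies = 3, frames_per_copy = 200,
                                  seed = 81)
  expect_length(study$trajectories, 3)
  tab <- compute_distance_table(study$trajectories)
  expect_equal(attr(tab, "boundaries"), c(1L, 201L, 401L))
  trace <- assign_modes(tab)
  expect_equal(trace$labels, study$truth$true_mode)
  ts <- transition_summary(trace)
  true_changes <- sum(vapply(split(study$truth$true_mode, study$truth$copy),
                             function(x) sum(diff(x) != 0), numeric(1)))
  expect_equal(sum(ts$matrix), true_changes)
})
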