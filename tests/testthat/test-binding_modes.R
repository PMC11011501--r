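test_that("default profile encodes the six-mode distance conditions", {
  defs <- default_mode_definitions()
  expect_length(defs, 6)
  m1 <- defs[[1]]
  expect_equal(m1$mode_id, 1L)
  expect_equal(vapply(m1$conditions, function(cc) cc$anchor$label,
                      character(1)), c("R427", "H248"))
  expect_equal(vapply(m1$conditions, `[[`, numeric(1), "cutoff"), c(5, 11))
  expect_equal(m1$conditions[[2]]$anchor$atom, "NE2")
  # all other cutoffs are 5 A
  other <- unlist(lapply(defs[2:5], function(d)
    vapply(d$conditions, `[[`, numeric(1), "cutoff")))
  expect_true(all(other == 5))
  # anchor atom types: NZ for Lys, CZ for Arg
  anchors <- unlist(lapply(defs, function(d)
    lapply(d$conditions, `[[`, "anchor")), recursive = FALSE)
  for (a in anchors) {
    expected <- switch(a$resname, ARG = "CZ", LYS = "NZ", HIS = "NE2")
    expect_equal(a$atom, expected)
  }
  m6 <- defs[[6]]
  expect_true(m6$fallback)
  expect_length(m6$conditions, 0)
  expect_equal(anyDuplicated(vapply(defs, `[[`, integer(1), "precedence")), 0)
  # the ND1 alternative for the histidine anchor is selectable
  alt <- default_mode_definitions(his_atom = "ND1")
  expect_equal(alt[[1]]$conditions[[2]]$anchor$atom, "ND1")
})

test_that("the shipped YAML profile equals the built-in definitions", {
  path <- system.file("extdata", "gpat4_g3p_modes.yaml",
                      package = "bindmodes")
  from_yaml <- read_mode_definitions(path)
  expect_equal(unclass(from_yaml), unclass(default_mode_definitions()),
               ignore_attr = TRUE)
  # write -> read round-trips
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_mode_definitions(default_mode_definitions(), tmp)
  expect_equal(unclass(read_mode_definitions(tmp)),
               unclass(default_mode_definitions()), ignore_attr = TRUE)
})

test_that("distance table reproduces closed-form and brute-force distances", {
  rec <- make_reference_receptor()
  spec <- synthetic_spec(jitter_sigma = 0)
  # one frame: mode-1 point (3,0,0); R427 CZ at origin -> 3; H248 at 11.5
  em <- emit_trajectory(rec, 1L, spec, seed = 1)
  tab <- compute_distance_table(em$trajectory)
  expect_equal(unname(tab[1, "R427"]), 3.0, tolerance = 1e-9)
  expect_equal(unname(tab[1, "H248"]), 8.5, tolerance = 1e-9)
  # ten jittered frames against a per-frame, per-anchor loop
  labs <- simulate_mode_walk(spec$transition_matrix, 10, seed = 2)
  em <- suppressWarnings(
    emit_trajectory(rec, labs, synthetic_spec(jitter_sigma = 1.5), seed = 3))
  tab <- compute_distance_table(em$trajectory)
  tr <- em$trajectory
  p_idx <- select_atoms(tr$topology, "resname G3P and name P")$indices
  for (lab in colnames(tab)) {
    a <- anchor_atom(lab, atom = if (lab == "H248") "NE2" else NULL)
    ai <- which(tr$topology$atoms$resno ==
                  a$resno & tr$topology$atoms$name == a$atom)
    for (i in 1:10) {
      expect_equal(unname(tab[i, lab]),
                   sqrt(sum((tr$coords[i, p_idx, ] - tr$coords[i, ai, ])^2)),
                   tolerance = 1e-12)
    }
  }
})

test_that("a 3-4-5 arrangement yields distance 5 and coincidence yields 0", {
  atoms <- rbind(
    data.frame(name = "CZ", elem = "C", resname = "ARG", resno = 427L,
               chain = "A", occ = 1),
    data.frame(name = "P", elem = "P", resname = "G3P", resno = 999L,
               chain = "A", occ = 1))
  topo <- md_structure(atoms, rbind(c(3, 4, 0), c(0, 0, 0)))
  coords <- array(NA_real_, dim = c(2, 2, 3))
  coords[1, , ] <- topo$xyz
  coords[2, 1, ] <- c(1, 1, 1); coords[2, 2, ] <- c(1, 1, 1)
  tr <- md_trajectory(topo, coords)
  tab <- compute_distance_table(tr, defs = list(R427 = anchor_atom("R427")))
  expect_equal(unname(tab[, "R427"]), c(5, 0))
})

test_that("mode assignment follows conditions and precedence", {
  defs <- default_mode_definitions()
  anchors <- names(profile_anchors_for_test(defs))
  mk <- function(...) {
    row <- rep(99, length(anchors)); names(row) <- anchors
    set <- list(...)
    row[names(set)] <- unlist(set)
    matrix(row, nrow = 1, dimnames = list(NULL, anchors))
  }
  # mode 1: R427 close and H248 within 11
  expect_equal(assign_modes(mk(R427 = 4, H248 = 9), defs)$labels, 1L)
  # everything distant: fallback mode 6
  expect_equal(assign_modes(mk(), defs)$labels, 6L)
  # satisfying modes 2 and 5 but not 1: precedence gives mode 2
  expect_equal(assign_modes(mk(K296 = 4, R292 = 4, R427 = 4, K365 = 4),
                            defs)$labels, 2L)
  # satisfying modes 3 and 5: precedence 5 before 3
  expect_equal(assign_modes(mk(R427 = 4, K426 = 4, K365 = 4), defs)$labels,
               5L)
  # boundary inclusive: exactly at the cutoff still satisfies
  expect_equal(assign_modes(mk(R427 = 5, H248 = 11), defs)$labels, 1L)
  # missing anchor column is an error
  bad <- mk()[, -1, drop = FALSE]
  expect_error(assign_modes(bad, defs), "lacks anchor")
})

test_that("occupancies cover declared modes and always sum to 100", {
  tr <- mode_trace(c(1L, 1L, 3L, 3L, 1L), mode_ids = 1:6)
  occ <- mode_occupancy(tr)
  expect_equal(unname(occ[c("1", "3")]), c(60, 40))
  expect_equal(unname(occ[c("2", "4", "5", "6")]), rep(0, 4))
  expect_equal(sum(occ), 100, tolerance = 1e-9)
  all_one <- mode_occupancy(mode_trace(rep(1L, 50), mode_ids = 1:6))
  expect_equal(unname(all_one["1"]), 100)
})

test_that("represented traces keep the first frame and per-copy structure", {
  lab <- rep(1:2, each = 1000)
  tr <- mode_trace(lab, boundaries = c(1L, 1001L), mode_ids = 1:6)
  rep500 <- represent_frames(tr, 500)
  expect_length(rep500$labels, 1000)
  expect_equal(rep500$boundaries, c(1L, 501L))
  expect_equal(unique(rep500$labels[1:500]), 1L)
  # 2000-frame copy at n = 1000 is every 2nd frame, first retained
  lab2 <- seq_len(2000) %% 2L + 1L   # alternating 2,1,2,1,...
  tr2 <- mode_trace(lab2, mode_ids = 1:6)
  rep1000 <- represent_frames(tr2, 1000)
  expect_length(rep1000$labels, 1000)
  expect_equal(rep1000$labels, lab2[seq(1, 2000, by = 2)])
  # n = T is the identity
  expect_equal(represent_frames(tr2, 2000)$labels, lab2)
  # 8 copies x 1000 -> concatenated length 8000 with 8 boundaries
  big <- mode_trace(rep(1L, 16000), boundaries = seq(1L, 16000L, by = 2000L),
                    mode_ids = 1:6)
  rep8 <- represent_frames(big, 1000)
  expect_length(rep8$labels, 8000)
  expect_equal(rep8$boundaries, seq(1L, 8000L, by = 1000L))
  # short copies are kept whole, with a warning
  expect_warning(short <- represent_frames(
    mode_trace(c(1L, 2L, 1L), mode_ids = 1:6), 10), "fewer")
  expect_length(short$labels, 3)
  expect_error(represent_frames(tr2, 0), "positive")
})

test_that("transitions are counted between consecutive frames only", {
  expect_equal(sum(transition_summary(
    mode_trace(rep(2L, 100), mode_ids = 1:6))$matrix), 0)
  ts <- transition_summary(mode_trace(c(1L, 3L, 3L, 5L), mode_ids = 1:6))
  expect_equal(ts$matrix["1", "3"], 1L)
  expect_equal(ts$matrix["3", "5"], 1L)
  expect_equal(sum(ts$matrix), 2L)
  expect_equal(ts$events$from, c(1L, 3L))
  expect_equal(ts$events$to, c(3L, 5L))
  # pairs straddling a copy boundary are excluded
  tsb <- transition_summary(mode_trace(c(1L, 1L, 2L, 2L),
                                       boundaries = c(1L, 3L),
                                       mode_ids = 1:6))
  expect_equal(sum(tsb$matrix), 0)
  expect_equal(nrow(tsb$events), 0)
})

test_that("raising the H248 cutoff never decreases mode-1 occupancy", {
  spec <- synthetic_spec()
  rec <- make_reference_receptor()
  labs <- simulate_mode_walk(spec$transition_matrix, 1000, seed = 41)
  em <- suppressWarnings(
    emit_trajectory(rec, labs, synthetic_spec(jitter_sigma = 2), seed = 42))
  tab <- compute_distance_table(em$trajectory)
  occ1 <- sapply(c(6, 9, 11, 14, 20), function(cut) {
    defs <- default_mode_definitions()
    defs[[1]]$conditions[[2]]$cutoff <- cut
    mode_occupancy(assign_modes(tab, defs))["1"]
  })
  expect_true(all(diff(occ1) >= 0))
})

test_that("occupancies of an i.i.d. mode walk recover the target profile", {
  pi_target <- c(32.3, 17.8, 9.1, 8.9, 13.2, 18.7) / 100
  tm <- matrix(pi_target, 6, 6, byrow = TRUE)   # i.i.d. sampling rows
  n <- 10000
  labs <- simulate_mode_walk(tm, n, seed = 43)
  rec <- make_reference_receptor()
  em <- emit_trajectory(rec, labs, synthetic_spec(transition_matrix = tm),
                        seed = 44)
  occ <- mode_occupancy(assign_modes(compute_distance_table(em$trajectory)))
  for (m in 1:6) {
    se <- sqrt(pi_target[m] * (1 - pi_target[m]) / n)
    expect_lt(abs(occ[as.character(m)] / 100 - pi_target[m]), 3 * se)
  }
  expect_equal(sum(occ), 100, tolerance = 1e-9)
})
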