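# Synthetic hotspot-hopping trajectories.
#
# Real binding-mode trajectories come from hundreds of nanoseconds of
# membrane-protein MD that cannot be redistributed or regenerated at desk
# scale.  The generator below emulates the statistical structure those
# analyses assume -- a ligand whose phosphorus hops between hotspots
# anchored on charged residues, with Markov switching and Gaussian
# positional noise -- so every analysis stage can be verified against
# ground truth.  It emulates label/geometry statistics only: no force
# field, no solvent, no membrane, no internal ligand flexibility.

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Rigid 10-heavy-atom ligand fragment with one phosphorus, in local
# coordinates with P at the origin.  A glycerophosphate-like shape is
# enough for RMSD clustering and contact statistics; no chemistry implied.
ligand_fragment_offsets <- function() {
  m <- rbind(
    P   = c( 0.0,  0.0,  0.0),
    O1P = c( 1.4,  0.6,  0.6),
    O2P = c(-1.2,  0.9,  0.6),
    O3P = c( 0.0, -1.0,  1.1),
    O3  = c( 0.2,  0.6, -1.4),
    C3  = c( 0.3,  0.1, -2.7),
    C2  = c( 0.5,  1.1, -3.8),
    O2  = c( 1.7,  1.8, -3.6),
    C1  = c( 0.5,  0.5, -5.2),
    O1  = c(-0.7, -0.2, -5.5)
  )
  colnames(m) <- NULL
  m
}

ligand_atom_table <- function(resno = 999L) {
  nm <- c("P", "O1P", "O2P", "O3P", "O3", "C3", "C2", "O2", "C1", "O1")
  data.frame(name = nm, elem = c("P", rep("O", 4), "C", "C", "O", "C", "O"),
             resname = "G3P", resno = resno, chain = "A", occ = 1,
             stringsAsFactors = FALSE)
}

# Fixed anchor-atom and hotspot geometry.  The R427 hub carries modes 1, 3
# and 5; the K296/R292 pair (mode 2) and the R148/R374 pair (mode 4) are
# separate hotspot groups >= 15 A away.  Every mode point satisfies its own
# conditions and violates all higher-precedence modes' conditions with
# margin >= 2 A (validated at construction).
default_anchor_coords <- function() {
  rbind(
    R427 = c(  0.0,  0.0,   0.0),
    H248 = c( 11.5,  0.0,   0.0),
    K426 = c( -3.0,  0.0,   5.0),
    K365 = c( -3.0,  0.0,  -5.0),
    K296 = c(  0.0, 18.0,   0.0),
    R292 = c(  0.0, 22.0,   0.0),
    R148 = c(  0.0,  0.0,  21.0),
    R374 = c(  0.0,  0.0,  25.0)
  )
}

default_mode_points <- function() {
  rbind(
    `1` = c(  3.0,   0.0,   0.0),
    `2` = c(  0.0,  20.0,   0.0),
    `3` = c( -1.5,   0.0,   2.5),
    `4` = c(  0.0,   0.0,  23.0),
    `5` = c( -1.5,   0.0,  -2.5),
    `6` = c( 20.0, -20.0, -10.0)
  )
}

#' Default transition matrix of the synthetic mode walk
#'
#' A sticky Markov chain `P = p I + (1 - p) 1 pi'` whose stationary
#' distribution is exactly `pi`. The default `pi` is the six-mode
#' occupancy profile of the default mode definitions' system
#' (32.3, 17.8, 9.1, 8.9, 13.2, 18.7 percent), so long synthetic runs
#' reproduce those occupancies in expectation, and `p = 0.99` gives the
#' dwell-and-hop timeline structure of concatenated multi-copy
#' simulations.
#'
#' @param persistence probability of staying put per step before the
#'   stationary mixture kicks in.
#' @param pi stationary occupancy over the six modes (percent or
#'   proportions; normalised internally).
#' @return 6 x 6 row-stochastic matrix.
#' @export
default_transition_matrix <- function(persistence = 0.99,
                                      pi = c(32.3, 17.8, 9.1, 8.9, 13.2, 18.7)) {
  pi <- pi / sum(pi)
  k <- length(pi)
  persistence * diag(k) + (1 - persistence) * matrix(pi, k, k, byrow = TRUE)
}

#' Specification of a synthetic hotspot-hopping system
#'
#' Bundles the anchor geometry, per-mode target points, Markov transition
#' matrix and noise level, and validates the geometric invariants the
#' recovery guarantees rest on: each mode's point satisfies all of that
#' mode's distance conditions and violates at least one condition of every
#' higher-precedence mode, both with a stated margin.
#'
#' @param defs a `mode_profile` (default profile by default).
#' @param anchors named matrix of anchor-atom coordinates (rows = anchor
#'   labels).
#' @param mode_points matrix of per-mode ligand phosphorus target points
#'   (rownames = mode ids).
#' @param transition_matrix row-stochastic matrix over the modes.
#' @param jitter_sigma isotropic Gaussian positional noise, Angstrom.
#' @param n_frames default frame count for generated walks.
#' @param seed default RNG seed.
#' @param min_margin smallest acceptable satisfaction/violation margin (A).
#' @return a validated `synthetic_spec`.
#' @export
synthetic_spec <- function(defs = default_mode_definitions(),
                           anchors = default_anchor_coords(),
                           mode_points = default_mode_points(),
                           transition_matrix = default_transition_matrix(),
                           jitter_sigma = 0.5, n_frames = 10000L,
                           seed = 1L, min_margin = 1.0) {
  validate_mode_profile(defs)
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
  if (n_frames < 1L) stop("n_frames must be >= 1")
  k <- length(defs)
  tm <- as.matrix(transition_matrix)
  if (!all(dim(tm) == k)) stop("transition matrix must be ", k, " x ", k)
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-12)) {
    stop("transition matrix rows must be non-negative and sum to 1")
  }
  ids <- vapply(defs, `[[`, integer(1), "mode_id")
  if (!all(as.character(ids) %in% rownames(mode_points))) {
    stop("mode_points must have one row per mode id")
  }
  margins <- mode_point_margins(defs, anchors, mode_points)
  if (any(margins < min_margin)) {
    bad <- names(margins)[which.min(margins)]
    stop("mode geometry invalid: ", bad, " margin ",
         format(min(margins), digits = 3), " A < required ", min_margin,
         " A (each mode point must satisfy its own conditions and violate ",
         "all higher-precedence modes' conditions)")
  }
  structure(list(defs = defs, anchors = anchors, mode_points = mode_points,
                 transition_matrix = tm, jitter_sigma = jitter_sigma,
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 margins = margins),
            class = "synthetic_spec")
}

# Satisfaction margin of each mode's own conditions and violation margin
# against every higher-precedence mode; returns the binding margins, named.
mode_point_margins <- function(defs, anchors, mode_points) {
  prec <- vapply(defs, `[[`, integer(1), "precedence")
  ord <- order(prec)
  margins <- numeric(0)
  for (i in seq_along(ord)) {
    d <- defs[[ord[i]]]
    pt <- mode_points[as.character(d$mode_id), ]
    if (!d$fallback) {
      for (cc in d$conditions) {
        dist <- sqrt(sum((pt - anchors[cc$anchor$label, ])^2))
        margins[paste0("mode", d$mode_id, "_satisfies_", cc$anchor$label)] <-
          cc$cutoff - dist
      }
    }
    for (j in seq_len(i - 1L)) {
      h <- defs[[ord[j]]]
      if (h$fallback) next
      viol <- vapply(h$conditions, function(cc) {
        sqrt(sum((pt - anchors[cc$anchor$label, ])^2)) - cc$cutoff
      }, numeric(1))
      margins[paste0("mode", d$mode_id, "_violates_mode", h$mode_id)] <-
        max(viol)   # the conjunction fails if any one condition fails
    }
  }
  margins
}

#' Minimal reference receptor for synthetic trajectories
#'
#' A deterministic structure holding the eight anchor residues (R148,
#' H248, R292, K296, K365, R374, K426, R427 with CZ/NZ/NE2 anchor atoms
#' and a backbone CA each) at the default hotspot geometry, plus three
#' glycine filler residues used by contact-frequency tests: G901 sits 2
#' Angstrom from the mode-1 hotspot (in contact exactly when the ligand is
#' in mode 1), G902 likewise for mode 2, and G903 is 60+ Angstrom from
#' everything (never in contact).
#'
#' @param seed RNG seed (the geometry is fixed; the argument keeps the
#'   generator API uniform and seed-pure).
#' @return an [md_structure].
#' @export
make_reference_receptor <- function(seed = 1L) {
  anchors <- default_anchor_coords()
  resname <- c(R427 = "ARG", H248 = "HIS", K426 = "LYS", K365 = "LYS",
               K296 = "LYS", R292 = "ARG", R148 = "ARG", R374 = "ARG")
  aname <- c(R427 = "CZ", H248 = "NE2", K426 = "NZ", K365 = "NZ",
             K296 = "NZ", R292 = "CZ", R148 = "CZ", R374 = "CZ")
  labels <- rownames(anchors)
  resno <- as.integer(substr(labels, 2, nchar(labels)))
  ord <- order(resno)
  atoms <- list(); xyz <- list()
  ca_offset <- c(0.8, 1.4, 1.0)   # backbone stub next to each anchor atom
  for (lab in labels[ord]) {
    rn <- as.integer(substr(lab, 2, nchar(lab)))
    atoms[[length(atoms) + 1L]] <- data.frame(
      name = c("CA", aname[[lab]]), elem = c("C", substr(aname[[lab]], 1, 1)),
      resname = resname[[lab]], resno = rn, chain = "A", occ = 1,
      stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <- rbind(anchors[lab, ] + ca_offset,
                                     anchors[lab, ])
  }
  fillers <- rbind(`901` = c(5, 0, 0),      # 2.0 A from the mode-1 point
                   `902` = c(2, 20, 0),     # 2.0 A from the mode-2 point
                   `903` = c(40, 40, 40))   # far from every hotspot
  for (rn in rownames(fillers)) {
    atoms[[length(atoms) + 1L]] <- data.frame(
      name = "CA", elem = "C", resname = "GLY", resno = as.integer(rn),
      chain = "A", occ = 1, stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <- fillers[rn, , drop = FALSE]
  }
  md_structure(do.call(rbind, atoms), do.call(rbind, xyz))
}

#' Markov-chain realisation of the mode walk
#'
#' @param transition_matrix row-stochastic matrix over modes; rows/columns
#'   follow `mode_ids`.
#' @param n_frames walk length.
#' @param seed RNG seed; the walk is a pure function of it.
#' @param start starting mode id.
#' @param mode_ids mode labels (default `1:nrow`).
#' @return integer vector of mode labels, length `n_frames`.
#' @export
simulate_mode_walk <- function(transition_matrix, n_frames, seed = 1L,
                               start = 1L,
                               mode_ids = seq_len(nrow(transition_matrix))) {
  tm <- as.matrix(transition_matrix)
  if (nrow(tm) != ncol(tm) || any(tm < 0) ||
      any(abs(rowSums(tm) - 1) > 1e-12)) {
    stop("transition matrix must be square, non-negative, rows summing to 1")
  }
  k <- nrow(tm)
  stopifnot(start %in% mode_ids, length(mode_ids) == k)
  state <- match(start, mode_ids)
  with_seed(seed, {
    labels <- integer(n_frames)
    labels[1L] <- state
    if (n_frames > 1L) {
      u <- stats::runif(n_frames - 1L)
      cum <- t(apply(tm, 1L, cumsum))
      for (i in 2:n_frames) {
        state <- findInterval(u[i - 1L], cum[state, ]) + 1L
        labels[i] <- state
      }
    }
    mode_ids[labels]
  })
}

#' Emit a synthetic trajectory from a mode-label sequence
#'
#' The receptor is held rigid; in every frame the ligand fragment is
#' placed with its phosphorus at the labelled mode's hotspot point plus an
#' isotropic Gaussian displacement of the whole (rigid) fragment. With the
#' default geometry the satisfaction/violation margins are >= 2 Angstrom,
#' so at `jitter_sigma <= 0.5` label recovery by [assign_modes()] is
#' essentially exact; if the noise is large relative to the margins a
#' warning reports the per-frame misassignment bound.
#'
#' @param receptor an [md_structure] containing the anchor residues
#'   (typically [make_reference_receptor()]).
#' @param labels integer mode labels, e.g. from [simulate_mode_walk()].
#' @param spec a `synthetic_spec`.
#' @param seed RNG seed for the jitter.
#' @param source_id trajectory copy label.
#' @return list with `trajectory` (an [md_trajectory] over receptor +
#'   ligand), `truth` (data.frame `frame`, `true_mode`) and
#'   `designed_contacts` (data.frame `residue`, `probability`: the
#'   noise-free contact probability of each receptor residue implied by
#'   the label sequence).
#' @export
emit_trajectory <- function(receptor, labels, spec = synthetic_spec(),
                            seed = 1L, source_id = "synthetic") {
  stopifnot(inherits(receptor, "md_structure"),
            inherits(spec, "synthetic_spec"))
  ids <- vapply(spec$defs, `[[`, integer(1), "mode_id")
  if (!all(labels %in% ids)) stop("labels contain undeclared mode ids")
  sigma <- spec$jitter_sigma
  margin <- min(spec$margins)
  if (sigma > 0) {
    # one-sided normal tail per geometric margin, union over the <= 4
    # conditions that matter for any one frame
    miss_bound <- 4 * stats::pnorm(-margin / sigma)
    if (miss_bound > 0.01) {
      warning("jitter_sigma = ", sigma, " A is large for the geometry ",
              "margin ", format(margin, digits = 3),
              " A: expected misassignment fraction may reach ",
              format(miss_bound, digits = 2))
    }
  }
  offsets <- ligand_fragment_offsets()
  lig_atoms <- ligand_atom_table()
  topo <- md_structure(rbind(receptor$atoms, lig_atoms),
                       rbind(receptor$xyz, offsets))
  n <- length(labels)
  nat <- nrow(topo$atoms)
  nrec <- nrow(receptor$atoms)
  coords <- array(NA_real_, dim = c(n, nat, 3L))
  for (k in 1:3) coords[, seq_len(nrec), k] <-
    matrix(receptor$xyz[, k], n, nrec, byrow = TRUE)
  pts <- spec$mode_points[as.character(labels), , drop = FALSE]
  jit <- with_seed(seed, matrix(stats::rnorm(3L * n, sd = sigma), n, 3L))
  centres <- pts + jit
  for (a in seq_len(nrow(offsets))) {
    for (k in 1:3) coords[, nrec + a, k] <- centres[, k] + offsets[a, k]
  }
  traj <- md_trajectory(topo, coords, source_id = source_id)
  list(trajectory = traj,
       truth = data.frame(frame = seq_len(n), true_mode = labels),
       designed_contacts = designed_contact_probs(receptor, labels, spec))
}

# Noise-free contact probability of each receptor residue given the label
# sequence: a residue is in contact in a frame iff its minimum distance to
# the ligand cloud placed at that frame's mode point is <= 3 A.
designed_contact_probs <- function(receptor, labels, spec, cutoff = 3.0) {
  offsets <- ligand_fragment_offsets()
  key <- paste0(receptor$atoms$chain, ":", receptor$atoms$resname,
                receptor$atoms$resno)
  res_keys <- unique(key)
  ids <- rownames(spec$mode_points)
  contact <- matrix(FALSE, nrow = length(res_keys), ncol = length(ids),
                    dimnames = list(res_keys, ids))
  for (m in ids) {
    cloud <- sweep(offsets, 2L, spec$mode_points[m, ], "+")
    for (r in seq_along(res_keys)) {
      idx <- which(key == res_keys[r])
      contact[r, m] <-
        min_distance(receptor$xyz[idx, , drop = FALSE], cloud) <= cutoff
    }
  }
  freq <- table(factor(as.character(labels), levels = ids)) / length(labels)
  data.frame(residue = res_keys,
             probability = as.numeric(contact %*% as.numeric(freq)),
             stringsAsFactors = FALSE)
}

#' Gaussian pose-blob trajectory for clustering tests
#'
#' `k` rigid ligand poses at well-separated sites; each frame draws one
#' pose (in block order) and adds isotropic Gaussian jitter to the whole
#' fragment. A four-atom rigid receptor stub provides the alignment
#' selection.
#'
#' @param k number of poses.
#' @param n_per_pose frames per pose: scalar or length-`k` vector.
#' @param sigma per-frame Gaussian jitter (Angstrom).
#' @param separation distance between neighbouring pose sites; keep it
#'   above twice the intended clustering cutoff.
#' @param seed RNG seed.
#' @return list with `trajectory` (an [md_trajectory]) and `truth`
#'   (data.frame `frame`, `pose_id`).
#' @export
make_pose_blobs <- function(k, n_per_pose, sigma = 0.3, separation = 12,
                            seed = 1L) {
  stopifnot(k >= 1L)
  if (length(n_per_pose) == 1L) n_per_pose <- rep(n_per_pose, k)
  stopifnot(length(n_per_pose) == k, all(n_per_pose >= 1L))
  # pose sites on a cubic grid scaled by `separation`
  grid <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2))[seq_len(k), ,
                                                            drop = FALSE]
  sites <- grid * separation
  rec_atoms <- data.frame(
    name = c("CA", "CA", "CA", "CA"), elem = "C", resname = "GLY",
    resno = 801:804, chain = "A", occ = 1, stringsAsFactors = FALSE)
  rec_xyz <- rbind(c(-20, 0, 0), c(-20, 5, 0), c(-20, 0, 5), c(-25, 2, 2))
  offsets <- ligand_fragment_offsets()
  topo <- md_structure(rbind(rec_atoms, ligand_atom_table()),
                       rbind(rec_xyz, offsets))
  n <- sum(n_per_pose)
  pose_id <- rep(seq_len(k), times = n_per_pose)
  nat <- nrow(topo$atoms)
  coords <- array(NA_real_, dim = c(n, nat, 3L))
  for (kk in 1:3) coords[, 1:4, kk] <- matrix(rec_xyz[, kk], n, 4, byrow = TRUE)
  jit <- with_seed(seed, matrix(stats::rnorm(3L * n, sd = sigma), n, 3L))
  centres <- sites[pose_id, , drop = FALSE] + jit
  for (a in seq_len(nrow(offsets))) {
    for (kk in 1:3) coords[, 4L + a, kk] <- centres[, kk] + offsets[a, kk]
  }
  list(trajectory = md_trajectory(topo, coords, source_id = "pose_blobs"),
       truth = data.frame(frame = seq_len(n), pose_id = pose_id))
}

#' One-call synthetic multi-copy study
#'
#' Generates `n_copies` independent hotspot-hopping trajectories under a
#' shared `synthetic_spec` (copy `i` uses `seed + i`), mirroring a
#' multi-copy MD campaign whose copies are pooled for analysis.
#'
#' @param spec a `synthetic_spec`.
#' @param n_copies number of independent copies.
#' @param frames_per_copy frames per copy (default `spec$n_frames`).
#' @param seed base RNG seed.
#' @return list with `trajectories` (list of [md_trajectory]), `truth`
#'   (concatenated data.frame `copy`, `frame`, `true_mode`) and `receptor`.
#' @export
simulate_hotspot_study <- function(spec = synthetic_spec(), n_copies = 8L,
                                   frames_per_copy = NULL, seed = NULL) {
  if (is.null(seed)) seed <- spec$seed
  if (is.null(frames_per_copy)) frames_per_copy <- spec$n_frames
  receptor <- make_reference_receptor(seed)
  ids <- vapply(spec$defs, `[[`, integer(1), "mode_id")
  trajs <- list(); truths <- list()
  for (i in seq_len(n_copies)) {
    labs <- simulate_mode_walk(spec$transition_matrix, frames_per_copy,
                               seed = seed + 2L * i, start = ids[1],
                               mode_ids = ids)
    em <- emit_trajectory(receptor, labs, spec, seed = seed + 2L * i + 1L,
                          source_id = paste0("copy", i))
    trajs[[i]] <- em$trajectory
    truths[[i]] <- data.frame(copy = paste0("copy", i), em$truth)
  }
  list(trajectories = trajs, truth = do.call(rbind, truths),
       receptor = receptor)
}
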