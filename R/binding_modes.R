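#' Anchor atom definition
#'
#' A binding-mode anchor is one specific side-chain atom of a positively
#' charged (or catalytic) residue: NZ for lysine, CZ for arginine and, for
#' histidine, NE2 by default (standard histidine has no atom literally
#' named "NE"; ND1 can be chosen instead).
#'
#' @param label short residue label, one-letter code + author residue
#'   number, e.g. `"R427"`.
#' @param atom atom name; default derived from the residue type.
#' @param chain optional chain restriction.
#' @return an `anchor_atom` list: `label`, `resname`, `resno`, `atom`,
#'   `chain`.
#' @export
anchor_atom <- function(label, atom = NULL, chain = NULL) {
  stopifnot(grepl("^[A-Z][0-9]+$", label))
  code <- substr(label, 1, 1)
  resname <- c(R = "ARG", K = "LYS", H = "HIS")[code]
  if (is.na(resname)) stop("unsupported anchor residue type '", code,
                           "' (expected R, K or H)")
  if (is.null(atom)) {
    atom <- unname(c(R = "CZ", K = "NZ", H = "NE2")[code])
  }
  structure(list(label = label, resname = unname(resname),
                 resno = as.integer(substr(label, 2, nchar(label))),
                 atom = atom, chain = chain),
            class = "anchor_atom")
}

# Resolve an anchor to exactly one atom index in a structure.
resolve_anchor <- function(st, anchor) {
  a <- st$atoms
  hit <- a$resno == anchor$resno & a$name == anchor$atom
  if (!is.null(anchor$chain)) hit <- hit & a$chain == anchor$chain
  idx <- which(hit)
  if (length(idx) == 0L) {
    stop("anchor ", anchor$label, ": no atom '", anchor$atom,
         "' in residue ", anchor$resno)
  }
  if (length(idx) > 1L) {
    stop("anchor ", anchor$label, ": ambiguous, matches ", length(idx),
         " atoms (set a chain)")
  }
  if (a$resname[idx] != anchor$resname) {
    stop("anchor ", anchor$label, ": residue ", anchor$resno, " is ",
         a$resname[idx], ", expected ", anchor$resname)
  }
  idx
}

#' Binding-mode definitions
#'
#' A mode is a conjunction of distance conditions: the mode holds in a
#' frame when the distance from the ligand's phosphorus atom to every
#' anchor atom is at or below that condition's cutoff. Exactly one mode is
#' the fallback ("dummy") that collects frames matching no other mode.
#'
#' @param mode_id integer mode label.
#' @param conditions list of `list(anchor = anchor_atom, cutoff = <A>)`;
#'   empty for the fallback.
#' @param precedence rank; when several modes' conditions hold in a frame,
#'   the lowest rank wins.
#' @param fallback is this the dummy catch-all mode?
#' @return a `mode_definition`.
#' @export
mode_definition <- function(mode_id, conditions, precedence,
                            fallback = FALSE) {
  if (!fallback && length(conditions) == 0L) {
    stop("a non-fallback mode needs at least one condition")
  }
  for (cond in conditions) {
    stopifnot(inherits(cond$anchor, "anchor_atom"))
    if (!is.numeric(cond$cutoff) || cond$cutoff <= 0) {
      stop("condition cutoffs must be positive")
    }
  }
  structure(list(mode_id = as.integer(mode_id), conditions = conditions,
                 precedence = as.integer(precedence), fallback = fallback),
            class = "mode_definition")
}

#' Default GPAT4 G3P binding-mode profile
#'
#' The six-mode profile for G3P on GPAT4. Distances are measured from the
#' phosphorus atom of G3P to NZ (Lys), CZ (Arg) or NE2 (His). All cutoffs
#' are 5 Angstrom except the H248 condition of mode 1, which uses 11
#' Angstrom: when G3P sits in the catalytic site its phosphorus holds a
#' steady ~10 Angstrom separation from the catalytic histidine, and that
#' distance alone separates the catalytic-site mode from every hotspot
#' mode. Mode 6 is the dummy fallback.
#'
#' Modes and anchors: 1 = R427 + H248; 2 = K296 + R292; 3 = R427 + K426;
#' 4 = R148 + R374; 5 = R427 + K365; 6 = fallback. Precedence is
#' 1 > 2 > 4 > 5 > 3 > 6: mode 1 is separated first by the histidine
#' distance; the uniquely anchored hotspot modes (2, 4, 5) come next; mode
#' 3 is a remainder class for frames still holding onto R427 and K426
#' during transitions; mode 6 collects the rest.
#'
#' @param his_atom histidine anchor atom name, `"NE2"` (default) or
#'   `"ND1"`.
#' @return list of six `mode_definition`s, a `mode_profile`.
#' @export
default_mode_definitions <- function(his_atom = c("NE2", "ND1")) {
  his_atom <- match.arg(his_atom)
  cond <- function(label, cutoff = 5, atom = NULL) {
    list(anchor = anchor_atom(label, atom = atom), cutoff = cutoff)
  }
  defs <- list(
    mode_definition(1L, list(cond("R427"),
                             cond("H248", cutoff = 11, atom = his_atom)),
                    precedence = 1L),
    mode_definition(2L, list(cond("K296"), cond("R292")), precedence = 2L),
    mode_definition(3L, list(cond("R427"), cond("K426")), precedence = 5L),
    mode_definition(4L, list(cond("R148"), cond("R374")), precedence = 3L),
    mode_definition(5L, list(cond("R427"), cond("K365")), precedence = 4L),
    mode_definition(6L, list(), precedence = 6L, fallback = TRUE)
  )
  validate_mode_profile(defs)
  structure(defs, class = "mode_profile")
}

validate_mode_profile <- function(defs) {
  prec <- vapply(defs, `[[`, integer(1), "precedence")
  if (anyDuplicated(prec)) stop("mode precedence ranks must be unique")
  if (sum(vapply(defs, `[[`, logical(1), "fallback")) != 1L) {
    stop("exactly one fallback mode is required")
  }
  ids <- vapply(defs, `[[`, integer(1), "mode_id")
  if (anyDuplicated(ids)) stop("mode ids must be unique")
  invisible(defs)
}

#' Read / write a mode profile as YAML
#'
#' Mode definitions are data, not code: the default GPAT4 profile ships as
#' `system.file("extdata", "gpat4_g3p_modes.yaml", package = "bindmodes")`
#' and other receptors can be analysed by supplying their own profile.
#'
#' @param path YAML file.
#' @return for `read_mode_definitions`, a `mode_profile`.
#' @export
read_mode_definitions <- function(path) {
  y <- yaml::read_yaml(path)
  defs <- lapply(y$modes, function(m) {
    conds <- lapply(m$conditions, function(cc) {
      list(anchor = anchor_atom(cc$residue, atom = cc$atom,
                                chain = cc$chain),
           cutoff = as.numeric(cc$cutoff))
    })
    mode_definition(m$id, conds, precedence = m$precedence,
                    fallback = isTRUE(m$fallback))
  })
  validate_mode_profile(defs)
  structure(defs, class = "mode_profile")
}

#' @rdname read_mode_definitions
#' @param defs a `mode_profile`.
#' @export
write_mode_definitions <- function(defs, path) {
  y <- list(modes = lapply(defs, function(d) {
    out <- list(id = d$mode_id, precedence = d$precedence)
    if (d$fallback) out$fallback <- TRUE
    out$conditions <- lapply(d$conditions, function(cc) {
      v <- list(residue = cc$anchor$label, atom = cc$anchor$atom,
                cutoff = cc$cutoff)
      if (!is.null(cc$anchor$chain)) v$chain <- cc$anchor$chain
      v
    })
    out
  }))
  yaml::write_yaml(y, path)
  invisible(path)
}

# All distinct anchors referenced by a profile, keyed by label.
profile_anchors <- function(defs) {
  anchors <- list()
  for (d in defs) {
    for (cc in d$conditions) anchors[[cc$anchor$label]] <- cc$anchor
  }
  anchors
}

#' Phosphorus-to-anchor distance table
#'
#' Per-frame Euclidean distance from the ligand phosphorus atom to each
#' anchor atom, pooled over trajectory copies. This table is the sole input
#' of mode assignment.
#'
#' @param trajs an [md_trajectory] or list of them.
#' @param defs a `mode_profile` (or list of `anchor_atom`s).
#' @param ligand_p_sel selection that must resolve to exactly one atom,
#'   default `"resname G3P and name P"`.
#' @return a numeric matrix (frames x anchors, Angstrom) of class
#'   `distance_table`, with attributes `boundaries` (start row of each
#'   copy), `copy_lengths` and `copies`.
#' @export
compute_distance_table <- function(trajs, defs = default_mode_definitions(),
                                   ligand_p_sel = "resname G3P and name P") {
  trajs <- as_traj_list(trajs)
  top <- trajs[[1]]$topology
  p_idx <- resolve_selection(top, ligand_p_sel)
  if (length(p_idx) != 1L) {
    stop("ligand phosphorus selection must resolve to exactly 1 atom, got ",
         length(p_idx))
  }
  anchors <- if (inherits(defs, "mode_profile")) profile_anchors(defs) else defs
  a_idx <- vapply(anchors, function(a) resolve_anchor(top, a), integer(1))
  bounds <- traj_boundaries(trajs)
  out <- matrix(NA_real_, nrow = bounds$total, ncol = length(a_idx),
                dimnames = list(NULL, names(anchors)))
  row <- 0L
  for (tr in trajs) {
    tn <- n_frames(tr)
    p_xyz <- tr$coords[, p_idx, , drop = FALSE]
    dim(p_xyz) <- c(tn, 3L)
    for (j in seq_along(a_idx)) {
      anc <- tr$coords[, a_idx[j], , drop = FALSE]
      dim(anc) <- c(tn, 3L)
      out[row + seq_len(tn), j] <- sqrt(rowSums((p_xyz - anc)^2))
    }
    row <- row + tn
  }
  attr(out, "boundaries") <- bounds$starts
  attr(out, "copy_lengths") <- bounds$lengths
  attr(out, "copies") <- vapply(trajs, `[[`, character(1), "source_id")
  class(out) <- c("distance_table", class(out))
  out
}

#' Assign a binding mode to every frame
#'
#' For each frame, modes are tested in precedence order; the first mode all
#' of whose conditions hold (distance <= cutoff, boundary inclusive) is
#' assigned. Frames satisfying no non-fallback mode receive the fallback
#' mode. Assignment is a pure function of the distance table and the
#' profile.
#'
#' @param table a `distance_table` (or plain matrix with anchor-labelled
#'   columns; boundaries then default to a single copy).
#' @param defs a `mode_profile`.
#' @return a `mode_trace`: list with `labels` (integer per frame),
#'   `boundaries` (first frame of each source copy), `mode_ids` (declared
#'   modes) and `copies`.
#' @export
assign_modes <- function(table, defs = default_mode_definitions()) {
  validate_mode_profile(defs)
  tab <- unclass(table)
  needed <- names(profile_anchors(defs))
  missing_cols <- setdiff(needed, colnames(tab))
  if (length(missing_cols)) {
    stop("distance table lacks anchor column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(tab)
  ord <- order(vapply(defs, `[[`, integer(1), "precedence"))
  labels <- rep(NA_integer_, n)
  fallback_id <- NA_integer_
  for (d in defs[ord]) {
    if (d$fallback) { fallback_id <- d$mode_id; next }
    hold <- rep(TRUE, n)
    for (cc in d$conditions) {
      hold <- hold & tab[, cc$anchor$label] <= cc$cutoff
    }
    assign_now <- is.na(labels) & hold
    labels[assign_now] <- d$mode_id
  }
  labels[is.na(labels)] <- fallback_id
  boundaries <- attr(table, "boundaries")
  if (is.null(boundaries)) boundaries <- 1L
  mode_trace(labels, boundaries = boundaries,
             mode_ids = sort(vapply(defs, `[[`, integer(1), "mode_id")),
             copies = attr(table, "copies"))
}

#' Per-frame mode label trace
#' @param labels integer mode labels, one per frame.
#' @param boundaries 1-based start positions of each source copy.
#' @param mode_ids declared mode ids (zero-count modes still report 0%).
#' @param copies optional copy labels.
#' @param times optional per-frame times.
#' @return a `mode_trace`.
#' @export
mode_trace <- function(labels, boundaries = 1L,
                       mode_ids = sort(unique(labels)), copies = NULL,
                       times = NULL) {
  labels <- as.integer(labels)
  boundaries <- as.integer(boundaries)
  if (length(labels) == 0L) stop("trace must contain at least one frame")
  if (!all(labels %in% mode_ids)) stop("labels outside declared mode_ids")
  if (is.unsorted(boundaries, strictly = TRUE) || boundaries[1] != 1L ||
      any(boundaries > length(labels))) {
    stop("boundaries must be strictly increasing, start at 1 and stay in range")
  }
  if (!is.null(times) && length(times) != length(labels)) {
    stop("times must align with labels")
  }
  structure(list(labels = labels, boundaries = boundaries,
                 mode_ids = as.integer(mode_ids), copies = copies,
                 times = times),
            class = "mode_trace")
}

#' @export
print.mode_trace <- function(x, ...) {
  cat("mode_trace: ", length(x$labels), " frames, ",
      length(x$boundaries), " source copy/copies\n", sep = "")
  occ <- mode_occupancy(x)
  cat("  occupancy (%): ",
      paste(sprintf("%d: %.1f", as.integer(names(occ)), occ),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Mode occupancies
#' @param trace a `mode_trace`.
#' @return named numeric vector: percentage of frames per declared mode
#'   (zero-count modes included); sums to 100.
#' @export
mode_occupancy <- function(trace) {
  stopifnot(inherits(trace, "mode_trace"))
  counts <- table(factor(trace$labels, levels = trace$mode_ids))
  out <- 100 * as.numeric(counts) / length(trace$labels)
  names(out) <- trace$mode_ids
  out
}

#' Uniform-stride representation of a trace or trajectory
#'
#' Downsamples each source copy to `n` frames by uniform stride, always
#' keeping the copy's first frame — the representation used to render
#' multi-copy timelines at a common length (1000 frames per copy).
#' A copy shorter than `n` is kept whole with a warning.
#'
#' @param x a `mode_trace` or [md_trajectory].
#' @param n frames to keep per source copy.
#' @return an object of the same class, with boundaries recomputed.
#' @export
represent_frames <- function(x, n = 1000L) {
  if (n <= 0L) stop("n must be positive")
  UseMethod("represent_frames")
}

stride_indices <- function(len, n) {
  if (len < n) {
    warning("copy has ", len, " frames, fewer than n = ", n,
            "; keeping all frames")
    return(seq_len(len))
  }
  unique(floor((seq_len(n) - 1L) * len / n) + 1L)
}

#' @export
represent_frames.mode_trace <- function(x, n = 1000L) {
  if (n <= 0L) stop("n must be positive")
  ends <- c(x$boundaries[-1L] - 1L, length(x$labels))
  pieces <- list(); new_bounds <- integer(0); total <- 0L
  for (s in seq_along(x$boundaries)) {
    seg <- x$boundaries[s]:ends[s]
    keep <- seg[stride_indices(length(seg), n)]
    new_bounds <- c(new_bounds, total + 1L)
    total <- total + length(keep)
    pieces[[s]] <- x$labels[keep]
  }
  mode_trace(unlist(pieces), boundaries = new_bounds, mode_ids = x$mode_ids,
             copies = x$copies)
}

#' @export
represent_frames.md_trajectory <- function(x, n = 1000L) {
  if (n <= 0L) stop("n must be positive")
  keep <- stride_indices(n_frames(x), n)
  md_trajectory(x$topology, x$coords[keep, , , drop = FALSE],
                frame_index = x$frame_index[keep], source_id = x$source_id)
}

#' Mode-transition counts and events
#'
#' Counts label changes between consecutive frames. Pairs straddling a
#' source-copy boundary are concatenation artefacts, not physical
#' transitions, and are excluded from both the matrix and the event list.
#'
#' @param trace a `mode_trace`.
#' @return list with `matrix` (modes x modes transition counts, from rows
#'   to columns) and `events` (data.frame `frame`, `from`, `to`; `frame` is
#'   the position of the new mode's first frame).
#' @export
transition_summary <- function(trace) {
  stopifnot(inherits(trace, "mode_trace"))
  k <- length(trace$mode_ids)
  mat <- matrix(0L, k, k, dimnames = list(trace$mode_ids, trace$mode_ids))
  lab <- trace$labels
  n <- length(lab)
  if (n >= 2L) {
    from <- lab[-n]; to <- lab[-1L]
    pos <- 2:n
    cross_boundary <- pos %in% trace$boundaries
    changed <- from != to & !cross_boundary
    if (any(changed)) {
      tf <- factor(from[changed], levels = trace$mode_ids)
      tt <- factor(to[changed], levels = trace$mode_ids)
      mat <- mat + unclass(table(tf, tt))
    }
    events <- data.frame(frame = pos[changed], from = from[changed],
                         to = to[changed])
  } else {
    events <- data.frame(frame = integer(0), from = integer(0),
                         to = integer(0))
  }
  dimnames(mat) <- list(trace$mode_ids, trace$mode_ids)
  list(matrix = mat, events = events)
}

#' Timeline plot of binding-mode transitions
#'
#' Frame id against mode label for a concatenated multi-copy trace:
#' horizontal segments per dwell, vertical connectors at transitions,
#' dashed ticks at copy boundaries.
#'
#' @param trace a `mode_trace`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_mode_timeline <- function(trace, ...) {
  stopifnot(inherits(trace, "mode_trace"))
  n <- length(trace$labels)
  graphics::plot(NA, xlim = c(1, n),
                 ylim = range(trace$mode_ids) + c(-0.5, 0.5),
                 xlab = "frame ID", ylab = "binding mode", yaxt = "n", ...)
  graphics::axis(2, at = trace$mode_ids)
  ends <- c(trace$boundaries[-1L] - 1L, n)
  for (s in seq_along(trace$boundaries)) {
    seg <- trace$boundaries[s]:ends[s]
    graphics::lines(seg, trace$labels[seg], type = "s")
  }
  graphics::abline(v = trace$boundaries[-1L] - 0.5, lty = 2, col = "grey60")
  invisible(trace)
}
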