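#' Molecular structure container
#'
#' An `md_structure` holds an ordered atom table plus Cartesian coordinates
#' in Angstrom. Residue numbering is the author numbering of the input file
#' and is never altered: selections and anchor definitions refer to residues
#' exactly as deposited (e.g. R427 of GPAT4).
#'
#' @param atoms data.frame with columns `name` (atom name), `elem` (element
#'   symbol), `resname`, `resno` (integer author numbering), `chain`,
#'   `occ` (occupancy, may be `NA`).
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param box optional numeric vector of 3 box lengths in Angstrom.
#'
#' @return An object of class `md_structure`.
#' @export
md_structure <- function(atoms, xyz, box = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  required <- c("name", "elem", "resname", "resno", "chain", "occ")
  missing_cols <- setdiff(required, names(atoms))
  for (mc in missing_cols) {
    atoms[[mc]] <- switch(mc,
      elem = guess_element(atoms$name),
      chain = "A",
      occ = NA_real_,
      stop("atom table lacks required column '", mc, "'")
    )
  }
  atoms <- atoms[, required]
  atoms$resno <- as.integer(atoms$resno)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns")
  if (nrow(xyz) != nrow(atoms)) {
    stop("atom table (", nrow(atoms), ") and coordinates (", nrow(xyz),
         ") disagree in atom count")
  }
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  rownames(xyz) <- NULL
  structure(list(atoms = atoms, xyz = xyz, box = box),
            class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain", "resname", "resno")]))
  cat("md_structure: ", nrow(x$atoms), " atoms, ", nres, " residues, ",
      length(unique(x$atoms$chain)), " chain(s)\n", sep = "")
  invisible(x)
}

#' Number of atoms in a structure or trajectory
#' @param x an `md_structure` or `md_trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "md_trajectory")) x <- x$topology
  nrow(x$atoms)
}

# Element symbol from a PDB-style atom name: strip digits/primes, first
# letter wins except for two-letter cases we never emit here.  Hydrogens
# named like "1HB" or "HG12" map to H.
guess_element <- function(name) {
  stripped <- gsub("[0-9']", "", trimws(name))
  el <- substr(stripped, 1L, 1L)
  el[el == ""] <- "X"
  toupper(el)
}

#' MD trajectory container
#'
#' A trajectory is a topology (`md_structure`) plus `T` coordinate frames in
#' Angstrom, stored as a `T x N x 3` array. `source_id` labels the
#' originating simulation copy so that concatenated multi-copy analyses can
#' keep copy boundaries.
#'
#' @param topology an `md_structure`.
#' @param coords numeric array `T x N x 3` (or an `N x 3` matrix for a
#'   single frame), Angstrom.
#' @param frame_index optional strictly increasing integer frame ids.
#' @param source_id label of the originating simulation copy.
#'
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, coords, frame_index = NULL,
                          source_id = "traj") {
  stopifnot(inherits(topology, "md_structure"))
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, dim(coords)))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("coords must be a T x N x 3 array")
  }
  if (dim(coords)[1] < 1L) stop("trajectory must contain at least one frame")
  if (dim(coords)[2] != nrow(topology$atoms)) {
    stop("frame atom count (", dim(coords)[2],
         ") does not match topology atom count (", nrow(topology$atoms), ")")
  }
  tn <- dim(coords)[1]
  if (is.null(frame_index)) frame_index <- seq_len(tn)
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != tn || any(diff(frame_index) <= 0L)) {
    stop("frame_index must be strictly increasing, one entry per frame")
  }
  structure(list(topology = topology, coords = coords,
                 frame_index = frame_index, source_id = source_id),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory: ", dim(x$coords)[1], " frames x ", dim(x$coords)[2],
      " atoms (source '", x$source_id, "')\n", sep = "")
  invisible(x)
}

#' Number of frames
#' @param traj an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as a structure
#' @param traj an `md_trajectory`.
#' @param i frame number (1-based position, not frame_index).
#' @return an `md_structure` with that frame's coordinates.
#' @export
frame_structure <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  md_structure(traj$topology$atoms, traj$coords[i, , , drop = TRUE],
               box = traj$topology$box)
}

# Normalise the common "one trajectory or a list of them" argument.
as_traj_list <- function(trajs) {
  if (inherits(trajs, "md_trajectory")) return(list(trajs))
  if (is.list(trajs) && all(vapply(trajs, inherits, logical(1), "md_trajectory")))
    return(trajs)
  stop("expected an md_trajectory or a list of md_trajectory objects")
}

# First frame positions at which each source trajectory starts in a
# concatenation (1-based), plus total length.
traj_boundaries <- function(trajs) {
  trajs <- as_traj_list(trajs)
  lens <- vapply(trajs, n_frames, integer(1))
  list(starts = cumsum(c(1L, lens[-length(lens)])), lengths = lens,
       total = sum(lens))
}
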