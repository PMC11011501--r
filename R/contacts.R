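#' Per-residue ligand contact frequency
#'
#' A residue is "in contact" in a frame when the minimum heavy-atom distance
#' between any of its atoms and any ligand heavy atom is at or below
#' `cutoff` (default 3 Angstrom, the proximity criterion used for
#' substrate-recognition profiling). Frequencies are pooled over all
#' supplied trajectory copies; a per-copy breakdown is attached.
#'
#' Hydrogens are excluded on both sides: crystallographic inputs carry
#' none, and including them for some inputs only would bias the statistic.
#'
#' @param trajs an [md_trajectory] or list of them (same topology).
#' @param ligand_sel ligand selection (expression string or
#'   `atom_selection`); hydrogens are dropped internally.
#' @param cutoff contact cutoff in Angstrom, boundary inclusive.
#' @param residue_scope selection restricting which residues are profiled;
#'   default is every non-ligand residue.
#' @return a `contact_profile` data.frame with columns `residue`
#'   (chain:resname+resno key), `chain`, `resname`, `resno`, `frequency`,
#'   `n_frames`; attributes `cutoff`, `n_total` (pooled frame count),
#'   `ligand_expression` and `per_copy` (frequency matrix, one column per
#'   trajectory copy).
#' @export
contact_frequency <- function(trajs, ligand_sel, cutoff = 3.0,
                              residue_scope = NULL) {
  trajs <- as_traj_list(trajs)
  top <- trajs[[1]]$topology
  lig_idx <- resolve_selection(top, ligand_sel)
  if (length(lig_idx) == 0L) stop("ligand selection matched no atoms")
  lig_idx <- lig_idx[top$atoms$elem[lig_idx] != "H"]
  if (length(lig_idx) == 0L) {
    stop("ligand selection contains only hydrogens; contacts are defined ",
         "over heavy atoms")
  }
  scope_idx <- if (is.null(residue_scope)) {
    setdiff(seq_len(nrow(top$atoms)), resolve_selection(top, ligand_sel))
  } else {
    resolve_selection(top, residue_scope)
  }
  scope_idx <- scope_idx[top$atoms$elem[scope_idx] != "H"]
  if (length(scope_idx) == 0L) stop("residue scope is empty")

  key <- paste0(top$atoms$chain, ":", top$atoms$resname, top$atoms$resno)
  res_keys <- unique(key[scope_idx])
  res_atoms <- split(scope_idx, factor(key[scope_idx], levels = res_keys))

  n_res <- length(res_keys)
  counts <- matrix(0L, nrow = n_res, ncol = length(trajs),
                   dimnames = list(res_keys, vapply(trajs, function(t)
                     t$source_id, character(1))))
  for (j in seq_along(trajs)) {
    tr <- trajs[[j]]
    for (i in seq_len(n_frames(tr))) {
      lig_xyz <- tr$coords[i, lig_idx, , drop = FALSE]
      dim(lig_xyz) <- c(length(lig_idx), 3L)
      for (r in seq_len(n_res)) {
        ai <- res_atoms[[r]]
        res_xyz <- tr$coords[i, ai, , drop = FALSE]
        dim(res_xyz) <- c(length(ai), 3L)
        if (min_distance(res_xyz, lig_xyz) <= cutoff) {
          counts[r, j] <- counts[r, j] + 1L
        }
      }
    }
  }
  lens <- vapply(trajs, n_frames, integer(1))
  total <- sum(lens)
  n_contact <- rowSums(counts)
  first_idx <- vapply(res_atoms, `[`, integer(1), 1L)
  out <- data.frame(
    residue = res_keys,
    chain = top$atoms$chain[first_idx],
    resname = top$atoms$resname[first_idx],
    resno = top$atoms$resno[first_idx],
    frequency = as.numeric(n_contact) / total,
    n_frames = as.integer(n_contact),
    stringsAsFactors = FALSE
  )
  attr(out, "cutoff") <- cutoff
  attr(out, "n_total") <- total
  attr(out, "ligand_expression") <-
    if (is.character(ligand_sel)) ligand_sel else ligand_sel$expression
  attr(out, "per_copy") <- sweep(counts, 2L, lens, "/")
  class(out) <- c("contact_profile", "data.frame")
  out
}

#' Filter and rank a contact profile
#'
#' Keeps residues whose pooled contact frequency exceeds `min_frequency`
#' (strictly), sorted by decreasing frequency; ties broken by ascending
#' residue number. Used e.g. to report only residues contacting the acyl
#' chain in more than half of the frames.
#'
#' @param profile a `contact_profile` from [contact_frequency()].
#' @param min_frequency retain entries with `frequency > min_frequency`.
#' @return the filtered, re-ordered `contact_profile`.
#' @export
rank_contacts <- function(profile, min_frequency = 0.5) {
  stopifnot(inherits(profile, "contact_profile"))
  keep <- profile$frequency > min_frequency
  out <- profile[keep, , drop = FALSE]
  ord <- order(-out$frequency, out$resno)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("cutoff", "n_total", "ligand_expression", "per_copy")) {
    attr(out, a) <- attr(profile, a)
  }
  class(out) <- class(profile)
  out
}

#' Write a contact profile to CSV
#' @param profile a `contact_profile`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contact_csv <- function(profile, path) {
  df <- as.data.frame(profile)
  df$cutoff <- attr(profile, "cutoff")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Bar plot of a contact profile
#' @param x a `contact_profile`.
#' @param top_n plot at most this many residues (highest frequency first).
#' @param ... passed to [graphics::barplot()].
#' @method plot contact_profile
#' @export
plot.contact_profile <- function(x, top_n = 25L, ...) {
  ord <- order(-x$frequency, x$resno)
  d <- x[ord, , drop = FALSE][seq_len(min(top_n, nrow(x))), ]
  graphics::barplot(d$frequency, names.arg = d$residue, las = 2,
                    ylab = "contact frequency", ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey50")
  invisible(x)
}
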