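#' Graft ligands from a resolved homolog complex onto a receptor model
#'
#' The geometric step of building a complex from a predicted apo model and
#' a homolog's experimentally resolved complex: the template complex is
#' superposed onto the receptor over an explicitly supplied matched atom
#' pairing (e.g. shared-pocket C-alpha atoms), the same rigid transform is
#' applied to the template's ligand residues, and receptor plus transferred
#' ligands are merged into one structure. Steric clashes introduced by the
#' transfer are audited with [clash_report()] and must be relieved by
#' restrained minimisation downstream; that step is outside this package.
#'
#' Automatic sequence-based pairing is deliberately not provided: between
#' non-identical sequences the pairing is a modelling decision and must be
#' auditable.
#'
#' @param receptor apo receptor [md_structure].
#' @param template_complex homolog complex [md_structure] containing the
#'   ligand residues.
#' @param ligand_resnames residue names of the ligands to transfer,
#'   e.g. `c("G3P", "COA")`.
#' @param receptor_align selection on `receptor` (expression,
#'   `atom_selection` or indices).
#' @param template_align matched selection on `template_complex`; must be
#'   the same length and atom order as `receptor_align`.
#' @return merged [md_structure] (receptor atoms then ligand atoms), with
#'   attributes `fit_rmsd` (Angstrom, over the alignment pairing) and
#'   `n_ligand_atoms`.
#' @export
graft_ligands <- function(receptor, template_complex, ligand_resnames,
                          receptor_align, template_align) {
  stopifnot(inherits(receptor, "md_structure"),
            inherits(template_complex, "md_structure"))
  r_idx <- resolve_selection(receptor, receptor_align)
  t_idx <- resolve_selection(template_complex, template_align)
  if (length(r_idx) != length(t_idx)) {
    stop("alignment selections must pair atoms 1:1 (receptor ",
         length(r_idx), ", template ", length(t_idx), ")")
  }
  lig_mask <- template_complex$atoms$resname %in% ligand_resnames
  if (!any(lig_mask)) {
    stop("template complex contains no residue named ",
         paste(ligand_resnames, collapse = "/"))
  }
  tfm <- kabsch_fit(template_complex$xyz[t_idx, , drop = FALSE],
                    receptor$xyz[r_idx, , drop = FALSE])
  lig_atoms <- template_complex$atoms[lig_mask, , drop = FALSE]
  lig_xyz <- apply_transform(tfm, template_complex$xyz[lig_mask, , drop = FALSE])
  merged <- md_structure(rbind(receptor$atoms, lig_atoms),
                         rbind(receptor$xyz, lig_xyz), box = receptor$box)
  attr(merged, "fit_rmsd") <- tfm$rmsd
  attr(merged, "n_ligand_atoms") <- sum(lig_mask)
  merged
}

#' Steric clash audit of a protein-ligand complex
#'
#' Lists every protein-heavy / ligand-heavy atom pair closer than
#' `threshold` (strict), ascending by distance — the contacts a restrained
#' energy minimisation has to relieve after ligand transfer.
#'
#' @param complex an [md_structure] containing the ligand residues.
#' @param ligand_resnames residue names treated as ligand.
#' @param threshold clash distance in Angstrom (default 2.0 heavy-atom
#'   separation; configurable).
#' @return a `clash_report` data.frame with `protein_atom`, `ligand_atom`
#'   (chain:resname+resno:name keys), `distance`; attributes `threshold`
#'   and `count`.
#' @export
clash_report <- function(complex, ligand_resnames, threshold = 2.0) {
  stopifnot(inherits(complex, "md_structure"))
  a <- complex$atoms
  lig <- which(a$resname %in% ligand_resnames & a$elem != "H")
  if (length(lig) == 0L) {
    stop("complex contains no heavy atoms in residue(s) ",
         paste(ligand_resnames, collapse = "/"))
  }
  prot <- which(!(a$resname %in% ligand_resnames) & a$elem != "H")
  key <- function(i) paste0(a$chain[i], ":", a$resname[i], a$resno[i], ":",
                            a$name[i])
  hit <- matrix(integer(0), 0L, 2L)
  if (length(prot) > 0L) {
    d <- sqrt(cross_dist2(complex$xyz[prot, , drop = FALSE],
                          complex$xyz[lig, , drop = FALSE]))
    hit <- which(d < threshold, arr.ind = TRUE)
  }
  if (nrow(hit) == 0L) {
    pairs <- data.frame(protein_atom = character(0),
                        ligand_atom = character(0), distance = numeric(0))
  } else {
    pairs <- data.frame(
      protein_atom = key(prot[hit[, 1]]),
      ligand_atom = key(lig[hit[, 2]]),
      distance = d[hit],
      stringsAsFactors = FALSE
    )
    pairs <- pairs[order(pairs$distance), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  attr(pairs, "threshold") <- threshold
  attr(pairs, "count") <- nrow(pairs)
  class(pairs) <- c("clash_report", "data.frame")
  pairs
}
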