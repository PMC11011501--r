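#' Pipeline run configuration
#'
#' Collects the inputs, selections, cutoffs and output location shared by
#' the pipeline subcommands. The default parameter profile is the one the
#' analyses are built around: contact cutoff 3 Angstrom, pose-cluster
#' cutoff 3 Angstrom, 1000 represented frames per copy, the shipped
#' six-mode profile, clash threshold 2 Angstrom.
#'
#' @param topology path to a structure file (PDB/GRO).
#' @param trajectories character vector of trajectory paths.
#' @param ligand ligand selection expression.
#' @param ligand_p ligand phosphorus selection expression.
#' @param align receptor alignment selection expression.
#' @param contact_cutoff,cluster_cutoff,clash_threshold cutoffs, Angstrom.
#' @param mode_profile path to a mode-definition YAML, or `NULL` for the
#'   shipped default profile.
#' @param represent_n represented frames per source copy.
#' @param out_dir output directory.
#' @param seed RNG seed for the stochastic subcommands.
#' @param ... further named entries kept verbatim (e.g. subcommand inputs).
#' @return a validated `run_config` list.
#' @export
run_config <- function(topology = NULL, trajectories = character(0),
                       ligand = "resname G3P",
                       ligand_p = "resname G3P and name P",
                       align = "name CA",
                       contact_cutoff = 3.0, cluster_cutoff = 3.0,
                       clash_threshold = 2.0, mode_profile = NULL,
                       represent_n = 1000L, out_dir = ".", seed = 1L, ...) {
  cfg <- list(topology = topology, trajectories = trajectories,
              ligand = ligand, ligand_p = ligand_p, align = align,
              contact_cutoff = contact_cutoff,
              cluster_cutoff = cluster_cutoff,
              clash_threshold = clash_threshold,
              mode_profile = mode_profile,
              represent_n = as.integer(represent_n),
              out_dir = out_dir, seed = as.integer(seed), ...)
  for (f in c("contact_cutoff", "cluster_cutoff", "clash_threshold")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) stop(f, " must be positive")
  }
  if (cfg$represent_n <= 0L) stop("represent_n must be positive")
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#' @param path YAML file.
#' @return for `read_run_config`, a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @param cfg a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

load_config_inputs <- function(cfg) {
  if (is.null(cfg$topology)) stop("config lacks a topology file")
  top <- read_structure(cfg$topology)
  if (length(cfg$trajectories) == 0L) stop("config lists no trajectories")
  trajs <- lapply(cfg$trajectories, function(p) read_trajectory(top, p))
  list(topology = top, trajs = trajs)
}

config_mode_defs <- function(cfg) {
  if (is.null(cfg$mode_profile)) default_mode_definitions()
  else read_mode_definitions(cfg$mode_profile)
}

write_manifest <- function(cfg, name, outputs) {
  inputs <- c(cfg$topology, cfg$trajectories, cfg$mode_profile)
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  inputs <- unlist(inputs)
  manifest <- list(
    subcommand = name,
    package_version = as.character(utils::packageVersion("bindmodes")),
    parameters = unclass(cfg)[c("ligand", "ligand_p", "align",
                                "contact_cutoff", "cluster_cutoff",
                                "clash_threshold", "represent_n", "seed")],
    inputs = if (length(inputs)) {
      data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)))
    } else data.frame(path = character(0), md5 = character(0)),
    outputs = outputs
  )
  path <- file.path(cfg$out_dir, paste0("manifest_", name, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  path
}

#' Run one pipeline stage
#'
#' Dispatches the named analysis stage on a validated configuration and
#' writes its artifacts plus a machine-readable run manifest (inputs with
#' hashes, parameters, package version) into `cfg$out_dir`. Stages:
#'
#' * `contacts` — pooled contact-frequency CSV (plus per-copy CSV)
#' * `cluster` — pose clustering: cluster table CSV + centroid PDBs
#' * `modes` — distance table, per-frame labels, occupancy and transition
#'   CSVs
#' * `timeline` — represented (n-per-copy) label CSV and timeline PDF
#' * `graft` — ligand transfer onto a receptor: merged PDB + clash CSV
#' * `simulate` — synthetic multi-copy study written as multi-model PDBs
#'   with a ground-truth CSV
#' * `motif` — motif matches across a FASTA file, CSV
#'
#' @param name stage name.
#' @param cfg a `run_config`; stage-specific entries (e.g. `receptor`,
#'   `template`, `fasta`, `pattern`, `n_copies`, `frames_per_copy`) ride
#'   along as extra config fields.
#' @return named list of written artifact paths, invisibly.
#' @export
run_subcommand <- function(name = c("contacts", "cluster", "modes",
                                    "timeline", "graft", "simulate",
                                    "motif"),
                           cfg) {
  name <- match.arg(name)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- switch(name,
    contacts = {
      io <- load_config_inputs(cfg)
      prof <- contact_frequency(io$trajs, cfg$ligand,
                                cutoff = cfg$contact_cutoff)
      p1 <- file.path(cfg$out_dir, "contact_frequency.csv")
      write_contact_csv(prof, p1)
      p2 <- file.path(cfg$out_dir, "contact_frequency_per_copy.csv")
      utils::write.csv(data.frame(residue = prof$residue,
                                  attr(prof, "per_copy")), p2,
                       row.names = FALSE)
      list(pooled = p1, per_copy = p2)
    },
    cluster = {
      io <- load_config_inputs(cfg)
      dm <- ligand_rmsd_matrix(io$trajs, cfg$align, cfg$ligand)
      cl <- gromos_cluster(dm, cutoff = cfg$cluster_cutoff)
      p1 <- file.path(cfg$out_dir, "clusters.csv")
      utils::write.csv(cluster_table(cl, dm), p1, row.names = FALSE)
      paths <- list(table = p1)
      for (k in seq_len(min(6L, length(cl$clusters)))) {
        pk <- file.path(cfg$out_dir, sprintf("centroid_%02d.pdb", k))
        write_structure(centroid_structure(io$trajs, cl, k, dm), pk)
        paths[[paste0("centroid_", k)]] <- pk
      }
      paths
    },
    modes = {
      io <- load_config_inputs(cfg)
      defs <- config_mode_defs(cfg)
      tab <- compute_distance_table(io$trajs, defs,
                                    ligand_p_sel = cfg$ligand_p)
      trace <- assign_modes(tab, defs)
      p1 <- file.path(cfg$out_dir, "mode_labels.csv")
      utils::write.csv(data.frame(frame = seq_along(trace$labels),
                                  mode = trace$labels), p1,
                       row.names = FALSE)
      p2 <- file.path(cfg$out_dir, "mode_occupancy.csv")
      occ <- mode_occupancy(trace)
      utils::write.csv(data.frame(mode = names(occ), occupancy_pct = occ),
                       p2, row.names = FALSE)
      p3 <- file.path(cfg$out_dir, "mode_transitions.csv")
      utils::write.csv(as.data.frame(transition_summary(trace)$matrix), p3)
      list(labels = p1, occupancy = p2, transitions = p3)
    },
    timeline = {
      io <- load_config_inputs(cfg)
      defs <- config_mode_defs(cfg)
      tab <- compute_distance_table(io$trajs, defs,
                                    ligand_p_sel = cfg$ligand_p)
      trace <- represent_frames(assign_modes(tab, defs),
                                n = cfg$represent_n)
      p1 <- file.path(cfg$out_dir, "timeline_labels.csv")
      utils::write.csv(data.frame(frame = seq_along(trace$labels),
                                  mode = trace$labels), p1,
                       row.names = FALSE)
      p2 <- file.path(cfg$out_dir, "timeline.pdf")
      grDevices::pdf(p2, width = 9, height = 3.2)
      plot_mode_timeline(trace)
      grDevices::dev.off()
      list(labels = p1, plot = p2)
    },
    graft = {
      receptor <- read_structure(cfg$receptor)
      template <- read_structure(cfg$template)
      merged <- graft_ligands(receptor, template, cfg$ligand_resnames,
                              cfg$receptor_align, cfg$template_align)
      p1 <- file.path(cfg$out_dir, "complex.pdb")
      write_structure(merged, p1)
      clashes <- clash_report(merged, cfg$ligand_resnames,
                              threshold = cfg$clash_threshold)
      p2 <- file.path(cfg$out_dir, "clashes.csv")
      utils::write.csv(as.data.frame(clashes), p2, row.names = FALSE)
      message("graft fit RMSD: ",
              format(attr(merged, "fit_rmsd"), digits = 4), " A; ",
              attr(clashes, "count"), " clash pair(s) < ",
              cfg$clash_threshold, " A")
      list(complex = p1, clashes = p2)
    },
    simulate = {
      spec <- synthetic_spec(jitter_sigma = cfg$jitter_sigma %||% 0.5,
                             seed = cfg$seed)
      study <- simulate_hotspot_study(
        spec,
        n_copies = cfg$n_copies %||% 8L,
        frames_per_copy = cfg$frames_per_copy %||% 1000L,
        seed = cfg$seed)
      paths <- list()
      for (i in seq_along(study$trajectories)) {
        pi_ <- file.path(cfg$out_dir, sprintf("synthetic_copy%d.pdb", i))
        write_trajectory(study$trajectories[[i]], pi_)
        paths[[paste0("copy", i)]] <- pi_
      }
      pt <- file.path(cfg$out_dir, "ground_truth.csv")
      utils::write.csv(study$truth, pt, row.names = FALSE)
      paths$truth <- pt
      paths
    },
    motif = {
      recs <- read_fasta(cfg$fasta)
      hits <- motif_table(recs, cfg$pattern)
      p1 <- file.path(cfg$out_dir, "motif_hits.csv")
      utils::write.csv(hits, p1, row.names = FALSE)
      list(hits = p1)
    }
  )
  write_manifest(cfg, name, outputs)
  invisible(outputs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
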