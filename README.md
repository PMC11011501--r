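# bindmodes

Binding-mode and pose analysis of protein–ligand molecular dynamics
trajectories, written for studies of substrate recognition in
glycerol-3-phosphate acyltransferases (GPATs) and applicable to any
receptor whose ligand is anchored by a small set of charged residues.

GPAT4 recognises glycerol-3-phosphate (G3P) through a salt bridge with
R427, but that arginine sits on a highly flexible region, so the
substrate's phosphate hops between several positively charged *hotspots*
rather than staying in one pose. Characterising that behaviour from MD
trajectories takes four analyses, all implemented here:

* **Contact frequencies** — fraction of frames in which a residue has any
  heavy atom within 3 Å of the ligand, pooled over trajectory copies
  (`contact_frequency()`, `rank_contacts()`).
* **Pose clustering** — Gromos/Daura greedy neighbour-count clustering of
  ligand poses at a 3 Å RMSD cutoff, computed in the receptor-aligned
  frame without refitting the ligand (`ligand_rmsd_matrix()`,
  `gromos_cluster()`, `cluster_sizes()`, `centroid_structure()`).
* **Binding modes** — each frame is labelled by the highest-precedence
  mode whose distance conditions all hold, where a condition bounds the
  distance from the G3P phosphorus to an anchor atom (NZ for Lys, CZ for
  Arg, NE2 for His; cutoffs 5 Å, with 11 Å for the catalytic histidine).
  The shipped six-mode GPAT4 profile lives in
  `inst/extdata/gpat4_g3p_modes.yaml`; occupancies, 1000-frame
  per-copy representation, transition counts and a timeline plot follow
  (`assign_modes()`, `mode_occupancy()`, `represent_frames()`,
  `transition_summary()`, `plot_mode_timeline()`).
* **Complex grafting** — rigid (Kabsch) transfer of ligands from a
  resolved homolog complex onto a predicted apo model over an explicit
  matched atom pairing, with a heavy-atom steric-clash audit
  (`graft_ligands()`, `clash_report()`).

Because the underlying MD trajectories of such studies are rarely
deposited, the package ships a fully seeded synthetic generator
(`synthetic_spec()`, `simulate_mode_walk()`, `emit_trajectory()`,
`make_pose_blobs()`) that emulates hotspot hopping with known ground
truth; every analysis stage is validated against it. Structure I/O covers
PDB and GRO; trajectories load from DCD or multi-model PDB (convert XTC
upstream, e.g. `gmx trjconv -o out.dcd`). Minimal FASTA/motif utilities
(`read_fasta()`, `find_motif()`) support sequence-level checks such as
locating the catalytic HXXXXD motif.

## Worked example

```r
library(bindmodes)

spec <- synthetic_spec()   # default hotspot geometry, sigma = 0.5 A jitter
study <- simulate_hotspot_study(spec, n_copies = 8,
                                frames_per_copy = 2000, seed = 1)

tab   <- compute_distance_table(study$trajectories)
trace <- assign_modes(tab)
round(mode_occupancy(trace), 1)
#>    1    2    3    4    5    6
#> 28.9 15.6  9.4  9.3 19.3 17.6
```

The six numbers are the percentage of the 16,000 pooled frames assigned
to each binding mode (mode 1 = catalytic site via R427 + H248, modes 2–5
= peripheral hotspots, mode 6 = unbound/other); they sum to 100 and here
track the generator's stationary profile. Transitions between hotspots
and the residues holding the ligand follow the same objects:

```r
sum(transition_summary(trace)$matrix)   # hotspot hops, boundaries excluded
#> [1] 127
prof <- contact_frequency(study$trajectories, "resname G3P")
rank_contacts(prof, 0.5)[, c("residue", "frequency")]
#>    residue frequency
#> 1 A:ARG427  0.571625
```

R427 is the only residue in contact with G3P in more than half of the
frames — the generator reproduces the signature of an R427-led
recognition. On noise-free data (`synthetic_spec(jitter_sigma = 0)`) the
recovered labels match the generator's ground truth exactly
(`mean(trace$labels == study$truth$true_mode)` is 1).

A thin command-line wrapper over the same functions is installed at
`system.file("scripts", "bindmodes-cli.R", package = "bindmodes")` with
subcommands `contacts`, `cluster`, `modes`, `timeline`, `graft`,
`simulate` and `motif`; every run writes a JSON manifest of inputs,
parameters and hashes next to its artifacts.

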