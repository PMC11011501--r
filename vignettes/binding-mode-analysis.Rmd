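---
title: "Characterising substrate binding modes from MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising substrate binding modes from MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindmodes)
```

## The problem

Membrane-bound glycerol-3-phosphate acyltransferases (GPATs) catalyse the
first step of triacylglycerol synthesis: transfer of an acyl group from
palmitoyl-CoA to glycerol-3-phosphate (G3P). For isoforms without a
resolved structure, complexes are built from a predicted apo model plus
ligands transferred from a resolved homolog, and molecular dynamics (MD)
then probes how the substrate is recognised. The analyses this package
implements answer three questions about such trajectories:

1. *Which residues hold the ligand?* — per-residue contact frequencies at
   a heavy-atom proximity criterion.
2. *What are the dominant poses?* — Gromos (Daura) clustering of ligand
   poses in the receptor-aligned frame.
3. *How does the ligand move between charged hotspots?* — binding-mode
   assignment from phosphorus-to-anchor distances, with occupancies and a
   transition timeline.

A fourth component, the grafting step, performs the geometric part of the
complex construction itself; a fifth generates synthetic trajectories with
known ground truth.

## Contact frequencies

A residue is *in contact* in a frame when the minimum distance between any
of its heavy atoms and any ligand heavy atom is at most the cutoff
(default 3 Å, boundary inclusive). Frequencies are pooled over all
trajectory copies — multi-copy campaigns are combined for analysis — and a
per-copy breakdown is attached for inspection. Hydrogens are excluded on
both sides because crystallographic inputs lack them; including them only
when present would bias comparisons across systems. Whether the original
statistic used atom–atom or residue-centre distances is not specified by
its source; the minimum heavy-atom pair distance is the natural reading of
"within 3 Å" and is what we compute.

## Pose clustering

Each frame is first superposed onto a reference (frame 1 of the first
copy, or a user-supplied structure) by a least-squares Kabsch fit over a
receptor selection; ligand RMSD is then computed pairwise *without*
refitting, so translation of the ligand relative to the pocket counts.
The Gromos algorithm greedily picks the frame with the most neighbours
within the cutoff (3 Å default) as a centroid, removes it with its
neighbours, and repeats. Two conventions are ours: neighbour-count ties
break to the lowest frame index (determinism), and the RMSD is unweighted
(no mass weighting). When two ligands are analysed jointly their heavy
atoms concatenate into one coordinate vector; per-ligand clustering is a
selection away.

## Binding modes

Charged residues form hotspots that trap the ligand's phosphate group, and
steady phosphorus-to-side-chain distances separate the resulting
interaction patterns. A mode is a conjunction of distance conditions
(distance from the G3P phosphorus to NZ of lysines, CZ of arginines, NE2
of histidines, each ≤ a cutoff). The shipped six-mode GPAT4 profile uses
5 Å cutoffs except the catalytic-histidine condition of mode 1 (11 Å):
when G3P sits in the catalytic site its phosphorus keeps a steady ~10 Å
separation from H248, and that distance alone separates the
catalytic-site mode from the hotspot modes.

Three decisions here were genuinely open and are ours:

* **Histidine atom.** "NE" is not a standard histidine atom name; we map
  it to NE2 by default with ND1 selectable.
* **Precedence 1 > 2 > 4 > 5 > 3 > 6.** Mode 1 is separated first by the
  histidine distance; modes 2, 4 and 5 are anchored by residue pairs
  unique to them, so their order barely matters (the hotspots are far
  apart); mode 3 is a remainder class for frames still holding onto R427
  and K426 during transitions; mode 6 is the fallback. The profile is
  data (YAML), so any other convention is one edit away.
* **Boundary inclusive** (`distance <= cutoff`), consistent with defining
  conditions by distances staying *below* the cutoff.

Occupancies are reported over all declared modes (zero counts included)
and always sum to 100%. For timelines, each copy is represented by 1000
uniform-stride frames (first frame kept) and concatenated; label changes
across copy boundaries are concatenation artefacts and are excluded from
transition counts while remaining visible as boundary ticks.

## Complex grafting

`graft_ligands()` superposes a resolved homolog complex onto a predicted
receptor model over an explicitly supplied matched atom pairing and
transfers the ligand coordinates with the fitted rigid transform.
Automatic sequence-based pairing is deliberately excluded: between
non-identical sequences the pairing is a modelling decision that must be
auditable. The transfer inevitably leaves steric clashes;
`clash_report()` lists protein–ligand heavy-atom pairs closer than 2 Å
(our default — the original protocol names clashing residues but no
numeric criterion) for a downstream restrained minimisation, which is out
of scope here, as is any remodelling of the reactants. Reading and
writing use PDB/GRO for structures and DCD/multi-model PDB for
trajectories; XTC input must be converted upstream.

## The synthetic generator — and what it does not show

`synthetic_spec()` fixes the study conditions: eight anchor residues at a
fixed geometry, one target point per mode placed so that it satisfies its
own mode's conditions and violates at least one condition of every
higher-precedence mode with ≥ 2 Å margin (validated at construction; the
spec is rejected otherwise), a sticky Markov chain
`P = 0.99 I + 0.01 1 πᵀ` whose stationary distribution π is the six-mode
occupancy profile of the reference system (32.3, 17.8, 9.1, 8.9, 13.2,
18.7%), isotropic Gaussian jitter of σ = 0.5 Å on the rigid ten-atom
ligand, and 10,000 frames per copy. These defaults were chosen once as
the conditions the analyses target and are not tuned.

With 2 Å margins and σ = 0.5 Å, a misassigned frame requires a ≥ 4σ
Gaussian excursion, so label recovery is essentially exact; the generator
warns with a tail bound when σ grows large relative to the margins.
Filler residues placed 2 Å from specific hotspots give contact
probabilities that are known functions of the label sequence
(`designed_contacts`), which the contact module must recover within
binomial error.

What passing these tests shows: the distance computations, state
machinery, clustering and bookkeeping are correct on data with exactly
the assumed structure. What they cannot show: anything about force
fields, sampling convergence, protein flexibility (the receptor is rigid
here), ligand internal motion, or whether a 3 Å/5 Å/11 Å criterion is
chemically appropriate for a particular system — those judgements stay
with the user.

## Numerical choices and problem sizes

Kabsch uses SVD with a reflection guard (det = +1 enforced) and uniform
weights; collinear point sets are rejected. The pairwise RMSD matrix is
computed via the Gram-matrix identity with negative round-off clamped to
zero and symmetry enforced; it is O(T²) in memory, so represent long
trajectories first (the package's own checks use 10,000-frame traces for
label statistics and ≤ 1000-frame sets for full matrices, which keeps the
whole suite under a minute). Markov-chain occupancy checks against the
stationary π use an i.i.d. row matrix, where the binomial standard error
is the right scale; under the sticky default chain, autocorrelation
inflates the variance, and the honest comparison is recovered-versus-
realised labels.

## Worked example

```{r example, eval = FALSE}
library(bindmodes)

spec <- synthetic_spec()                      # sigma = 0.5 A, default chain
study <- simulate_hotspot_study(spec, n_copies = 8,
                                frames_per_copy = 2000, seed = 1)

tab <- compute_distance_table(study$trajectories)
trace <- assign_modes(tab)
mode_occupancy(trace)
transition_summary(trace)$matrix
plot_mode_timeline(represent_frames(trace, 1000))

prof <- contact_frequency(study$trajectories, "resname G3P")
rank_contacts(prof, 0.5)
```

## Limitations

Trajectory input is limited to DCD and multi-model PDB (no XTC reader);
the clustering stores a dense T × T matrix; the selection grammar covers
names, residues, chains, elements and boolean algebra but not distance-
based selections; and mode assignment presumes a single ligand phosphorus
per system.
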