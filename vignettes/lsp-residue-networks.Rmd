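---
title: "LSP alignment residue networks: model, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LSP alignment residue networks: model, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A conformational ensemble — frames of one protein domain — is reduced to
per-residue Cα and Cβ coordinates. Within one frame, residues *i,j* form
a candidate link when d(Cαᵢ, Cαⱼ) < 12 Å (strict; sequence neighbours are
not excluded). The link's geometry is captured by four internal
coordinates of the Cα–Cβ vector pair: three distances (Cα₁–Cα₂, Cα₁–Cβ₂,
Cα₂–Cβ₁) and the signed dihedral θ(Cβ₁–Cα₁–Cα₂–Cβ₂), IUPAC convention,
in (−180°, 180°].

Two frames are aligned by retaining every link, present in the contact
graphs of **both** frames, whose descriptors agree within strict
tolerances: 0.2 Å on the Cα–Cα distance, 0.45 Å on each cross distance,
10° on the dihedral. The dihedral difference is circular,
min(|Δθ|, 360 − |Δθ|), so +179° vs −179° counts as 2°. Because all four
numbers are internal coordinates the procedure needs no superposition:
per-frame rigid motion of any magnitude is provably (and, in the test
suite, bit-for-bit) irrelevant. Under reflection the distances survive
but θ flips sign — improper transforms are *not* silently tolerated.

Over a window of *n* frames all C(n, 2) frame pairs are aligned (4950
for the canonical 100-frame window) and the binary adjacencies averaged:

> W(i, j) = (# frame pairs retaining the link) / C(n, 2).

"Averaged and normalized" is read here as division by the number of
frame pairs — the only reading under which W is a retention probability
in (0, 1] and D = −log W a nonnegative length. Links never retained are
absent (disconnected), not zero-weight edges.

## Centralities

* **DC** — weighted degree (node strength), unnormalised. Only relative
  comparisons are meaningful downstream (scatter plots, percent
  differences), so the absolute scale is a free convention.
* **BC** — shortest-path betweenness on distances D = −ln W,
  unnormalised, fractional split over co-minimal paths. The log base
  only rescales all distances uniformly and cannot change shortest
  paths; the invariance that actually holds (and is asserted as a
  property test) is under the *power* transform W → W^c, which scales
  every D by c. Multiplying W by a constant is **not** BC-invariant —
  it adds a constant per edge and so penalises longer hop chains.

**Ties and zero-length edges.** A fully conserved link (W = 1) has
D = 0, and rigid cores produce whole cliques of them. Counting *all*
minimal-distance simple paths there explodes combinatorially (any
wandering through the zero-distance clique is "minimal"), and graph
libraries disagree on the convention — igraph refuses zero weights
outright. `lspprn` counts minimal-distance paths **of minimal hop
count**, computed by a lexicographic (distance, hops) Dijkstra/Brandes
pass with index-ascending tie-breaks. The convention is symmetric in the
endpoints, deterministic, and identical to plain shortest-path counting
whenever distances are generic (no exact ties) — which is also why it
agrees exactly with the exhaustive path-enumeration oracle on random
continuous-weight graphs in the test suite.

Window profiles report per-residue mean and SE = sd/√m over the m
windows (sample SD; m = 15 in the reference design of 3 trajectories ×
5 windows of 100 frames). A single window yields SE = NA rather than an
error, since one-window exploratory runs are common. Mutant constructs
are compared residue-wise as 100 × (mut − ref)/ref of the mean DC (or
BC); residues with reference mean 0 are reported as undefined, never
dropped.

**Hubs.** Rigid communities are delineated by greedy agglomerative
modularity maximisation on W with fixed lowest-index tie-breaking, then
ranked by mean DC. The choice of community method is an explicit,
replaceable convention — the underlying analysis only needs *some*
deterministic partition to colour hub membership.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `contact_cutoff` | 12 | Å | Cα–Cα link threshold per frame |
| `tol_caca` | 0.2 | Å | match tolerance, Cα–Cα distance |
| `tol_cross` | 0.45 | Å | match tolerance, both cross distances |
| `tol_theta` | 10 | deg | match tolerance, circular dihedral |
| `frames_per_window` | 100 | frames | all-to-all alignment block |
| `bond_length` (virtual Cβ) | 1.521 | Å | ideal Cα–Cβ bond |

All cutoff comparisons are strict (`<`), matching how they are printed,
so boundary values are reproducible rather than platform-dependent.

**Glycine.** The descriptor needs a Cβ on every node; glycine has none.
Default: a virtual Cβ from backbone N/Cα/C by ideal tetrahedral
geometry on the L-amino-acid side of the backbone plane (validated
against ideal side-chain geometry to < 0.1 Å; the construction is exact
in bond length and commutes with rigid motion). `glycine = "drop"`
removes glycine nodes instead, for sensitivity analysis. Missing Cβ on
any *other* residue is a hard error — never silent imputation.

## The synthetic ensemble generator

`ensemble_spec()` describes a stated world, not a tuning dial: a
50-residue two-lobed domain (two antiparallel helical lobes ~10.5 Å
apart, joined by a surface loop that protrudes from the core), with

* two rigid blocks (residues 1–20, 31–50) — shared small per-frame
  rigid perturbation (rotation SD 1.5°, translation SD 0.3 Å) plus
  per-residue jitter SD 0.15 Å, emulating internally stable,
  Zn²⁺-organised clusters;
* a flexible loop (21–30) with independent per-residue jitter SD 1.2 Å,
  a typical surface-loop RMSF scale;
* optional coupling (`apply_coupling()`) that makes loop residues move
  with the second block — the stiffened-loop analogue of a mutation
  that docks a loop onto the core; `remove_coupling()` is its exact
  inverse (the rescue analogue);
* optional per-frame global rigid motion (uniform rotations,
  translations in ±15 Å), which the LSP pipeline must — and does —
  ignore exactly.

Jitter translates a residue's Cα and Cβ together, so bond geometry
survives while *relative* orientations between residues genuinely
degrade; jitter is applied before global motion. Identical spec + seed
reproduces the ensemble bit for bit.

What the generator does **not** emulate: force-field energetics,
solvent, Zn²⁺ coordination chemistry, anharmonic transitions, or
realistic backbone dihedral statistics. A green test therefore
establishes that the pipeline *recovers planted rigidity structure from
coordinates*, not that it reproduces any particular MD observable.
Published centrality values from real trajectories depend on the MD
protocol and on centrality normalisation conventions and are out of
reach of desk-scale synthetic data; the package's checks are therefore
combinatorial constants (frame-pair counts, window counts), exact
oracle equivalences, invariance properties, and sign/ordering recovery
of planted effects — with effect-size bounds frozen from a pilot run,
not tuned to outcomes.

## Numerical and design choices

* **Candidate edges per frame pair** = intersection of the two contact
  graphs (a link must exist in both frames for its orientation to be
  comparable).
* **Windows never span trajectories**; trailing frames that cannot fill
  a window are dropped with a warning.
* **Determinism everywhere**: pair enumeration order is fixed;
  tie-breaks are lexicographic by residue index; pipeline seeds for
  simulated constructs derive from the master seed and the construct
  *label* (never its position, so reordering a config cannot change
  numbers); reruns are byte-identical.
* **Degenerate geometry** (collinear backbone for a virtual Cβ, Cβ on
  the Cα–Cα axis for a dihedral, coincident Cα) raises an error naming
  the residue.
* Residue identity is the 1-based chain ordinal; display labels (e.g.
  an isoform numbering convention) are a pure relabelling that cannot
  affect any computation.
* Networks are exported with the full roster (isolated residues stay
  nodes), W and D on edges, and DC/BC/community on nodes, so Gephi-style
  maps with node diameter ∝ DC can be drawn directly.

## Known limitations

* Absolute DC/BC values depend on normalisation conventions that differ
  between graph libraries; only within-run relative structure (and
  percent differences) should be interpreted.
* Path multiplicity among exactly tied distances is convention-bound
  (see above); BC differences *inside* a fully conserved clique are not
  meaningful under any convention.
* The PDB reader is minimal by design (ATOM/MODEL records, one chain at
  a time); mmCIF and binary trajectory formats are out of scope — frames
  arrive as multi-model PDB or as in-memory tables.
* With a single window, SEs are undefined (NA) and hub/communicator
  calls rest on one network realisation.
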