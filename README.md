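# lspprn — local spatial pattern alignment residue networks

`lspprn` turns a conformational ensemble of a protein domain (MD frames,
NMR models, or simulated stand-ins) into weighted **protein residue
networks** and centrality profiles, using **local spatial pattern (LSP)
alignment** — a superposition-free comparison of structures. It is aimed
at structural bioinformaticians who want to locate rigid "hub" clusters
(e.g. the two Zn²⁺-organised communities of a PKC C1 domain), the
"communicator" residues that bridge them, and the way point mutations
rewire those networks.

## The method

For one structure, residues *i*, *j* are linked when their Cα atoms lie
closer than 12 Å. Each link is described by four internal coordinates of
the two Cα–Cβ vectors:

> d(Cα₁,Cα₂), d(Cα₁,Cβ₂), d(Cα₂,Cβ₁), and the dihedral
> θ = ∠(Cβ₁–Cα₁–Cα₂–Cβ₂)

Two frames are *LSP-aligned* by keeping every link whose descriptors
agree within Δd(CαCα) < 0.2 Å, Δd(cross) < 0.45 Å, Δθ < 10° (circular).
Because all four numbers are internal, arbitrary rigid body motion of
either frame changes nothing — no superposition step exists to bias the
comparison.

Within a time window of *n* frames (100 frames ≙ 10 ns at a 0.1 ns
stride), all C(n,2) frame pairs are aligned — 4950 binary adjacency
matrices for n = 100 — and averaged: the edge weight

> W(i,j) = (# frame pairs retaining the link) / C(n,2) ∈ (0, 1]

is the link's conservation probability. Per window the package computes

* **Degree centrality** DC(v) = Σᵤ W(u,v) — high for residues in locally
  rigid surroundings;
* **Betweenness centrality** on distances **D = −log W** — high for
  residues carrying shortest paths between stable communities.

Across windows (15 in the reference design: 3 trajectories × 5 windows)
profiles are reported as mean ± SE, and mutants are compared to a
reference construct as 100 × (mut − ref)/ref per residue. Glycine
receives a virtual Cβ from ideal tetrahedral backbone geometry.

## Worked example

A synthetic 50-residue, two-lobed domain stands in for a C1-like domain:
two rigid blocks (residues 1–20 and 31–50), a flexible surface loop
(21–30), optional per-frame global tumbling. Coupling the loop into the
second block emulates a stiffening mutation:

```r
library(lspprn)

wt_spec  <- ensemble_spec(n_frames = 100, seed = 1)               # "WT"
mut_spec <- apply_coupling(wt_spec, construct = "R42P-like")      # stiffened loop

wt  <- generate_ensemble(wt_spec)
mut <- generate_ensemble(mut_spec)

wt_prof  <- aggregate_windows(ensemble_networks(wt,  frames_per_window = 50))
mut_prof <- aggregate_windows(ensemble_networks(mut, frames_per_window = 50))
wt_prof
#> <lsp_profile> construct 'WT': 50 residues over 2 windows
#> # A tibble: 50 × 7
#>   residue_index residue_label dc_mean  dc_se bc_mean bc_se n_windows
#> 1             1 A1               3.6  0.0498     0     0           2
#> 2             2 A2               3.95 0.144      0     0           2
#> 3             3 A3               5.42 0.166      5.5   4.5         2
#> ...

cmp <- percent_difference(mut_prof, wt_prof, metric = "dc")
dplyr::arrange(dplyr::as_tibble(cmp), dplyr::desc(pct_diff))
#> # A tibble: 50 × 6
#>   residue_index residue_label reference_mean mutant_mean pct_diff undefined
#> 1            24 A24                   0.0988        3.05    2985. FALSE
#> 2            26 A26                   0.103         3.12    2925. FALSE
#> 3            27 A27                   0.102         3.08    2904. FALSE
#> ...
```

Every top DC gainer is a loop residue (median loop gain ≈ +1720 %): the
planted stiffening is read off the network, exactly the signature used
to reason about loop-stabilising mutations. `autoplot(wt_prof)` draws
the DC–BC scatter with SE bars; `autoplot(cmp)` the per-residue percent
difference profile; `detect_hubs()` partitions a network into rigid
communities; `write_network()` exports GraphML/GEXF for Gephi, with
`dc_mean` as the node-size attribute.

The full design — several constructs, windows, comparisons, TSV/GraphML
outputs and a provenance manifest — runs through one call:

```r
res <- run_lsp_pipeline(demo_run_config(n_frames = 200, seed = 1))
```

Real trajectories enter as multi-model PDB files via
`read_pdb_ensemble()` (chain/model selection, striding, virtual Cβ for
glycine), or through a YAML configuration (`read_run_config()`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the demonstration pipeline from scratch against the installed
package — four simulated constructs, windowed all-to-all LSP alignment,
centrality aggregation and mutant comparisons — logs one summary line
per construct, and writes the JSON result file.
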