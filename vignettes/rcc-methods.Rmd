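---
title: "Residue cluster classes: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue cluster classes: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcc3d)
```

## The representation

A protein's 3D structure induces a *residue contact graph*: vertices are the
residues (in observed polymer order, indexed 0, 1, 2, ... per chain) and an
edge joins two residues whenever some pair of their atoms lies within a
distance threshold $d$. A *maximal clique* of this graph is a set of mutually
contacting residues that cannot be extended. Each maximal clique of size 3--6
is assigned a *residue cluster class*: sort the clique's residues by sequence
position, collect the maximal runs of sequence-adjacent residues (consecutive
ordinals within one chain), and record the run lengths as a non-decreasing
integer partition of the clique size. For example, residues $\{45, 46, 101,
102\}$ contain two adjacent pairs, giving class $[2,2]$; four consecutive
residues give $[4]$; three mutually non-adjacent residues give $[1,1,1]$.

There are $3 + 5 + 7 + 11 = 26$ partitions of the integers 3--6, hence 26
classes. Counting a structure's maximal cliques per class yields a
26-dimensional integer vector -- a compact, rigid-motion-invariant structural
fingerprint that has been used to learn both structural (CATH-style) and
functional (GO-style) classifications with standard machine-learning models.
The catalog order is fixed (see `class_catalog()`); note it is a *published
convention*, not a mechanical sort: within size 4 the order is
$[1,1,1,1], [1,1,2], [2,2], [1,3], [4]$, and within size 5, $[1,4]$ precedes
$[1,2,2]$. Export columns are named `c<size>_<parts>`, e.g. `c4_22`.

## Contact definition and its parameters

* **`d` (Angstrom, default 5).** Two residues are in contact when their
  minimum atom-pair distance is `<= d` (inclusive by default; a strict `< d`
  convention is available via `contact_params(inclusive = FALSE)` because the
  boundary convention is not standardized in the field). The batch driver
  sweeps `c(5, 6, 7, 8, 9, 10, 15)` by default, the range over which these
  fingerprints are typically screened; 7--8 Angstrom without side chains is
  the regime reported to classify best.
* **`include_side_chains` (default `TRUE`).** When `FALSE`, both the
  envelopes and the exact distance checks use only backbone atoms. The
  backbone set is N, CA, C, O plus the terminal OXT -- the conventional
  peptide backbone; the choice is ours since no standard enumeration exists,
  and it keeps CA-only traces usable. Hydrogens are excluded everywhere by
  default (`read_pdb(include_hydrogens = TRUE)` to override): most
  depositions lack them, so including them would make graphs
  deposition-dependent.
* **`filter_mode` (default `"sound"`).** Residue pairs are prescreened with
  per-residue bounding spheres (centre = unweighted mean of retained atoms,
  radius = distance to the farthest one). The *sound* rules are exact bounds:
  exclude when $D - r_d - s_d > d$ and include when $D + r_d + s_d \le d$
  (centres $D$ apart, radii $r_d$, $s_d$); pairs settled by neither rule get
  an exact atom-pair scan, so the result always equals the brute-force
  predicate. The literal published quick rules -- include when $D < d$,
  exclude when $\min(D - r_d, D - s_d) > d$ -- are unsound for extended
  residues in both directions; they are retained as `filter_mode = "paper"`
  for comparison studies, and `compare_filter_modes()` surfaces any
  resulting edge/RCC differences rather than resolving them silently.
  Whether the original database used the literal rules or an exact check is
  not determinable from the publication.

A half-volume sphere-overlap inclusion rule that the original implementation
itself disabled (overhead comparable to the time saved) is not implemented.

## Grid hashing

Atoms are hashed into cubic cells of width $d$ (`floor(coord / d)` per
axis); candidate residue pairs are those sharing a cell or occupying
26-neighboring cells. Hashing is per **atom**, not per residue centre: a
residue may span several cells, and point-hashing residues can miss
contacting pairs whose centres sit in non-adjacent cells. Per-atom hashing
guarantees no false negatives for any residue geometry; false positives are
removed by the envelope rules and exact checks. One consequence worth
knowing: under `filter_mode = "paper"`, a pair whose *centres* are closer
than $d$ but whose atoms all lie farther than $d$ apart can be pruned by the
grid before the literal $D < d$ rule would have (wrongly) included it, so
"paper" mode reproduces the literal *filters*, not every artifact of a
centre-hashed pipeline.

## Clique enumeration

Maximal cliques are enumerated by Bron--Kerbosch with Tomita pivoting (pivot
= the vertex of $P \cup X$ with the most neighbours in $P$), with the outer
level iterating over a degeneracy ordering (repeated minimum-degree removal).
This bounds recursion depth by degeneracy + 2, which for contact graphs is
small (interval-like local structure), and makes enumeration on sparse
graphs near-optimal. Tie-breaks are fixed -- minimum-degree and pivot ties go
to the smallest vertex id, cliques are emitted as sorted id vectors and the
list is ordered lexicographically -- so output is byte-deterministic. The
enumerator reports *all* maximal cliques, including singletons and pairs;
the RCC layer filters to sizes 3--6.

Cliques larger than 6 residues are **dropped entirely**, not decomposed:
their sub-cliques are not maximal, and counting them would double-count.
At 5 Angstrom such cliques are rare; at 15 Angstrom they are common, so the
26-vector at large $d$ deliberately ignores a large share of the graph's
clique structure. This is a documented choice of this package; whether the
original database handled oversized cliques the same way is unstated.

## Sequence adjacency

Adjacency is defined on 0-based *observed-order* ordinals within a chain,
so residues flanking an unresolved gap in the crystal are treated as
adjacent (the indexing follows the published convention). Residues in
different chains are never adjacent, even when author numbering happens to
run consecutively across the chain break. Insertion-code residues are
ordered as deposited. Alternate locations resolve to the highest-occupancy
conformer (ties: alphabetically first altloc); multi-model files use the
first model unless another is requested. MSE/SEC/PYL HETATM records are
treated as polymer residues (dropping selenomethionine would create
spurious sequence gaps); waters and other HETATM ligands are excluded.

## What the synthetic generators emulate

* `make_ideal_helix()` places CA atoms on a canonical alpha-helix (rise 1.5
  Angstrom/residue, 100 degrees/residue, radius 2.3 Angstrom), giving the
  dense local contact pattern of all-alpha proteins; constants are textbook
  values, not fitted.
* `make_random_chain()` is a self-avoiding random walk with fixed 3.8
  Angstrom CA-CA steps and a 4.0 Angstrom clash radius -- a generic
  polymer-like point process exercising irregular contact topology.
* Optional schematic backbone atoms and a dummy side-chain pseudo-atom (CB,
  2.4 Angstrom from CA, pointing away from the local backbone) exist so that
  side-chain inclusion/exclusion and backbone stripping measurably change
  the graphs.

These fixtures are *not* physically realistic proteins: no rotamers, no
secondary-structure mixture, no packing optimization, no B-factors, no
missing residues. A green oracle-equivalence suite therefore establishes
that the optimized pipeline computes exactly the defined function of
coordinates on realistic scales and geometries -- it does not validate any
biological claim about real PDB entries.

## Numerical and degenerate-input choices

* All distance comparisons are done on squared distances where possible; the
  inclusive/strict boundary is exposed as a flag, and invariance tests keep
  their points away from exact-threshold distances, where floating-point
  rotation can legitimately flip an edge.
* PDB fixed format carries 3 decimals; `round_coords()` pre-rounds fixtures
  so file round-trips compare exactly.
* Envelope of a single-atom residue: radius 0; a residue reduced to zero
  atoms by filtering is dropped without renumbering ordinals.
* Empty graphs, edgeless graphs and single-residue structures flow through
  every stage (yielding all-zero vectors) rather than erroring; genuinely
  unusable inputs raise classed conditions (`rcc_input_error`,
  `rcc_empty_structure_error`, `rcc_size_error`, ...), and the batch driver
  records per-file failures and continues.

## Batch semantics

`batch_compute()` evaluates one record per (structure x distance x
side-chain setting) -- an embarrassingly parallel workload -- and sorts
records by (structure_id, d, side_chains), so output is invariant to worker
count and input order; the worker-determinism acceptance test compares
output files byte for byte. The default sweep (7 distances x 2 side-chain
settings) produces 14 records per structure; the original publication states
"16 representations" for the same 7 x 2 design, an arithmetic discrepancy we
note and do not resolve. CSV schema: `structure_id, chain, d, side_chains,
n_residues, n_edges`, then the 26 class columns in canonical order. Timings
in records are informational only and never asserted on (hardware-dependent).

## Known limitations

* No mmCIF reader; no structure validation/repair, assembly generation or
  symmetry expansion.
* Weighted contacts, CB-only/centroid contact definitions and k-clique
  communities are out of scope.
* Published classification accuracies (CATH cross-validation, GO Fmax) are
  not reproducible here: they require external databases and off-the-shelf
  ML training. This package's claims end at the fingerprint itself, which is
  why the test suite is built entirely on internal oracle equivalence and
  invariance properties.
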