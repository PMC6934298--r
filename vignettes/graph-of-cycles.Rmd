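---
title: "Graphs of cycles: representation, similarity and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graphs of cycles: representation, similarity and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcsim)
```

## The model

`gcsim` treats the *structure* of a molecule as the interconnection pattern
of its elementary cycles, not as its full atom-bond graph. The working
assumption, common in synthesis planning, is that the cyclic part of a
molecule carries its structural identity while acyclic appendages carry
chemical function. Two molecules are structurally similar when their ring
systems — ring sizes, fusion pattern, spiro junctions, and the chains
between ring systems — can be matched, even if substituents differ widely.

The pipeline is:

1. **Hydrogen-suppressed molecular graph.** Atoms are vertices labelled by
   element, bonds are edges labelled single/double/triple/aromatic.
   Hydrogens never lie on a cycle of a simple graph and are dropped at parse
   time. Cycle computations ignore bond labels entirely; they matter only to
   the molecular-graph MCES baseline when `match_bonds = TRUE`.

2. **Structural graph.** The 2-core (iterated deletion of degree-<2
   vertices). It retains exactly the rings and the isthmus chains between
   ring systems, and is empty for acyclic molecules.

3. **Canonical generator.** Cycles are GF(2) vectors over the edge index
   set; the cycle space of a component with `n` vertices and `m` edges has
   dimension `m − n + 1`. Horton's algorithm enumerates candidates
   `C(v, xy) = SP(v, x) + SP(v, y) + xy`, keeps the elementary ones, sorts
   by length, and greedily extracts a minimum-weight basis by Gaussian
   elimination. Minimum cycle bases are not unique (two fused 4-rings plus
   their symmetric difference give three interchangeable bases), so the
   basis is *closed*: whenever the XOR of two generator cycles is a single
   elementary cycle whose length equals the longer of the pair, it is added,
   repeating until fixpoint. The closure makes the generator — and
   everything downstream — invariant under atom renumbering and under the
   particular basis Horton happened to emit. A minimum cycle basis is
   hierarchical: its cycles of length ≤ j generate every elementary cycle of
   length ≤ j, which justifies the optional length filter below.

4. **Graph of cycles.** Vertices are generator cycles labelled by length μ.
   Two cycles sharing at least one atom get a type-1 edge (ν = 1) with
   θ = number of shared bonds; θ = 0 signals a spiro junction. Two cycles
   in different 2-connected components, sharing no atom, get a type-2 edge
   (ν = 2) when some path between them uses only bonds lying on no
   generator cycle; θ is the length of the shortest such path.

5. **Similarity.** The maximum common edge subgraph of two graphs of
   cycles, scored by
   `sim = (|V12| + |E12|)^2 / ((|V1| + |E1|) (|V2| + |E2|))`. The solver
   builds the compatibility product of the two line graphs and runs an
   exact branch-and-bound maximum-clique search; every candidate clique is
   converted back to an edge correspondence and accepted only if it induces
   a consistent injective vertex mapping (this closes the classical
   triangle-vs-star loophole of the line-graph reduction).

## Tunable parameters

* **`j` (cycle-length bound, default `Inf`).** Large rings are sometimes
  scaffolding rather than structure: two congeners can differ only by long
  cycles threaded through a heteroatom. Bounding `j` (7 is a useful working
  value: it keeps common 3–7-rings and drops macrocycles) makes such pairs
  identical in GC terms. No single default is faithful for all chemistry —
  macrolides *are* their macrocycle — so the bound is an explicit, logged
  parameter and the default keeps everything.

* **`tol` (cycle-length match tolerance, default 0.2).** Two cycles may
  correspond when their lengths differ by at most `tol * min(len_a, len_b)`:
  a 5-ring can stand in for a 6-ring (|5−6| = 1 ≤ 1), a 6-ring cannot stand
  in for an 8-ring (2 > 1.2). The value is an empirical setting, exposed as
  a parameter.

* **`theta_match` (`"strict"` default, `"relaxed"`).** Matched GC edges must
  always agree on type ν; strict mode also requires equal θ, which is the
  most conservative reading and is what makes isomer pairs score exactly
  1.0. Relaxed mode tolerates |θ − θ′| ≤ 1 when near-matches of fusion depth
  should still count.

* **`closure` (`"fixpoint"` default, `"single-pass"`).** A single pass over
  basis pairs can depend on pair order; iterating to fixpoint cannot, and
  canonicality is the whole point of the closure. Pairs only — closing over
  triples is never needed for the invariance property the package tests.

* **`time_limit` (seconds per pair, default 20).** MCES is NP-complete; the
  product graph of two molecular graphs can defeat any exact solver. On
  timeout the best common subgraph found so far is reported with status
  `"timeout-best-found"`, never silently as similarity 0. Graphs of cycles
  are typically 3–10 vertices, so GC comparisons effectively never time
  out; the limit matters for the molecular-graph baseline.

## Numerical and tie-break choices

* Shortest paths in Horton candidates use BFS with smallest-vertex-index
  tie-breaks; equal-length basis candidates are ordered by their edge
  pattern. Both choices affect which minimum basis is found, never its
  weight, and the closure erases the difference before anything downstream
  sees it (tested with 100 random relabelings per fixture).
* Generators are stored sorted by (length, edge pattern), so serialization
  is deterministic within a run; cross-run canonicality is defined up to
  graph isomorphism and checked with label-aware VF2.
* Degenerate inputs: an acyclic molecule has an empty GC and compares with
  similarity 0 (with a warning). Two single-ring molecules have one-vertex,
  zero-edge GCs; the edge-based MCES machinery cannot see them, so the
  solver falls back to maximum compatible vertex matching — a C5 and a C6
  ring score 1.0 because the length predicate admits (5, 6). This is the
  honest reading of the similarity degree for edgeless graphs and is
  documented behaviour, not an accident.
* Among common subgraphs with maximal edge count the solver prefers maximal
  vertex count, since the similarity degree rewards both.

## Interpretation conventions

Two clauses of the formal graph-of-cycles definition need interpretation,
and the worked examples fix both. First, the final clause of the edge-label
definition refers to type-1 edges twice; the second occurrence must be the
type-2 (shortest-path) label, otherwise the quinine values (ν=2 edge with
θ=2 across a two-bond chain) are impossible. Second, type-1 edges are
defined within a 2-connected component, yet spiro rings — which share
exactly one atom and are therefore split into different blocks by the cut
vertex — are explicitly given θ = 0. The package resolves this by letting
atom-sharing take precedence: any two cycles sharing an atom are type-1;
type-2 edges connect atom-disjoint cycles of different blocks through
isthmus chains. Consequently two ring systems separated by a third ring
system get no type-2 edge (the connecting path would have to cross ring
bonds), and when the `j` filter removes a cycle, the removed cycle's bonds
count as free for type-2 paths — membership is tested against the filtered
generator, exactly as the definition states.

## What the synthetic generator emulates

`generate_molecule()` grows fused-ring systems ring by ring: edge-fused
(one shared bond), spiro (one shared atom), bridged (a shared two-bond
path) and isthmus-linked (a connecting chain) attachments, ring sizes drawn
from 5–7 by default, carbon-biased element labels, and optional leaf-atom
decoration. Every attachment raises the cyclomatic number by exactly one,
so the intended ring count is ground truth for the minimum-basis size. A
companion `random_graph_molecule()` produces arbitrary connected graphs
(spanning tree plus chords) to exercise the cycle-space code on topologies
fused-ring growth cannot reach (K4-like blocks, high chord density). Both
use a private linear-congruential stream, so fixtures are reproducible and
independent of R's global RNG.

What they do *not* emulate: valence constraints (a carbon may end up with
five neighbours), aromaticity perception, stereochemistry, charges, and the
size distribution of real databases. Passing tests therefore demonstrate
correctness of the graph algorithms on realistic *topologies*, not chemical
validity of the fixtures; the shipped transcriptions (quinine, dopamine,
strychnine) cover the worked-example chemistry.

The strychnine congener `vomicine_like()` is a synthetic stand-in, built by
re-bridging the strychnine skeleton through an added N-methyl nitrogen so
that the minimum cycle basis gains a 9-ring through the nitrogen and the
closure a second 9-cycle. It reproduces the documented behaviour of the
real pair — identical graphs of cycles at `j = 7`, different ones
unbounded — but its molecular formula is not vomicine's, and it is named
and documented accordingly.

## Validation scales

The property tests run at sizes where independent oracles are exhaustive:
minimum-basis weight and hierarchy against full cycle enumeration on 200
random graphs of ≤ 12 edges; canonicality over 20 fixtures × 100 random
relabelings; MCES against brute-force common-subgraph search on 100 random
labelled pairs of ≤ 7 edges; clique reduction against exhaustive clique
enumeration; network components against union-find on a 50-molecule
hierarchical matrix. These sizes were chosen so every oracle is exact;
the algorithms themselves have no small-size assumptions.

## Known limitations

* MCES on molecular graphs grows exponential quickly; beyond ~20 ring-system
  bonds per molecule expect timeouts at the default limit (reported, never
  hidden). The GC comparison is the intended fast path.
* Aromatic bond labels survive SDF input (bond code 4) but the Open Babel
  SMILES route may kekulize; this never affects cycles, only strict
  bond-label matching in the molecular-graph baseline.
* No stereochemistry, charges, isotopes or tautomer handling; molecules are
  compared as constitutional graphs.
* Fingerprint generation for the Tanimoto baseline is delegated to external
  toolkits (e.g. ChemmineR atom pairs via `sdf_fragment_sets()`); only the
  coefficient itself is implemented here.
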