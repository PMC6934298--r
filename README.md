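# gcsim — structural similarity of molecules via graphs of cycles

Chemists searching a reaction database for a synthesizable precursor care
less about atom-by-atom agreement than about whether two molecules share the
same *ring architecture*: which elementary cycles exist, how long they are,
and how they are fused, spiro-joined or chained together. `gcsim` implements
that notion of structural similarity for cheminformatics work in R.

## The representation and the measure

For a hydrogen-suppressed molecular graph *G* = (*V*, *E*):

1. **Structural graph.** Take the 2-core of *G* (iteratively delete vertices
   of degree < 2): the ring systems plus the isthmus chains joining them.
2. **Canonical generator.** On each 2-connected component, compute a minimum
   cycle basis *B* with Horton's algorithm (candidates
   *C*(*v*, *xy*) = *SP*(*v*,*x*) + *SP*(*v*,*y*) + *xy*, greedily reduced
   over GF(2)). Because minimum cycle bases are not unique, close *B*: for
   every pair *c*<sub>i</sub>, *c*<sub>j</sub> whose XOR is a single
   elementary cycle *c* with |*c*| = max(|*c*<sub>i</sub>|, |*c*<sub>j</sub>|),
   add *c*; repeat to fixpoint. The result is independent of atom numbering
   and of which basis Horton found. Optionally keep only cycles of length
   ≤ *j* (minimum cycle bases are hierarchical, so the ≤ *j* subset generates
   every cycle of length ≤ *j*).
3. **Graph of cycles (GC).** One vertex per generator cycle, labelled by its
   length μ. Cycles sharing at least one atom get a type-1 edge (ν = 1)
   labelled θ = number of shared bonds (θ = 0 for spiro junctions); cycles of
   different ring systems joined by an isthmus chain get a type-2 edge
   (ν = 2) labelled θ = shortest chain length.
4. **Similarity.** The maximum common edge subgraph (MCES) of two GCs —
   solved exactly as a maximum clique on the compatibility product of their
   line graphs — scored by the similarity degree

   sim(G₁, G₂) = (|V₁₂| + |E₁₂|)² / ((|V₁| + |E₁|) · (|V₂| + |E₂|)) ∈ [0, 1],

   where cycles may correspond when ||v| − |v′|| ≤ 0.2 · min(|v|, |v′|).
   Baselines: the same MCES on the molecular graphs themselves
   (`mg_similarity()`), and the Tanimoto coefficient
   σ = F₁₂ / (F₁ + F₂ − F₁₂) over externally generated fragment sets
   (`tanimoto()`).

All-pairs matrices can be thresholded into connected components with sizes
and densities (edges / (s(s−1)/2)) to map families of structurally similar
molecules (`similarity_matrix()`, `components_at_threshold()`,
`threshold_sweep()`).

## Worked example

```r
library(gcsim)
mols <- builtin_molecules()

summary(mols$quinine)
#> <molgraph> quinine
#>   atoms: 24 - C:20 N:2 O:2
#>   bonds: 27 - aromatic:11 double:1 single:15
#>   cyclomatic number: 4

graph_of_cycles(mols$quinine)
#> <graph_of_cycles> quinine: 5 cycle(s), 6 edge(s)
#>   mu: 6 6 6 6 6
#>   edges: c1-c5 nu=1 theta=1; c2-c3 nu=1 theta=3; c2-c4 nu=1 theta=3;
#>          c2-c5 nu=2 theta=2; c3-c4 nu=1 theta=3; c3-c5 nu=2 theta=2
```

Quinine's cycle basis has 4 cycles (cyclomatic number 4), but the
canonicalization adds the third equivalent 6-ring of the quinuclidine cage,
giving the 5-cycle generator. In the GC, the two fused quinoline rings share
one bond (ν=1, θ=1), the quinuclidine rings pairwise share three-bond arms
(θ=3), and the two-bond chain linking the ring systems appears as ν=2, θ=2
edges.

Bounding the cycle length separates core structure from incidental large
rings. Strychnine and the shipped vomicine-like congener differ only by
9-membered rings through a ring nitrogen:

```r
gc_similarity(mols$strychnine, mols$vomicine_like, j = 7)
#> <mces_result> strychnine vs vomicine_like: sim = 1 (|V12| = 7, |E12| = 11, optimal, 0 s)
gc_similarity(mols$strychnine, mols$vomicine_like)       # unbounded j
#> <mces_result> strychnine vs vomicine_like: sim = 0.6 (|V12| = 7, |E12| = 11, optimal, 0.095 s)
```

At *j* = 7 the two graphs of cycles are identical (similarity 1); with the
9-cycles included they are not. A command-line front end wrapping the same
functions ships in `inst/cli/gcsim.R` (subcommands `parse`, `cycles`, `gc`,
`pair`, `matrix`, `network`, `fixtures`).

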