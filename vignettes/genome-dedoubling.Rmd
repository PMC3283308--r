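---
title: "Genome dedoubling: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome dedoubling: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdd)
```

## The problem

Breakpoint-duplication (BD) rearrangements copy one or two markers while
breaking and regluing a chromosome, leaving the duplicate on the far side of
the breakpoint. Given a present-day genome whose duplicated families arose
this way, `gdd` searches for a shortest rearrangement scenario back to a
non-duplicated ancestor. The key reduction is that a length-k BD scenario
from ancestor `A` corresponds to a length-k *plain* DCJ/reversal scenario
from a *dedoubled* genome `D` (every couple adjacent, same orientation) whose
reduction is `A`; so the computational problem is: transform the given
totally duplicated genome into *some* dedoubled genome with as few DCJs (or
reversals) as possible. `lift_bd_scenario()` realizes this correspondence
constructively and is tested by replay on seeded simulations.

Partially duplicated genomes are reduced first: `totalize()` replaces each
maximal run of non-duplicated markers beginning with `s*x` by the pair
`s*x, s*x'`. The introduced pair is already dedoubled, so it adds one couple
*and* one independent self-loop to the graph below, leaving both distance
formulas unchanged; this placement is the package's choice of the
distance-preserving realization and is validated against the brute-force
oracle on tiny instances. The run map restores the original markers into the
reconstructed ancestor (`expand_ancestor()`).

## The dedoubled adjacency graph and the distances

`build_adjacency_graph()` takes the adjacencies of `G` as vertices; each
couple `x` contributes the edge pairing head(`x`) with tail(`x'`) and the
edge pairing tail(`x`) with head(`x'`). This head–tail pairing is the unique
rule under which exactly the dedoubled forms `(x x')`/`(x' x)` become
self-loops, which the theory requires (a dedoubled genome must show one
independent self-loop per couple). Degrees are 1 or 2, so components are
paths and cycles; two elements *intersect* when they share a couple, and an
element is *duplicated* when it contains a couple twice.

With `n` couples, `C` cycles, and `C_i` the maximum size of a set of
pairwise independent non-duplicated cycles:

* unrestricted DCJ: `d = n − C_i`;
* DCJ with a single linear chromosome required at the end: `d = n − C + 2m`
  with `m = C − C_i` the minimum number of cycles to merge into the path;
* reversals, for oriented genomes: also `n − C + 2m`.

Choosing the cycle set is a maximum independent set problem on the conflict
graph of non-duplicated cycles (APX-complete in general).
`max_independent_cycles()` offers an exact branch-and-bound (branching on
the maximum-degree node with a size bound; default gate 25 nodes,
overridable) and a deterministic greedy (repeatedly take a minimum-degree
node, ties by smaller couple set then lexicographically). The concrete
2-approximation from the original theory is not reproduced here; instead
the greedy's factor-2 contract is enforced empirically against the exact
solver on 500 seeded instances in the test suite. The exact solver is
cross-checked against exhaustive subset enumeration and against
`igraph::independence_number()`.

## Scenario construction

`dcj_sort()` fixes an exact selection S_i, then (a) resolves each selected
cycle with k couples by k−1 self-loop extractions — cut the two endpoint
adjacencies of one couple edge, rejoin the paralogous extremities into the
dedoubled pair — leaving the last couple sorted for free, and (b) sorts each
uncovered couple with one such DCJ. Because an element's vertices only
contain extremities of its own couples, these operations never disturb
sorted couples or the selected cycles, so every step decreases the exact
distance by one (asserted per-step in the tests).

`dcj_sort_linear()` first merges every non-selected cycle into the path
(realized as reversals: one cut in the cycle, one in the path; `C` and `m`
each drop by one). The resolution phase then picks, at each step, a sorting
DCJ that provably decreases the remaining distance by one and keeps exactly
one linear chromosome; intermediates may carry circular chromosomes, which
later steps reabsorb. The remaining-distance measure applies `n − C + 2m` to
such intermediates — the formula is stated in the theory for single-linear
genomes only, and its extension to one-linear-plus-circles states is a
design choice of this package, validated against breadth-first search
exhaustively for two couples and on seeded three-couple genomes. A full
search over all DCJs backs the preferred candidates; it has never been
needed in testing but guards the optimality invariant.

`reversal_sort()` follows the overlap-graph theory: `build_overlap_graph()`
gives each couple the smallest interval containing its copies, with edges
for *properly crossing* intervals (intersecting, neither containing the
other — under the containment-inclusive reading the 26-marker worked genome
would not reproduce its printed component count). A vertex is *oriented*
when its copies carry opposite signs and *sorted* when the couple is already
dedoubled; sorted vertices are isolated and excluded from component
classification — without this exclusion a genome like `L 1 -1' 2 2'` would
be misclassified as unoriented and its one-reversal scenario lost. Phase 1
merges non-selected cycles with merging reversals (these never strand an
unoriented component); phase 2 repeatedly applies `rho`/`rho_bar` of a
maximum-score oriented vertex, verifying per step that a cycle is extracted
(distance −1) and the genome stays oriented, and falling back to the other
oriented vertices if the maximum-score vertex offers no safe variant — the
theory guarantees existence but not that the max-score vertex always
suffices, so the implementation checks rather than assumes. Scores are
computed by rebuild; the local-complementation shortcut is implemented
independently and the two routes are compared in the tests after every
applied reversal.

Unoriented genomes are rejected by the reversal solver (`gdd_unoriented_genome`):
their treatment requires an orientation cost beyond this package's scope.
The linear-DCJ model covers them at the same `n − C + 2m` cost.

## Operations and their encoding

A DCJ is stored as two cut adjacencies (ordered extremity pairs) plus a
rejoin `pattern` pairing the cuts' elements by position; reversals are the
orientation-reversing rejoin and need no pattern. BD operations name the
duplicated family and the cut where its copy is inserted; the copy is glued
to the marker with the same orientation and the second step cuts *between*
the copies, so the duplicate ends up flanking the breakpoint (for a
BD-reversal this yields the familiar inverted duplication at the two
breakpoint regions). Scenario files print cuts order-preservingly and BD
lines carry their explicit rejoin, making replay bit-exact; telomeres print
as `$`.

Telomere semantics are capped: cutting a telomeric adjacency exposes one
real extremity; a rejoin of two caps deletes the empty chromosome. The DCJ
move set (solvers and oracle alike) cuts two existing adjacencies — linear
fission through a phantom null chromosome is not modelled.

## The simulator and what it does (not) show

`random_ancestor()` draws a signed permutation over 1..n;
`random_bd_evolution()` applies k operations with a 40% 1-BD / 30% 2-BD /
30% plain mix (the theory gives no generative model; these defaults exercise
every operation kind and are configurable), drawing cuts uniformly over
current adjacencies; the reversal model restricts to single-chromosome
reversals, and `oriented_only` resamples until the totalized derived genome
is oriented. Every simulation record replays from its ancestor to its
derived genome, and solver distances respect the bound `d ≤ k`.

The simulator emulates the *combinatorial* model only: uniform breakpoint
usage, no breakpoint re-use hot spots, no sequence divergence between
copies, no marker loss, at most two copies per family. Passing tests
therefore certify the algorithms on the model's own terms, not the fidelity
of the model to any particular genome.

## Numerical and testing choices

Problem sizes: the brute-force BFS oracle is exact and is run exhaustively
over all ~600 two-couple genomes and on 100 seeded three-couple genomes per
model; scenario soundness is replayed on 200 seeded genomes per model with
up to seven couples; the simulation bound on 500 seeded evolutions with up
to six operations; the greedy/exact ratio on 500 seeded instances with up to
ten couples. These sizes keep the whole suite under ten minutes on one CPU
while covering every code path; the formulas themselves are size-independent.

Determinism: copy labels are canonical (first occurrence in reading order is
plain) but every computation is invariant under relabelling, which the tests
assert; element traversals, tie-breaks (smallest family, then smallest
adjacency) and the greedy are deterministic, and seeds control all sampling.
Genome equality is tested up to chromosome order, rotation, reflection and
copy-label swaps.

## Limitations

* Reversal dedoubling of unoriented genomes (and the associated orientation
  cost) is out of scope.
* The exact cycle selector is exponential in the worst case and gated at 25
  conflict-graph nodes; beyond that, use the greedy (distance then becomes
  an upper bound within factor ~2 on the `C_i` term).
* Families with more than two copies are rejected; marker inference from
  sequence data is upstream of this package.
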