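# gdd — genome dedoubling by DCJ and reversal

Segmental duplications in eukaryote genomes are frequently found at the
breakpoints of rearrangement events: when a chromosome breaks and is
reglued, a short segment near the break is sometimes copied to the other
side of the junction (inverted duplications at reversal breakpoints in
*Drosophila* are the classic example). `gdd` implements the combinatorial
machinery for exploiting exactly those duplications: given a present-day
genome whose duplicated markers were created by *breakpoint-duplication*
(BD) rearrangements, it computes a minimum-length rearrangement scenario
back to a non-duplicated genome and reconstructs that ancestor.

This is a different problem from genome halving: duplications here arise
one or two markers at a time, at breakpoints, not from whole-genome
doubling.

## The model in brief

Genomes are sequences of signed markers on linear or circular chromosomes;
a duplicated family has two interchangeable copies `x` and `x'` (a
*couple*). A genome is *dedoubled* when every couple is adjacent with the
same orientation — `(x x')` or `(x' x)` — so that collapsing each pair
yields a non-duplicated ancestor. A *BD-DCJ* (or *BD-reversal*) first
copies one or two markers at its breakpoints, then performs an ordinary
double-cut-and-join (or reversal). Finding the nearest ancestor under BD
operations reduces to finding a minimum DCJ (reversal) scenario from the
given totally duplicated genome `G` to *some* dedoubled genome.

Distances come from the **dedoubled adjacency graph** A(G): vertices are
the adjacencies of `G`; each couple contributes two edges pairing
paralogous extremities head-to-tail. Components are paths and cycles. With
`n` couples, `C` cycles, `C_i` the maximum number of pairwise independent
non-duplicated cycles, and `m = C − C_i` the minimum number of cycles to
merge into the path:

| model                                    | distance      |
|------------------------------------------|---------------|
| DCJ, any chromosome structure            | `n − C_i`     |
| DCJ, single linear chromosome preserved  | `n − C + 2m`  |
| reversal (oriented genomes)              | `n − C + 2m`  |

Selecting `C_i` is an NP-complete maximum-independent-set problem; the
package ships an exact branch-and-bound (default, gated at 25 cycles) and a
deterministic greedy heuristic that is empirically within factor two of the
optimum. Reversal sorting works on a **dedoubled overlap graph** in
Hannenhalli–Pevzner style: one vertex per couple with the interval between
its copies, edges for properly crossing intervals, and sorting reversals
acting by local complementation.

Partially duplicated genomes are handled by *totalization*: every maximal
run of non-duplicated markers starting with `x` is replaced by the pair
`x x'` and restored into the reconstructed ancestor afterwards.

## A worked example

The genome `L 1 2 2' 1'` (one linear chromosome, couples 1 and 2 nested)
has A(G) = one path {1}, one 2-edge cycle {1,2}, one self-loop {2}; the two
cycles intersect, so `C_i = 1`:

```r
library(gdd)
g <- parse_genome("L 1 2 2' 1'")
dcj_distance(g)
#> dcj dedoubling distance: 1  (n=2, C=2, C_i=1; exact)
dcj_distance_linear(g)
#> dcj_linear dedoubling distance: 2  (n=2, C=2, C_i=1, m=1; exact)

res <- dcj_sort_linear(g)
res$scenario
#> Scenario with 2 operation(s)
#>   REVERSAL ; (2,2') ; ($,1)
#>   DCJ ; (1,2) ; (-1',-2') ; pattern=1
write_genome(res$genome)
#> [1] "L -1' -1 2' 2"
write_genome(reduce_dedoubled(res$genome))
#> [1] "L -1 2"
```

One unrestricted DCJ suffices to dedouble (excising a circular `(2 2')`),
but keeping a single linear chromosome costs `n − C + 2m = 2`. The
26-marker example genome with 13 couples:

```r
fig <- worked_examples()$worked26
reversal_distance(fig)
#> reversal dedoubling distance: 10  (n=13, C=3, C_i=3, m=0; exact)
length(build_overlap_graph(fig)$components)
#> [1] 4
```

A command-line interface wraps the same functions:

```sh
exec/gdd distance genome.gdd --model reversal --json
exec/gdd sort genome.gdd --model dcj-linear -o scenario.txt --ancestor ancestor.gdd
exec/gdd simulate --markers 8 --ops 4 --model reversal --seed 7 -o derived.gdd
```

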