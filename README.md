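# supernoder

Recursive supernode extraction from labeled networks.

`supernoder` simplifies a labeled network by finding over-represented small
motifs, collapsing node-disjoint motif occurrences into *supernodes*, and
repeating the procedure on the reduced graph. Supernodes from one round can
take part in the motifs of the next, so the output is a hierarchy of
progressively coarser, structure-preserving summaries of the input network.

## The method

Given a labeled graph $G = (N, E, \ell)$, a motif size $k$ and a frequency
threshold $t$, one reduction iteration performs:

1. **Enumeration** — list every connected induced $k$-node subgraph with the
   ESU scheme (`enumerate_k_subgraphs()`); per-depth sampling probabilities
   give the randomized RAND-ESU variant for large inputs.
2. **Census** — group instances into label-preserving isomorphism classes
   (`find_frequent_motifs()`), hashing on a label/degree signature and
   refining each hash bucket with an explicit backtracking isomorphism
   check; keep classes whose F1 count (occurrences, overlaps allowed) is
   at least $t$.
3. **Disjoint selection** — from the frequent instances, extract a large set
   that is pairwise node-disjoint (the F3 measure). This is a maximum
   independent set problem on the instance *overlap graph*; five heuristics
   are provided (`select_disjoint()` with `"h1"`–`"h5"`): greedy shuffles,
   Ramsey recursion on chunks, motif-degree ranked elimination, repeated
   ranked elimination, and sampled overlap-degree elimination. An exact
   branch-and-bound solver (`exact_mis()`, ≤ 25 instances) serves as a
   yardstick.
4. **Collapse** — replace each selected instance by a supernode labeled with
   the sorted concatenation of member labels, re-attaching all external
   edges (`collapse_instances()`); node count drops by exactly $(k-1)$ per
   selected instance.

Node labels may additionally be remapped to a coarser level of a label
hierarchy before the run (`map_labels()`), which merges isomorphism classes
and lets more motifs pass the threshold.

See the vignette (`vignettes/motif-based-network-reduction.Rmd`) for the
algorithms, parameter defaults, tie-breaking rules and design decisions.

## Worked example

Plant six `(A, A, B)` triangles in a sparse random background, then recover
and collapse them:

```r
library(supernoder)

fx <- generate_planted_network(seed = 2024)   # 6 planted triangles + 60 background nodes
fx$graph
#> A labeled undirected graph: 78 nodes (0 supernodes), 32 edges

res <- run_pipeline(fx$graph, k = 3, t = 6, heuristic = "h1", seed = 7)
tidy(res)
#> # A tibble: 2 × 6
#>   iteration n_classes n_frequent_instances n_selected n_nodes n_edges
#>       <int>     <int>                <int>      <int>   <int>   <int>
#> 1         0        NA                   NA         NA      78      32
#> 2         1         1                    6          6      66      14

glance(res)
#> # A tibble: 1 × 7
#>   iterations initial_nodes final_nodes initial_edges final_edges total_selected
#>        <int>         <int>       <int>         <int>       <int>          <int>
#> 1          1            78          66            32          14              6

dplyr::filter(graph_nodes(res$graphs[[1]]), is_supernode)
#> # A tibble: 6 × 4
#>   id    label is_supernode members
#>   <chr> <chr> <lgl>        <list>
#> 1 SN1_1 A-A-B TRUE         <chr [3]>
#> 2 SN1_2 A-A-B TRUE         <chr [3]>
#> ...
```

The single frequent class is the planted triangle; all six disjoint copies
are selected and the graph shrinks by $(k-1) \times 6 = 12$ nodes.
`autoplot(res)` draws the node/edge trajectory, and `write_reduction(res, dir)`
writes per-iteration node/edge/provenance files plus a `report.tsv`.

A command-line driver is installed at `inst/scripts/supernoder`:

```sh
Rscript inst/scripts/supernoder --nodes nodes.txt --edges edges.txt \
  --size 3 --threshold 6 --heuristic h1 --iterations 2 --seed 1 --out out/
```

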