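# phyloflat

Flat array-backed phylogenies for ultra-large trees.

Viral and bacterial phylogenies now reach tens of millions of tips, and many
analyses on them (clustering, ancestral state reconstruction, clock
estimation, transmission risk) reduce to loading the tree and traversing it.
Object-per-node tree libraries struggle at that scale: pointers, per-node
objects and per-node containers dominate memory, and traversal becomes
pointer chasing.  `phyloflat` is for bioinformaticians who need to load and
walk very large rooted trees cheaply, and for tool authors who want a minimal
tree backend.

## The representation

A tree with `N` nodes is four parallel arrays indexed by a 0-based node
identifier `u`:

* `parent[u]` — the parent of `u` (a reserved null sentinel, the maximal
  value of the configured 32- or 64-bit identifier width, for the root);
* `children[u]` — `u`'s children in Newick left-to-right order;
* `label[u]` — `u`'s label (optional array);
* `length[u]` — the length of the edge from `parent[u]` to `u` (optional
  array).

Identifiers are assigned in the depth-first pre-order of the Newick text by a
**single-pass streaming parser** with a constant-size input buffer, so

* `parent[u] < u` for every non-root node,
* the ascending identifier sweep `0..N-1` *is* a pre-order traversal and the
  descending sweep `N-1..0` *is* a valid post-order — traversal is an index
  range, not a data structure,
* the most recent common ancestor of a set of nodes falls out of repeatedly
  replacing the maximum-identifier member with its parent.

On top of this the package provides patristic distances, subtree extraction,
a level-order re-encoding in which every node's children occupy a contiguous
identifier interval (so the whole child structure is two integers per node),
a dual-birth/Yule branching-process simulator for generating test trees of
any size, and a command-line interface (`inst/cli/phyloflat`).

## Worked example

```r
library(phyloflat)

tr <- parse_newick(text = "((A:0.25,B:0.5)X:0.125,(C:0.75,D:1)Y:0.25)R;")
tr
#> flat_tree: 7 nodes (4 leaves, 3 internal), 32-bit IDs
#>   total branch length: 2.875

tr$parent                       # pre-order IDs: R=0, X=1, A=2, B=3, Y=4, C=5, D=6
#> 4294967295  0  1  1  0  4  4

traverse(tr, "levelorder")
#> 0 1 4 2 3 5 6

find_mrca(tr, c(2, 3))          # MRCA of A and B is X
#> 1

patristic_distance(tr, 2, 6)    # A -> X -> R -> Y -> D
#> 1.625

write_newick(extract_subtree(tr, 1))
#> (A:0.25,B:0.5)X;
```

The parent array's first entry is the 32-bit null sentinel `2^32 - 1 =
4294967295`: node 0 is the root.  The total branch length `2.875` is the sum
of the six non-root edges; the distance `1.625` is `0.25 + 0.125 + 0.25 + 1`
along the path from A to D.

Simulated trees follow the same identities — a Yule tree with `n` leaves
always has `2n - 1` nodes:

```r
sim <- simulate_tree(10000, seed = 42)
sim
#> flat_tree: 19,999 nodes (10,000 leaves, 9,999 internal), 32-bit IDs
#>   total branch length: 10150.1
```

## Limitations

* Newick only — no Nexus, NeXML or phyloXML, and one tree per file.
* Topology is immutable after parsing/simulation; labels and lengths are
  editable.  (The immutability is what guarantees the pre-order invariant.)
* A missing length token is stored as `0`; there is no missing-value marker.
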