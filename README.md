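# keynodes

Spectral identification of the nodes that matter to a network's community
structure — and of *how* they matter.

Many networked systems in biology and beyond (protein interaction maps,
neural wiring, collaboration and association networks) organize into
communities: groups with dense internal and sparse external connections.
Some nodes are disproportionately important to that organization, and they
come in two kinds. A **community core** organizes its own community —
remove it and the community structure blurs. A **bridge** sits between
communities with near-equal membership in several of them — remove it and
the structure sharpens. `keynodes` detects and distinguishes both using
only the spectrum of the graph, without ever computing an explicit
community partition.

## The two indices

For an undirected, optionally weighted network with adjacency matrix `W`
and `c` communities, the `c` largest adjacency eigenvalues λ₁ ≥ … ≥ λ_c
separate from the bulk of the spectrum and carry the community structure.

**Importance.** The importance of node *i* is the mean relative change of
those eigenvalues when the node is removed:

    I_i = (1/c) Σ_{j=1..c} (λ_j − λ'_j) / λ_j

where λ'_j are the eigenvalues after deleting row and column *i*
(`importance_exact()`). First-order perturbation theory reduces this to a
closed form in the leading eigenvectors x_j:

    I_i ≈ (1/c) Σ_{j=1..c} x_ji²

(`importance_perturbative()`), one eigendecomposition for the whole
network. The normalized index Ī_i = I_i / Σ_j I_j sums to one, so its mean
is exactly 1/N; on an Erdős–Rényi null model every node sits near 1/N, and
`Ī_i > 1/N` flags a node as important to community structure.

**Bridgeness.** The RatioCut relaxation places community information in the
eigenvectors u_k of the smallest graph-Laplacian eigenvalues (`L = D − W`).
Node *i*'s vertex-vector magnitude across the first `c` of them,

    s_i = (1/c) Σ_{k=1..c} u_ki²   (normalized to sum 1)

is large for nodes planted firmly inside one community and near zero for
nodes shared between several. `s_i < 1/N` is the bridgeness criterion.
`classify_nodes()` combines both rules: bridge if the score is below
threshold, else core if the importance is above threshold, else peripheral.

The number of communities `c` is the only input besides the graph; it can
be read off the adjacency eigengap with `estimate_num_communities()`.

## Worked example

The package ships an 11-node weighted test network: two 5-cliques
(communities {1..5} and {6..10}) with designated cores 4 and 9 (intra-
community weight 2, all inter-community links weight 0.2, other
intra-community links weight 1) plus bridge node 11 tied to all ten nodes
with weight 1.

```r
library(keynodes)
g  <- generate_weighted_toy()
imp <- importance_perturbative(g, c = 2)
sc  <- bridge_score(g, c = 2)
round(imp$normalized, 3)
#>     1     2     3     4     5     6     7     8     9    10    11
#> 0.079 0.079 0.079 0.150 0.079 0.079 0.079 0.079 0.150 0.079 0.067
round(sc$score, 4)
#>      1      2      3      4      5      6      7      8      9     10     11
#> 0.0955 0.0955 0.0955 0.0955 0.0955 0.0955 0.0955 0.0955 0.0955 0.0955 0.0455
classify_nodes(imp, sc)$label
#>          1          2          3          4          5          6          7
#> peripheral peripheral peripheral       core peripheral peripheral peripheral
#>          8          9         10         11
#> peripheral       core peripheral     bridge
```

The cores 4 and 9 clear the importance threshold 1/11 ≈ 0.091; node 11's
score 0.0455 falls below it, marking the bridge. On Zachary's karate club
(`inst/extdata/karate.edgelist`, 34 nodes), the instructor (node 1) and
administrator (node 34) attain the two largest importances with `c = 2`,
and node 3 — tied to both factions — has one of the smallest bridgeness
scores.

A thin command-line interface wraps the same pipeline:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","keynodes.R",package="keynodes"))')" \
    analyze --toy weighted --c 2
```

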