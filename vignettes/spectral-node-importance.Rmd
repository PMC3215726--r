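---
title: "Spectral indices of node importance to community structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral indices of node importance to community structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keynodes)
```

## The model

A network with `c` strong communities has an adjacency matrix that is, up
to node relabeling, a perturbed block-diagonal matrix: the diagonal blocks
are the communities, the off-diagonal blocks the sparse inter-community
links. Each disconnected community contributes its own leading eigenvalue,
and when the inter-community perturbation is weak those `c` eigenvalues
remain well separated from the bulk of the spectrum. They are therefore the
spectral carriers of community structure, and a node's importance to that
structure can be defined as the mean relative change of the `c` largest
adjacency eigenvalues when the node is removed:

$$I_i \;=\; \frac{1}{c}\sum_{j=1}^{c}\frac{\lambda_j - \lambda_j'}{\lambda_j},$$

with $\lambda_j'$ the eigenvalues of the principal submatrix obtained by
deleting row and column $i$ (`importance_exact()`). Cauchy interlacing
guarantees $\lambda_j' \le \lambda_j$, so $I_i \ge 0$.

Computing $N$ eigendecompositions is wasteful, and first-order perturbation
theory gives a closed form. Writing the removal of node $i$ as a rank-style
perturbation of the adjacency matrix and discarding second-order terms, the
relative eigenvalue change collapses to the squared eigenvector component:
$(\lambda_j - \lambda_j')/\lambda_j \approx x_{ji}^2$, hence

$$I_i \;\approx\; \frac{1}{c}\sum_{j=1}^{c} x_{ji}^2$$

(`importance_perturbative()`), one symmetric eigendecomposition for the
whole network. Because each eigenvector is unit-norm, these raw values sum
to exactly 1. Before the large-$N$ simplification the first-order ratio is
$x_{ji}^2/(1 - x_{ji}^2)$; the package exposes this as
`corrected = TRUE`, but the plain form is the default — it is the one whose
row sums are exactly 1, matching the normalization the index is built on.
The normalized index $\bar I_i = I_i/\sum_j I_j$ has mean exactly $1/N$ on
*every* graph, which fixes the null criterion: on an Erdős–Rényi random
graph (homogeneous, no communities) each node is expected at $1/N$, so
$\bar I_i > 1/N$ flags nodes important to community structure.

Both methods rank nodes nearly identically on planted-partition benchmarks
(the test suite requires Spearman correlation of at least 0.9 at mixing up
to $z_{out} = 4$); the perturbative form is the default for its single
decomposition.

## Cores versus bridges

Two kinds of nodes pass the importance test for opposite reasons. The
distinction comes from the graph Laplacian $L = D - W$. Minimizing RatioCut —
the partition objective $\sum_j \mathrm{cut}(A_j,\bar A_j)/|A_j|$ — relaxes
to an eigenproblem of $L$: for two groups the optimal relaxed indicator is
the Fiedler vector, and for $c$ groups the bottom-$c$ eigenvectors span the
relaxed solution (the package's `ratiocut()` and `ratiocut_quadratic()`
verify the underlying identities $h^\top L h = N\cdot\mathrm{RatioCut}$ and
$\mathrm{Tr}(H^\top L H) = \mathrm{RatioCut}$ on exhaustive small cases).
Collecting node $i$'s components across those eigenvectors gives its vertex
vector; its squared magnitude

$$s_i \;=\; \frac{1}{c}\sum_{k=1}^{c} u_{ki}^2,$$

normalized to sum 1, is the bridgeness score. A node firmly inside one
community carries full weight in the relaxed indicators ($s_i$ large); a
node with near-equal membership in several communities sits near the zero
crossing of each indicator ($s_i \approx 0$), and its presence forces a
large RatioCut. The same null-model argument as above makes $s_i < 1/N$ the
bridge criterion.

The constant eigenvector $u_1$ (eigenvalue 0) is *included* in the sum.
This is deliberate: on the 11-node weighted example below the bridge scores
$(1/2)(1/11) \approx 0.0455$ — the constant vector's share alone — which is
exactly what the closed-form symmetry analysis and the package's printed
output give. Excluding $u_1$ would break the sum-to-one structure that the
$1/N$ criterion rests on.

`classify_nodes()` applies the two criteria independently, score first:
bridge if $s_i < m_b/N$, else core if $\bar I_i > m_i/N$, else peripheral.
A bridge is not required to pass the importance threshold first — spreading
its membership over several communities dilutes its leading-eigenvector
mass, so a genuine bridge can sit slightly below $1/N$ in importance while
being the most structurally consequential node in the graph (the weighted
example's bridge does exactly this: $\bar I = 0.067 < 1/11$). Near the
thresholds the robust signal is the relative ranking of scores, not the
hard cut; the multipliers $m_i, m_b$ (default 1) expose the cut to the
user.

## Choosing c

Both indices need the number of communities, not a partition. The
adjacency eigengap provides it: `estimate_num_communities()` returns
$\arg\max_c (\lambda_c - \lambda_{c+1})$ over a candidate range, on
algebraically sorted eigenvalues. Two remarks:

* **Algebraic versus magnitude ordering.** Community modes are the large
  *positive* eigenvalues. Sorting by magnitude would let a large negative
  eigenvalue (a strongly bipartite-like mode) displace a community mode, so
  the package sorts algebraically and warns when a discarded eigenvalue
  exceeds the retained ones in magnitude.
* **Degeneracy.** When position $c$ falls inside a degenerate eigenvalue
  block (exactly degenerate for symmetric constructions and disconnected
  graphs), squared-component sums over the first $c$ eigenvectors are
  basis-dependent. The package therefore detects the block containing
  position $c$ (tie tolerance $10^{-8}$, relative) and weights the whole
  block's eigenspace fractionally: vectors before the block get weight 1,
  the block's vectors share the remaining $c - a + 1$ units equally. This
  is the projector onto the block eigenspace up to the unique scaling that
  preserves $\sum_i I_i = 1$, and it makes both indices basis-invariant.

## Worked example

```{r toy}
g <- generate_weighted_toy()
res <- run_pipeline(g, c = 2)
res$table
```

The construction (two 5-cliques, cores 4 and 9 with intra-community weight
2, all inter-community links 0.2, bridge 11 tied to every node with weight
1) is mirror-symmetric, so the score admits a closed form: the Fiedler
vector is $\pm 1/\sqrt{10}$ on the cliques and 0 on the bridge, giving
$s_{11} = (1/2)(1/11) = 0.04545$ and $s_{\text{other}} =
(1/2)(1/11 + 1/10) = 0.09545$. The test suite checks the computed scores
against this closed form at $10^{-10}$.

## Numerical choices

* Dense `eigen(symmetric = TRUE)` below 500 nodes; ARPACK
  (`igraph::arpack`) above, with a fixed deterministic start vector
  (`sin(1:N)`) so repeated runs agree, convergence tolerance $10^{-9}$.
  Iterative results are tested against the dense decomposition.
* Symmetry on load: asymmetry up to $10^{-9}$ (relative) is averaged away;
  beyond that loading fails — directed graphs must not silently pass as
  undirected. Self-loops and negative weights are rejected.
* Exact importance divides by $\lambda_j$; if any of the `c` leading
  eigenvalues is $\le 10^{-12}$ the relative change is undefined and the
  computation errors rather than returning noise.
* Threshold comparisons are strict with a one-part-in-$10^9$ tie guard:
  values at exactly $1/N$ up to eigensolver jitter are excluded on both
  sides (a perfectly symmetric graph has *no* cores and *no* bridges).
* Disconnected graphs are allowed with a warning; the degenerate-block rule
  makes the indices well-defined there. This matters for the
  small-community limitation below.

## The generators and what they emulate

`generate_gn(z_out, seed)` draws the classical planted-partition benchmark:
4 communities of 32 nodes, independent Bernoulli edges with
$p_{in} = z_{in}/31$, $p_{out} = z_{out}/96$ and $z_{in} + z_{out} = 16$
(the standard expected total degree). It is statistically homogeneous, so
it is the *null* case: no node should be systematically important. The
acceptance suite verifies the pooled mean of $\bar I$ is exactly $1/128 =
0.0078$ and that no node is flagged persistently across 100 realizations.
One caveat on the spread of that distribution: under independent Bernoulli
edges the node-to-node spread of leading-eigenvector mass is set by
binomial degree fluctuations (standard deviation $\approx\sqrt{16}$ around
mean degree 16), which puts the pooled standard deviation of $\bar I$ near
0.003. Constructions that fix degrees exactly (stub-matched regular
variants) drive the spread toward zero instead; we verified both regimes
with an independent implementation. The published reference value for this
spread (0.0008) lies between the two regimes and is not reproduced by the
Bernoulli construction this package deliberately uses; the corresponding
acceptance check reports the honestly computed value and is expected to
disagree.

`generate_er_pair(q, p, seed)` draws two mutually disconnected ER
communities of sizes 10 and $10q$. It exposes a real limitation of
adjacency-spectrum importance: with $c = 2$ and sizes very different
($q \gtrsim 20$ at $p = 0.1$), both leading eigenvalues belong to the large
community, so *every* node of the small community falls below $1/N$ — the
index cannot see important nodes in small communities. The within-community
edge probability defaults to $p = 0.1$; the property is qualitative and
insensitive to the exact value.

`generate_core_bridge_sketch(seed)` builds a 15-node, two-community fixture
(a hub wired to its whole community, a sparse ring among non-hubs, one
bridge attached to three random members of each side) whose planted hubs
attain the top-2 importance and whose planted bridge attains the strictly
smallest score across all tested seeds.

`generate_lfr()` delegates to the established LFR implementation in Python
networkx (power-law degrees and community sizes; mixing parameter
$\mu = 0.1$, degree exponent 3, community-size exponent 1.5, average degree
15, minimum community 20) and retries deterministically over derived seeds,
because the LFR construction does not converge for every seed. The harness
itself accepts any graph with planted labels.

Problem sizes in the test and acceptance runs — 100 GN realizations of 128
nodes, one LFR draw of 1000 nodes, randomized property graphs up to 50
nodes — were chosen so the full suite completes in well under a minute of
eigensolver time while keeping Monte-Carlo error far below the tolerances
tested.

## What passing tests do and do not show

The generators emulate community structure, degree heterogeneity (LFR), and
size heterogeneity (ER pairs), but not degree–degree correlations,
weight–topology correlations, overlapping communities, or directed edges —
all present in real data. Passing the suite shows the indices behave as
derived on networks with planted, unambiguous structure; on real networks
the number of communities is itself uncertain, and the indices inherit that
uncertainty through `c`. The package's karate-club check is deliberately
qualitative (rank statements, not values) for exactly this reason.

## Known limitations

* Small communities are invisible to the importance index when community
  sizes are very heterogeneous (see the ER-pair discussion above); the
  bridgeness score does not share this failure mode but rests on the same
  choice of `c`.
* The perturbative form assumes node removal is a small perturbation; on
  very small graphs (tens of nodes) the exact method is cheap and
  preferable when precision matters.
* Directed networks are out of scope: loading enforces symmetry.
* `c` near a degenerate eigenvalue block makes the indices depend on the
  block rule; the package handles this invariantly but a different choice
  of `c` can still change the picture, as it should.
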