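---
title: "Gene co-targeting networks from bipartite miRNA–mRNA interaction lists"
author: "cernaNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene co-targeting networks from bipartite miRNA-mRNA interaction lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernaNet)
```

## The model

A validated miRNA–mRNA interaction list is a bipartite affiliation
network: two disjoint node classes (genes, miRNAs) with edges only between
classes. cernaNet's central object is the single-mode projection of that
network onto the gene class. Two genes are joined iff at least one miRNA
targets both, and the edge weight is the count of such shared targeting
miRNAs:

$$w(g_1, g_2) = \left|\{\, m : (g_1, m) \in E \;\wedge\; (g_2, m) \in E \,\}\right|.$$

The projection is computed as the sparse cross-product $B B^\top$ of the
biadjacency matrix $B$ (genes × miRNAs, via the Matrix package), with the
diagonal — each gene's intersection with itself — discarded. Self-loops
carry no co-targeting information, so discarding the diagonal is the only
sensible treatment. The weights satisfy an exact combinatorial identity
used as a cross-check everywhere in the test suite: a miRNA of degree $d$
creates $\binom{d}{2}$ co-targeted pairs, so

$$\sum_{\text{edges}} w = \sum_{m} \binom{\deg(m)}{2}.$$

Under the ceRNA (competing endogenous RNA) hypothesis, transcripts
sharing many targeting miRNAs compete for a common miRNA pool, so
high-weight cliques in the projection are candidate co-regulation
modules. The package ranks genes by **strength** (sum of incident edge
weights — total shared targeting interactions), extracts the induced
subnetwork of the top-$k$ genes, and scores topological brokerage with
**betweenness centrality**.

## Design choices in detail

**Isolated genes.** A gene with validated miRNA interactions but no
shared miRNA with any other gene keeps its node in the projection (degree
0). This keeps the projected node count equal to the bipartite gene
count, which is the natural bookkeeping for "network contains N genes"
statements; `projectToGenes(net, dropIsolated = TRUE)` removes them for
plotting.

**Ranking semantics.** "Genes with the highest number of shared targeting
miRNAs" is interpreted as projected node strength. Bipartite degree
(number of distinct targeting miRNAs) is exposed as an alternative
(`topGenesByShared(..., rankBy = "degree")`); in real targeting networks
the two rankings tend to coincide at the top, and observing that
coincidence is itself informative, so neither is hidden behind the other.

**Betweenness variants.** The default is unweighted shortest paths. The
weighted alternative uses edge length $1/w$: a naive use of $w$ as a
distance would make strongly co-targeted pairs *far apart*, which is
semantically inverted for affiliation weights. Both run Brandes'
single-source accumulation (BFS per source unweighted, Dijkstra for
inverse-weight lengths); undirected pairs are counted once (the halved
convention), and normalization divides by $(n-1)(n-2)/2$ with $n$ the
node count of the whole graph — matching the common library convention so
values are comparable across tools. Because the exact variant behind any
given published node-size figure is rarely stated, exact numeric
reproduction of third-party centrality rankings is not promised; the
correctness surface is equivalence with an exhaustive shortest-path
enumeration oracle at $10^{-9}$.

**Numerical notes.** Inverse-weight path lengths are floating sums, so
Dijkstra detects shortest-path ties within a relative tolerance of
$10^{-10}$; with integer weights up to the few hundreds seen in real
co-targeting networks, distinct path lengths differ by far more than
that. All rankings break ties by byte-order (C-locale) gene id, and node
sets preserve first-appearance order, so every output is reproducible for
a fixed input file regardless of locale.

**Identifier handling.** Surrounding whitespace is trimmed; case is never
folded (miRNA nomenclature is case-sensitive; `hsa-miR-16-5p` and a
hypothetical upper-cased variant must not merge). Header presence in
input CSVs is declared, never auto-detected — determinism over
convenience. Reading is lossless; redundancy removal (multiple
experimental validations of one pair) is the explicit, logged
`deduplicate()` step. An identifier appearing in both columns across a
file is a hard error, since it almost always means the columns are
swapped; `swapColumns = TRUE` handles that dialect.

## Styling parameters

`styleGraph()` reduces the "hairball" of dense projections:

| parameter | default | units | meaning |
|---|---|---|---|
| `edgeScale` | 0.03 | width units per shared miRNA | edge width = weight × scale; tune per network |
| `vmin`, `vmax` | 5, 30 | plot units | affine range for vertex size from betweenness |

Edge transparency is weight over the maximum weight, capped at 1, so the
strongest tie is fully opaque. When all betweenness values are equal the
affine rescale is degenerate and every vertex gets the midpoint size
$(v_{\min}+v_{\max})/2$. The styled attributes — `vertex_size`,
`betweenness`, `width`, `alpha`, `weight` — are written into GraphML, the
exchange contract; a rendered layout is engine- and seed-dependent and is
deliberately not part of it.

## What the synthetic generator emulates — and what it does not

`generateAdjacency()` produces seeded adjacency lists with the format and
gross structure of real validated-interaction exports: two node classes,
many-to-many links. Two models:

* **uniform**: every (gene, miRNA) link present independently with
  probability `p`;
* **planted-motif**: the uniform background plus a complete block in
  which `motifMirnas` miRNAs each target all `motifGenes` genes, so every
  motif gene pair shares at least `motifMirnas` miRNAs.

The planted block is deliberately complete: expected weights are then
analytic (background pair weight ≈ `nMirnas · p²`), and recovery of the
motif by `topGenesByShared()` is the end-to-end pipeline test — the
synthetic analogue of finding a tightly interlinked candidate ceRNA
module in a real network. The default test conditions (30 genes × 100
miRNAs, `p = 0.05` background, 5 × 40 motif) put the planted pairwise
weight (≥ 40) two orders of magnitude above the expected background pair
weight (≈ 0.25), so recovery is expected in every seeded run, and the
suite requires 25/25.

What the generator does **not** emulate: the heavy-tailed degree
distributions of real curated databases, nomenclature aliasing (miR-16
vs hsa-miR-16-5p), or literature-driven correlation between miRNA
families. Passing tests therefore demonstrate algorithmic correctness on
networks of realistic size and density, not robustness to curation
artifacts — those must be cleaned upstream of the adjacency list.

## Problem sizes and verification

The test suite verifies the projection against a brute-force pairwise
set-intersection oracle on 200 random fixtures of up to 50 genes, and
betweenness against exhaustive shortest-path enumeration
(Floyd–Warshall distances plus distance-pruned path enumeration, shared
code with nothing in the package) on 100 random graphs of up to 12 nodes,
in both distance modes. Subset–projection commutation — filtering the
adjacency list to a gene set and re-projecting equals inducing the
subgraph on the full projection, because pairwise shared-miRNA counts
never depend on which other genes are present — is checked on every
fixture. These sizes keep the whole suite under a minute while the
oracles remain tractable; the pipeline itself handles the
hundreds-of-genes scale of real curated networks in well under a second.

## Limitations

* Only the gene-side projection is implemented; a miRNA-side projection
  is a trivial extension but out of scope.
* Raw shared counts are the only weight scheme — no Jaccard or
  Newman-style normalization, which would change ranking semantics.
* Betweenness is exact, not sampled; for networks orders of magnitude
  larger than the curated lists this targets, approximate methods would
  be needed.
* Tripartite extensions (e.g. lncRNAs as a third class) are not
  supported.
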