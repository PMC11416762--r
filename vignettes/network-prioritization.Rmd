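---
title: "Neighborhood-similarity gene prioritization: model, conventions, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighborhood-similarity gene prioritization: model, conventions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`ppirank` implements guilt-by-association prioritization on a simple
undirected protein-protein interaction (PPI) graph $G(V, E)$: genes that
share many interaction partners with the members of a functional gene
set are candidates for sharing that function. The graph is simplified on
input — duplicate edges and self-loops removed — and all structure used
afterwards is the open neighborhood $N(v)$, the set of vertices adjacent
to $v$ excluding $v$ itself.

Three pairwise scores are computed for every gene pair:

$$J(A,B) = \frac{|N(A) \cap N(B)|}{|N(A) \cup N(B)|}, \qquad
SI(A,B) = \frac{2\,|N(A) \cap N(B)|}{|N(A)| + |N(B)|}, \qquad
S(A,B) = \frac{J + SI}{2}.$$

$J$ is the Jaccard index of the two neighborhoods, $SI$ the
Sorensen-Dice coefficient, and $S$ their arithmetic mean — the
"integrated" similarity used everywhere downstream. The two indices are
algebraically locked together ($SI = 2J/(1+J)$, hence $J \le SI$), which
the test suite exploits as an identity check on every computed pair.

Downstream of the matrix:

* **Seed scoring** (`rank_genes`): each gene's score is
  $\sum_{s \in \text{seed} \cap V,\ s \neq g} S(g, s)$ — the summed
  integrated similarity to the seed genes present in the network. Genes
  are ranked by descending score; seed genes are usually excluded from
  the reported ranking (`exclude_seed = TRUE`).
* **Permutation test** (`permutation_test`): the association of a query
  gene with a pathway is the mean $S$ to the pathway members, compared
  against the means for random gene sets of fixed size drawn uniformly
  without replacement from the network gene list.
* **Over-representation** (`ora`): hypergeometric upper-tail tests of a
  candidate list against annotation sets, Benjamini-Hochberg adjusted,
  significant at adjusted $p < 0.01$ by default.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `min_weight` (edge read) | none (0) | STRING-style confidence filtering is optional; the default keeps all edges because the full network is the reference analysis condition. |
| `neighborhood` | `"open"` | A vertex is not its own neighbor; direct adjacency alone contributes nothing, only shared partners do. A `"closed"` variant exists for diagnostics but is not the default. |
| scoring `metric` | `"combined"` | The integrated $S$; `jaccard`/`dice` alone are exposed for diagnostics. |
| `n_perm` | 10000 | Monte-Carlo resolution of the empirical p (floor $1/10001$). |
| `set_size` | 50 | Size of each random gene set; `"match"` draws sets matching the pathway's effective size instead. |
| `alpha` | 0.01 | BH-adjusted significance threshold for ORA. |
| `min_overlap` | 1 | Terms disjoint from the query are not reported. |

## Conventions and numerical choices

* **Degenerate pairs score 0, not NaN.** If two genes have no neighbors
  (empty union / zero total degree) all three scores are defined as 0 so
  the ranking stays total. The source formulas leave this case open;
  this is our documented choice.
* **Self term excluded from seed scores.** A seed gene's score counts
  its similarity to *other* seed genes only; otherwise every seed gene
  would receive a constant +1 (self-similarity) and distort the
  `exclude_seed = FALSE` ranking. Recorded in the output metadata.
* **Sparse support.** Only pairs with at least one shared neighbor are
  stored — exactly the vertex pairs at graph distance ≤ 2 with a common
  neighbor. Common-neighbor counts come from one sparse matrix product
  ($A^2$); an independent brute-force evaluator over all pairs serves as
  the oracle in the tests (agreement within 1e-12).
* **Ties break lexicographically** by gene symbol, so score tables and
  matrix files are byte-identical across reruns.
* **Empirical p uses the plus-one estimator**
  $p = (1 + \#\{\bar{s}_{null} \ge \bar{s}_{obs}\})/(1 + B)$ with a
  $\ge$ comparison: significance means the pathway similarity exceeds
  random gene sets, and $p$ can never be 0. The exact enumeration
  oracle applies the same conventions to the full subset count. Because
  the plus-one denominators differ (number of subsets vs number of
  Monte-Carlo draws), the two *reported* p's differ deterministically by
  up to $(1-q)/(C+1)$ on a pool with $C$ subsets; consistency between
  the two routes is therefore asserted on the tail *fractions*, which is
  what the binomial standard error describes.
* **Scores are ratios of exact integer counts** evaluated in double
  precision; all equivalence tests compare at 1e-12.
* **Sampling pool** for the permutation null is all network genes minus
  the query (the "whole gene list" reading); excluding the pathway genes
  from the pool is available as an option.
* **ORA universe** defaults to the caller-supplied background — in the
  pipeline, the network vertex set; term sizes are counted within that
  universe, and BH runs within one annotation collection at a time.

## What the synthetic generator emulates — and what it does not

`generate_planted_module_network` draws a planted-partition graph: every
pair inside a designated module gets an edge with probability `p_in`,
every other pair with `p_out` (`p_out <= p_in`; equality is the null
model used for calibration — the spec-level invariant is stated strictly
but the null calibration requires equality, so equality is allowed and
documented). Module members therefore share many neighbors, which is
precisely the signal the scoring assumes; part of each module is held
out of the seed list to measure ranking recovery.

The headline simulation condition (500 background genes, one module of
30 with 20 seeds and 10 held out, `p_in = 0.3`, `p_out = 0.02`) was
chosen as a sparse-but-cohesive regime: background mean degree ~10,
within-module degree ~9 on top — roughly the density contrast of a
well-annotated pathway inside a large PPI network, at a size that keeps
25 replicates within a CI budget.

What the generator does **not** reproduce: the heavy-tailed degree
distribution of real PPI networks (no degree correction by default),
edge-confidence structure, and the curated composition of real pathway
collections. A green recovery test therefore establishes that the
scoring recovers shared-neighbor cohesion — not that it reproduces any
database-specific gene list.

The 12-vertex permutation fixture (`inst/extdata/perm12_edges.tsv`) is a
frozen Erdos-Renyi draw selected so the query gene's 11 similarities are
positive and distinct and all 55 two-gene subset means are distinct.
That tie-free spectrum is a precondition of the null-uniformity check:
with heavy ties the $\ge$ comparison makes the empirical p
conservatively non-uniform by construction, which would test the
fixture, not the code.

## Design choices where the design was open

* Whether the source analysis thresholded STRING edges is unstated;
  `min_weight` defaults to 0 and is a CLI flag.
* Whether the seed sum ran over all seed genes or only those present in
  the network is unstated; we restrict to present genes and report the
  count used (`n_seed_used`).
* Random sets are drawn from the full network gene list minus the query;
  tie and zero conventions of the original are unstated, ours are above.
* Gene identifiers are opaque case-sensitive strings; an optional
  two-column mapping file translates protein ids to symbols, with
  re-simplification merging neighborhoods when ids collapse.
* Genes of a seed or pathway set absent from the network are dropped
  with a message, never an error.

## Known limitations

* Similarity is strictly first-neighbor: genes farther than distance 2
  from every seed gene score 0 and cannot be prioritized. No diffusion,
  random-walk, or Katz-style second-order similarity is implemented.
* The generator samples all vertex pairs (O(n²)); it is intended for
  networks up to a few thousand vertices, not genome-scale graphs.
* ORA has no ontology structure: no GO DAG propagation or redundancy
  trimming — terms are plain gene sets from a GMT file.
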