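---
title: "Methods: network discovery in candidate gene lists with linker genes"
author: "linkernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network discovery with linker genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkernet)
```

## The problem

A transcriptomic experiment typically ends in a list of differentially
expressed genes. The next question is structural: do some of these genes
form coherent molecular networks — modules of genes known to interact
genetically or physically? linkernet answers this against a curated
interaction database (for example, one exported from an organism database
for *C. elegans*), with statistical assessments of each reported network.

Two features define the method:

* **Evidence filtering.** Interactions that are only computationally
  predicted (e.g. transferred from orthologous interactions) and not
  experimentally confirmed are excluded before anything else happens.
* **Linker genes.** A key gene may be missing from the candidate list for
  purely technical reasons. Therefore two list genes are considered
  adjacent not only when a curated interaction joins them directly
  (*direct* edge), but also when a pair of interactions joins them through
  exactly one intermediate gene that is not on the list (*indirect* edge).
  The intermediate is called a *linker gene*. Chains of two or more
  consecutive non-list genes are never edges: the definition is exactly
  one linker.

## The basic graph and the search

Given the list L, the package builds the basic graph **G** = (V, E): V is
the set of list genes present in the database, and E holds the direct and
indirect edges defined above. Discovering networks is then close to
finding connected components — but components of well-studied gene sets
are often huge, so the search is bounded by an **iteration depth D**: from
a start gene, only nodes reachable in at most *d* steps are collected
(one direct *or* indirect edge = one step).

For each depth *d* = D, D−1, …, 1 the search walks the candidate list in
its input order. For each list gene not yet absorbed into a network in the
current depth pass it collects the *d*-neighbours and expands them into a
reported network **N**: each indirect edge is replaced by its two database
legs plus a new node for the linker gene. A network is emitted if it
contains at least `minListGenes` list genes (default 2) and its exact node
set has not been emitted before; lower depths therefore contribute only
genuinely smaller networks. Emitting at every depth intentionally reports
overlapping networks of decreasing complexity rather than a single
partition.

Two details of the iteration were genuinely open and are fixed here as
package policy:

* *Consumption.* "Remaining genes of the list" is read as: all list genes
  absorbed into a network during the current depth pass are skipped as
  start genes for that pass; consumption resets between passes, and exact
  duplicate node sets are suppressed globally. This keeps start-gene
  coverage while avoiding repeats.
* *Sub-networks.* A network found at *d* < D that is a strict subset of a
  larger one is still reported unless its node set is an exact duplicate —
  overlapping results are part of the method's output style.

## Statistics

Each network is assessed from two independent angles.

**Network score.** The score of **N** is the mean number of distinct
publications supporting its edges — strength of experimental evidence.
Citations per edge are counted as *distinct* publication identifiers after
merging duplicate database records; this is the defensible reading of
"described in only one publication" styling and makes the count invariant
to how rows were split in the input.

**Score p-value.** The observed score is compared with the scores of
`nSim` randomly simulated networks; the p-value is the fraction of
simulated scores at least as large as the observed one. What exactly a
"randomly simulated network" is was open; the package's default null draws
|E(N)| edges uniformly without replacement from the database's
experimental edge set and scores them. This preserves the only quantity
the score depends on (the edge count), makes the null exactly enumerable
on small databases (which the test suite exploits), and matches the
reading that simulated *scores*, not topologies, are resampled. A
connectivity-preserving variant — growing a random connected edge set of
the same size — is available via `scorePvalue(..., method = "connected")`
but is not the default. The estimator is the literal fraction and can
return 0; `addOne = TRUE` gives the (hits+1)/(nSim+1) correction. With the
default `nSim = 10000`, the smallest nonzero p-value is 0.0001, and
reports render smaller values as `<0.0001`.

**List p-value.** The induced sub-network **N¹** contains every database
gene at distance one from any node of **N**, together with **N**'s own
nodes (a member of a connected network is a 1-neighbour of its partner;
`includeNetwork = FALSE` exposes the exclusive variant). **N¹** is
computed on the *full* database graph, not the list-restricted graph,
because the null hypothesis compares the list against the entire gene
universe. Under the null that list membership is unrelated to **N¹**, the
overlap k = |N¹ ∩ L| is hypergeometric with parameters N (universe size),
|N¹| and |L|:

$$ f(k) = \frac{\binom{N-|N^1|}{|L|-k}\binom{|N^1|}{k}}{\binom{N}{|L|}},
\qquad p = \sum_{\tilde k = k}^{n} f(\tilde k), $$

with the tail's upper limit n = min(|N¹|, |L|) — the only choice for
which the sum covers the support. The universe N defaults to the number of
genes in the database and should be overridden with a genome-wide count
(`universeSize`) when the database covers only part of the genome; the
implementation uses `stats::dhyper`, and the tests check it against
exhaustive subset enumeration.

Reported tables give raw p-values per network; Benjamini–Hochberg adjusted
columns are appended as a clearly labeled extension, since multiple
networks are tested.

**Sorting.** Networks are sorted by score (descending); ties break by
list p-value (ascending), node count (descending), then lexicographically
smallest gene — a deterministic total order.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `maxDepth` (D) | 2 | steps allowed from a start gene; published analyses of dense lists often use 1 |
| `minListGenes` | 2 | smallest number of list genes per reported network |
| `nSim` | 10000 | permutation draws; 0 skips the score test |
| `seed` | — | mandatory; all randomness flows from it |
| `universeSize` | database gene count | enrichment universe N |
| `keepPredicted` | FALSE | retain predicted-only interactions |
| `alpha` | 0.01 | report significance threshold |

Identifier matching is exact after whitespace stripping; `caseFold = TRUE`
lower-cases identifiers, off by default because silent case-folding can
merge distinct loci. Self-interactions are dropped (they cannot join two
list genes and distort neighbourhood sizes); edges are undirected because
the method never uses direction. Genetic and physical interactions are
treated identically — the class is kept as metadata only — as nothing in
the scoring or search distinguishes them.

## The synthetic-data generator

`generateDatabase()` emulates a curated interactome as an Erdős–Rényi
background whose per-edge citation counts come from a chosen regime:
`constant`, `geometric` (1 + geometric, exact mean), or the default
`two_point` (citations 1 with probability 0.95, else 135) which mimics the
empirical pattern of curated databases — most interactions reported once,
a few canonical ones reported very many times. Publications are
materialized as synthetic identifiers so that citation counts always equal
publication-set sizes. `plantNetwork()` inserts path/star/clique motifs on
fresh gene identifiers with boosted citations and records the exact
expected network; `generateList()` builds candidate lists that contain the
planted list genes and never the planted linkers.

What the generator does *not* emulate: the heavy-tailed degree
distribution of real interactomes, correlated annotation depth (well-known
genes have both more edges and more citations), and identifier noise.
Passing tests therefore demonstrate algorithmic correctness and
calibration under idealized sampling, not robustness to curation biases of
any particular database release.

Study sizes used by the test suite were chosen as the smallest instances
that still exercise every code path meaningfully: oracle equivalence on
200 random graphs of ≤ 12 genes (exhaustive brute force stays exact),
permutation-null checks on ≤ 8-edge databases (enumerable), planted
recovery on 100 replicates of a 40-gene background with citation boost 10
(boosted motifs score ≥ 11 against a unit background, so recovery failure
would indicate a search defect, not noise), and null calibration over
1000 analyses of 120-gene databases with 15-gene uniform lists. For the
calibration bound, note that discovered networks are *selected* for
containing ≥ 2 list genes, so their enrichment p-values are not uniform;
with mean degree ≈ 5 the typical 2-member network has |N¹| ≈ 11 and
P(k ≥ 2) ≈ 0.4 under the null, keeping the fraction below 0.01 small.

## Numerical and degenerate-input policy

* Scores are means of integer citation counts; comparisons in the
  permutation test use plain `>=` on identically computed means.
* Report rendering rounds half away from zero (scores to 2 decimals,
  p-values to 4); internal values keep full precision, and the JSON
  report serializes full precision.
* A gene list with no database matches yields an empty graph with a
  warning, not an error; a single-gene list yields no networks.
* An empty edge set makes the network score undefined (error), and a
  database smaller than the network's edge count cannot be simulated
  (error).
* DOT, TSV and JSON outputs order nodes and edges byte-stably
  (C-locale radix sort), so identical configurations give identical
  bytes; timestamps are confined to `run.log`.

## Worked example

The shipped fixture is a six-gene neighbourhood of the *C. elegans*
insulin/IGF-signalling hub *daf-16*: five unit-citation edges and one
edge (*daf-16*–*daf-2*) supported by 135 publications. *daf-2* is absent
from the candidate list and enters the network as a linker. The exact
wiring of the unit edges is one admissible synthetic layout (the score
depends only on the citation multiset).

```{r example}
db <- buildInteractionDb(filterExperimental(
  readInteractionTable(iisExample()$db)))
gl <- readGeneList(iisExample()$genes)
an <- analyzeNetworks(db, gl, searchConfig(maxDepth = 1, seed = 1))
resultTable(an)[, c("rank", "genes", "nodes", "edges", "score")]
```

One network: 6 nodes, 6 edges, score (135 + 5·1)/6 = 23.33. Its score
p-value against this six-edge database is 1 by construction (every
six-edge draw is the whole database); against a realistically sized
database the same network scores far in the null's tail.

## Known limitations

* The permutation null resamples edges without preserving topology;
  degree-preserving randomization is out of scope.
* Raw p-values are reported per network as the primary output; the BH
  columns mitigate but do not model the strong overlap between reported
  networks.
* Citation counts measure attention as much as evidence; the score
  favours well-studied interactions by design.
* Linker genes are limited to one per indirect connection by definition;
  paths through two unlisted genes are invisible to the method.
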