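---
title: "Methods: semantic disease maps, cluster stability, and phenotype search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantic disease maps, cluster stability, and phenotype search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdmap)
```

This vignette is the package's account of its methods: the distance model
and its assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator does and does not emulate, and
the numerical and design choices made where the design was genuinely open.

## The distance model

### Term distance on an ontology DAG

Phenotype and gene-function vocabularies (HPO, GO) are rooted DAGs whose
terms link to parents by "is a" edges. The package's elementary distance
between two terms is the *common-ancestor-path* distance

$$\mathrm{Dist}_p(p_1,p_2) = \frac{\min_a \left(d(p_1\!\to\!a) + d(p_2\!\to\!a)\right)}{d_{\max}},$$

the minimum over shared ancestors $a$ of the two shortest climb lengths,
normalized by the ontology constant $d_{\max}$. Two points matter:

* **Routes are restricted to common ancestors.** A generic undirected
  shortest path could descend through a shared *child*; that would make two
  unrelated terms with one overly specific common descendant look similar.
  Climbing only is the conservative semantic reading.
* **Climb lengths are shortest paths.** Terms can have several parents; the
  minimum in the formula governs both summands.

Terms in different connected components (multi-root ontologies) have no
common ancestor; their distance is defined as 1, preserving the $[0,1]$
codomain. An alternative id (`alt_id`) resolves to its canonical term;
obsolete terms are rejected in queries with a clear error.

### The normalization constant $d_{\max}$

Two modes are provided. `exact` is the maximum common-ancestor-path
distance over all term pairs, computed by a min-plus product over the
ancestor incidence matrix; it is quadratic in the number of terms and is
the mode used throughout the tests, where DAGs have at most a few hundred
terms. `depth_bound` returns $2\times$ the maximum depth — an upper bound
reached when two deepest terms meet only at a root — and is the default for
real ontologies with tens of thousands of terms, where the exact all-pairs
computation is not worth its cost. The mode in effect is recorded on the
ontology and in every serialized output, because absolute similarity
scores (not ranks) scale with it.

### Disease distances

A disease is a set of phenotype terms with frequency weights
$w \in [0,1]$. The phenotype distance between diseases is the symmetric
two-way weighted best-match average: every term of one disease is matched
to its nearest term in the other, matched distances are multiplied by the
product of the two terms' weights, each direction is averaged over its own
term count, and the two directions are averaged. The gene-side disease
distance is the unweighted analogue over pathogenic gene lists, where the
gene-gene distance averages per-aspect best-match term distances over the
three GO aspects (cc, mf, bp).

Three conventions resolve ambiguities the formulas leave open:

* **The matched-side weight** is that of the term attaining the minimum
  distance; ties in the minimum break toward the *larger* weight, so the
  weighting reflects the most clinically typical match and the result is
  deterministic.
* **Aspect distance between term sets** uses the best match (minimum over
  cross-pairs); a best-match-average variant is available
  (`aspect_method = "bma"`). A gene lacking an aspect contributes 1 for
  that aspect — dropping the aspect silently would make unannotated genes
  look universally similar.
* **Weighted distances are implemented exactly as the formula reads**:
  small weights deflate contributions. This has a real consequence for
  search (below).

These best-match averages are *not* metrics: a "hub" disease annotated
with both of two distant terms sits close to each of the single-term
diseases while those remain maximally distant (a pinned test documents
`0.25 + 0.25 < 1` on a toy DAG). This is expected and is why the map step
reports how non-Euclidean its input was.

## Map construction

The all-pairs distance matrix (diseases ordered by id, so the matrix is
reproducible regardless of input order) is embedded by classical Torgerson
scaling: double-center the squared distances, eigendecompose, scale the top
two eigenvectors. Because the distances violate the triangle inequality,
negative eigenvalues always appear; they are clamped to zero — standard
classical-scaling practice — and their share of the total absolute
eigenvalue mass is reported as a map-quality metric (typically ~0.25 on
synthetic knowledge bases). Eigenvalues at numerical noise level (below
$10^{-8}$ of the leading one) are treated as zero; if the requested
dimensionality exceeds the effective rank, the surplus coordinates are
zeroed with a warning rather than filled with noise.

### Choosing the number of clusters

The 2-D embedding is partitioned by seeded k-means (best of `restarts`
random starts; default 10). For each candidate $k$, stability is estimated
by bootstrap: resample the points, re-cluster, assign every original point
to its nearest bootstrap centroid, and record each original cluster's
maximal Jaccard overlap with the induced clusters; its stability is the
mean over `B` resamples (default 20). The selected $k$ is the **largest
candidate whose least stable cluster reaches the threshold**, falling back
(and flagged `"fallback"`) to the $k$ with the best mean stability when
none qualifies.

The stability threshold defaults to **0.8**. This was calibrated against
the behavior the rule is supposed to produce, on data where the truth is
known: on three well-separated Gaussian blobs, arbitrary k-means splits of
one blob retain a mean maximal Jaccard of roughly 0.56–0.74 across seeds
(the optimal 2-split of a fixed finite point cloud is partially
reproducible under resampling), so a threshold of 0.6 accepts $k=5$ or 6;
and on a single diffuse blob every candidate $k$ clears 0.6, so the
fallback path would never trigger. At 0.8 — consistent with the
cluster-stability literature's reading of max-Jaccard values below ~0.75
as dissolved clusters — planted structure is selected exactly and null
structure falls through to the fallback, robustly across seeds. The
threshold remains a parameter for users who prefer a laxer or stricter
regime. Clustering operates on the 2-D coordinates (the object being
partitioned *is* the map); clustering on the full distance matrix via
medoids is deliberately not implemented.

One master seed fans out to per-stage seeds (per-$k$, per-replicate), so
runs are bit-reproducible and every stochastic output records its seed.

## Search

The default score ("Similarity") is **one-way, query → disease**: each
query term is matched to its nearest disease term and the matched
distances (times the matched term's frequency weight; query terms carry
weight 1) are averaged over the query. One-way scoring never penalizes
annotations the clinician did not mention — the right behavior for
incomplete queries, and the variant that proves more stable under
imprecision in the benchmark. "Similarity-Avg" is the symmetric two-way
variant; "Jaccard" is the direct term-overlap baseline, converted to a
distance $1-J$ so every method sorts ascending. Ranks are tie-aware:
$1 + $ the number of *strictly* smaller scores, so a target tied with
others but with none better ranks 1.

**Frequency weighting in search is a flag** (`weighted`). Search defaults
to weighted scores, matching the disease-distance convention. The in
silico benchmark, however, defaults to unweighted scores: the weight
multiplies the matched distance *after* the argmin, so an unrelated
disease whose nearest annotation happens to be a low-frequency term gets
its score deflated and can overtake the true target once the query is
imprecise. The benchmark's purpose is to isolate semantic versus lexical
matching, so it excludes that separate effect; both behaviors are
available through the flag.

## Evaluation protocols

**In silico imprecision benchmark.** Target diseases are sampled uniformly
among those with at least `terms_per_query` phenotypes (default 4). Each
target's query is its `terms_per_query` highest-weight terms (ties broken
by term id), degraded to each imprecision level by replacing a uniform
random subset of terms with a uniformly chosen *graph-adjacent* term —
parent or child, the candidate pool being their union with no double
weighting of parents; replacements never equal the original. The same
degraded query feeds every method, so comparisons are paired. The report
gives, per level and method, the fraction of targets ranked 1, the
fraction in the top 10, and the mean rank — the performance metric is
deliberately reported in all three forms rather than committing to one.

**Case harness.** A case is an external target reference (e.g. an OMIM id,
resolved through knowledge-base xrefs) plus a curated phenotype query; the
harness records each target's tie-aware rank and score, reports unresolved
targets as a count rather than an error, and keeps any reference
rank/score columns side-by-side for comparison. The package ships the 20
published rare-disease case reports used to evaluate the public RDmap,
with the ranks and scores that deployment reported. Reproducing those
numbers requires the same 2019-era Orphanet/HPO snapshot (and they are
sensitive to the frequency-weighting flag and the $d_{\max}$ mode), so the
package's tests exercise the harness end-to-end on synthetic knowledge
bases and verify the shipped table's internal consistency instead of
asserting the historical values.

## The synthetic-data generator

Every test runs on fixtures generated in code with known ground truth.

* **DAGs**: single root; each new term attaches to 1–`max_parents`
  existing terms with probability weighted by $(\text{depth}+1)^2$, which
  produces deep ontologies like HPO/GO rather than the log-depth graphs
  uniform attachment gives. Acyclicity is guaranteed by construction and
  re-validated on load.
* **Knowledge bases**: diseases draw `terms_per_disease` (default 8)
  phenotype terms; frequency classes are drawn as
  Obligate/Very frequent/Frequent/Occasional/Very rare with probabilities
  0.10/0.45/0.35/0.07/0.03 — real Orphanet annotations are predominantly
  frequent — and "Excluded" is never drawn at random (a disease whose
  weights are all zero is distance-0 to everything by the formula, so such
  diseases are flagged and left off maps). Genes draw per-aspect GO terms
  analogously.
* **Planted clusters**: cluster anchors are deep terms chosen greedily to
  maximize their minimum pairwise distance; each cluster's diseases sample
  terms from the anchor's radius-1 graph neighborhood (radius grows only
  if the pool is too small). Tight neighborhoods around well-separated
  anchors give within-cluster distances of a couple of edges against
  near-maximal between-cluster distances, which is the regime where map +
  k-means recovery can be asserted (≥95% label agreement under best label
  matching, computed by exhaustive permutation search — fine for $k\le 8$).
* **Manifests** record the seed, every assignment, and true memberships;
  regenerating with the same seed is byte-identical, and written
  OBO/TSV/XML round-trip through the package's own loaders.

What the generator does **not** emulate: the term-frequency and
annotation-size marginals of real Orphanet/HPO data, prevalence-class
marginals, obsolete-term churn, or cross-ontology xref noise. Passing
tests therefore demonstrate the correctness and the qualitative behavior
of the algorithms (degradation orderings, recovery in separable regimes),
not clinical performance on real data.

## Numerical choices and degenerate inputs

* Distance computations use a cached min-plus product over the ancestor
  incidence matrix for ontologies up to 3000 terms (all test fixtures);
  larger ontologies fall back to per-query cross products.
* A single-term ontology has $d_{\max}=0$; the normalized distance is
  undefined and guarded (0 for identical ids, 1 otherwise), with a warning
  at construction.
* All-zero distance matrices embed at the origin with a warning.
* Frequency labels accept full bands ("Frequent (79-30%)"), bare names
  ("frequent"), or numeric fractions; the class→weight table is the band
  midpoints (1.0, 0.895, 0.545, 0.17, 0.02, 0) and is configurable, since
  the numeric reading of the classes is a modeling choice that absolute
  scores are sensitive to.
* Duplicate phenotype rows keep the first occurrence with a warning;
  unresolvable terms are dropped with a logged count rather than failing
  the whole load.

## Problem sizes

The test suite and the acceptance script run on 60-disease knowledge bases
over 200-term DAGs (oracle-equivalence checks use 10–50-term DAGs where
exhaustive enumeration is cheap), 10-point clouds for scaling fidelity,
B = 20 bootstrap replicates, and 5–10 seeded benchmark replicates. These
sizes were chosen so every property is exercised well inside a minute or
two while remaining in the regime the method targets (thousands of
diseases would change nothing structurally — the matrices just grow).

## Known limitations

* Only "is a" edges are used; GO "part of" relations are ignored.
* No information-content (Resnik/Lin-style) weighting of terms; the
  distance treats all edges equally, so dense shallow regions of an
  ontology look artificially tight.
* The published deployment's absolute cluster counts and scores depend on
  its 2019 data snapshot and unknown bootstrap settings and are not
  reproduction targets here.
* Weighted best-match distances are not metrics; the 2-D map is a lossy
  view and should be read together with its negative-eigenvalue mass.
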