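---
title: "Scoring drug-target associations on semantic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring drug-target associations on semantic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A drug and a protein target that do not (yet) share a known interaction may
still be related through their neighborhood in a heterogeneous network:
the drug binds a protein that shares a GO annotation with the target, the
drug shares a substructure with a known ligand of the target, and so on.
`slapr` scores such indirect evidence. Its input is a typed undirected
network whose nodes are instances of classes (compounds, targets, GO terms,
pathways, substructures, tissues, side effects, diseases, ...) and whose
edges carry relation types (`bind`, `express`, `hasGO`, `hasPathway`,
`hasSubstructure`, `PPI`, ...); its output is, for any node pair, an
association score with a p-value, built from the paths that join the pair.

## The model

**Paths and patterns.** All simple paths between the pair with at most
`max_length` edges are enumerated (default 3; path counts grow explosively
with the bound, and evidence mediated by more than two intermediates is
weak). The *pattern* (meta-path) of a path is the alternating sequence of
node classes and edge types along it, read from the query end, e.g.
`Compound|bind|Target|hasGO|GOTerm|hasGO|Target`. Paths with the same
pattern carry the same kind of evidence.

**Raw score.** Traversal is modelled as a random walk that, leaving node
$v$ along an edge of type $t$, picks uniformly among the $d_t(v)$ neighbors
of $v$ within that type, so each step has probability $1/d_t(v)$. Step
probabilities multiply along a path and the natural logarithm is taken;
because the graph is undirected the raw score of a path is the average of
the forward and backward log-probabilities,

$$\mathrm{raw}(p) = -\tfrac{1}{2}\sum_{i}\left[\log d_{t_i}(v_i) +
\log d_{t_i}(v_{i+1})\right] \le 0 .$$

The score is 0 exactly when every step in both directions is forced
(degree 1): maximally specific evidence. Routes through hubs are penalized.
The choice of logarithm base is immaterial: rescaling the raw scores of a
pattern by a constant leaves every z score below unchanged.

**Pattern z-normalization.** Raw scores are not comparable across patterns
(a three-step pattern through annotation hubs is systematically more
negative than a one-step pattern), so each path's raw score is standardized
within its pattern: a sample of `n_pairs` random source-target pairs is
drawn, all their paths scored, and each pattern's scores fitted to a normal
distribution with mean $\mu$ and standard deviation $\sigma$; a path then
gets $z = (\mathrm{raw}-\mu)/\sigma$. Because random-pair paths reach a
node with probability proportional to its degree, the sample is
hub-enriched, and a genuinely specific path lands in the upper tail of its
pattern's distribution.

**Validity and the association score.** A path is *valid* when $z > 0$ and
its pattern is both usable (at least `min_pattern_n = 30` sampled paths and
$\sigma > 10^{-9}$; thinner fits are unreliable and contribute nothing) and
informative (below). The association score of a pair is the sum of its
valid paths' z scores, 0 when no valid path exists. More evidence and more
specific evidence both increase the score.

**Informative patterns.** Not every pattern helps: some edge types connect
nodes essentially at random. Each pattern is assessed as a standalone
predictor by summing, per pair, the raw scores of the pair's matching paths
on a benchmark of known positives and random decoys, and computing the
AUROC of the resulting ranking. Because the pattern score is a sum of
log-probabilities, its *magnitude* grows with the amount of matching
evidence, and a pair with no matching path has no evidence at all; the
ranking therefore uses the magnitude, with 0 (no path) the weakest value.
A pattern is removed only when its AUROC stays at or below
`pattern_threshold` on *every* supplied benchmark (removal requires
agreement; one benchmark is built automatically from the positives and
seeded decoys, a second may be supplied). The default threshold 0.55 sits
between chance-level patterns (about 0.5) and the clearly useful ones
(0.62 and up in our fits); it is a configuration knob.

**Null model and p-values.** The association scores of random pairs,
restricted to the strictly positive ones (zero scores carry no logarithm;
their count is recorded and their p-value is defined as 1), have
approximately log-normally distributed scores. A normal distribution is
fitted to the log scores of `n_null` random pairs by sample mean and
standard deviation; the p-value of a score is the fitted upper-tail
probability, and `significance_threshold(null, alpha)` inverts it exactly.

**Direct-link exclusion.** When scoring known pairs (benchmarking, missing
link recovery), every path that traverses a direct edge between the two
nodes is removed first — not just the one-edge path, so longer paths
re-using the direct edge are excluded too. The score then reflects
neighborhood evidence only.

## Polypharmacology profiles

Scoring one drug against a target panel gives its profile; profiles are
compared by Pearson correlation. `filter_matrix()` drops drugs/targets
whose best score is below `significance_threshold(null, alpha = 0.05)`
(repeated to a fixed point, making the operation idempotent), so that each
retained drug has at least one significant target and vice versa.
Zero-variance profiles have undefined correlation and propagate as missing
values, never as 0. Drug pairs with correlation at or above 0.75 (the
default cut-off) form the similarity network; isolated drugs are retained
so unclustered compounds stay visible.

## The synthetic test-bed

Real semantic networks are built from database snapshots and are far too
large (and too entangled with licensing) to ship in a package, so all
validation runs on seeded synthetic networks from `synth_config()` /
`synth_generate()`. The generator emulates the *structure* of a semantic
drug-target network at desk scale:

* eight populated node classes with default counts 60 compounds, 60
  targets, 40 GO terms, 25 pathways, 50 substructures, 12 tissues, 30 side
  effects, 10 diseases;
* background edges per type at mean degrees (per node of the first class)
  bind 4, express 1.5, hasGO 4, hasPathway 2, hasTissue 2, PPI 2.5,
  hasSubstructure 4, hasSideEffect 2, treats 0.5 — a typical
  compound-target pair is joined by tens of length-3 paths, so path counts
  alone carry little signal and discrimination must come from specificity,
  the regime the method is designed for;
* endpoints sampled with a Zipf-like weight of exponent `degree_skew = 1.1`
  by default, giving the heavy-tailed degree distributions of real chem-bio
  networks. `degree_skew = 0` gives uniform Erdős–Rényi backgrounds; we
  made the skewed variant the default because under uniform backgrounds at
  this scale the planted routes dominate per-pair path counts, making
  count-based baselines artificially strong and raw-score sums artificially
  anti-predictive — neither of which happens at realistic scale;
* 40 planted positive pairs, each wired with `strength = 3` indirect
  evidence routes drawn from the three informative mechanisms (shared
  ligand, shared GO term, shared substructure). The direct drug-target edge
  is *not* added (so tests probe missing-link recovery; `add_direct = TRUE`
  adds it), and background `bind`/`express` edges never join a planted
  pair.

`synth_profile_groups()` builds the clustering test-bed: disjoint drug
groups (default 6 drugs each) are wired to disjoint target sets (default 8
targets) through *group-shared* evidence channels — an anchor scaffold
substructure, anchor ligands and anchor GO annotations shared by the whole
group, the way a real drug class shares them. Six channels per group (two
per mechanism) are the default: enough shared evidence that within-class
pairs clear the profile significance filter at $\alpha = 0.05$. An early
design that planted independent routes per pair instead turned every group
drug into an unspecific hub and produced flat profiles; shared channels
are both more realistic and actually informative.

What the generator does **not** emulate: correlated annotations (real GO
terms are hierarchically related), multi-class membership, edge weights
(binding affinities enter only as an optional load-time cutoff), and the
sheer scale of real networks (hundreds of thousands of nodes, hundreds to
thousands of paths per pair). Passing tests on this test-bed show that the
statistics do what they claim under the model's assumptions, not that any
particular biological prediction is correct.

## Numerical and design choices

* Natural logarithms throughout; harmless by the base-invariance property.
* Path enumeration is complete within the length bound (not only shortest
  paths) and its output order is deterministic — sorted by length, then
  pattern signature, then node ids — so downstream floating-point sums are
  bit-for-bit reproducible.
* All AUROCs use the rank-based (Mann–Whitney) statistic with ties counted
  1/2, shared by every evaluation path in the package; ROC curves computed
  by threshold sweep integrate to exactly that value.
* Random pair samples are uniform without replacement over the declared
  source × target pools minus known positives; every sampling step takes an
  explicit seed and restores the caller's RNG state.
* In the decoy-ratio experiment the decoy sets are nested across ratios,
  which couples the runs: recall thresholds depend only on the positives,
  so precision at fixed recall responds to class imbalance alone.
* Zero association scores are excluded from the null fit and given
  p-value 1; degenerate fits (zero spread) are errors, not silent NaNs.
* A fitted model serializes to versioned JSON (pattern statistics, pattern
  report, informative set, null fit, pools, configuration, seeds). The
  graph is not serialized; scoring a deserialized model takes the graph as
  an argument.

## Problem sizes used by the test suite

The packaged tests fit models with 1,200–3,000 random pairs for pattern
statistics, 300–1,000 random pairs for the null, benchmarks of 40 planted
positives against 1–12× decoys, and 10-seed replicates for every
stochastic claim; these sizes keep each pattern's fit well above the
usability floor on the default network while completing in minutes on one
CPU. The pattern-selection stability check uses a larger bundle (100
compounds × 100 targets, 150 planted pairs) because deciding that a
chance-level pattern stays below a 0.55 AUROC threshold in every replicate
needs benchmark resolution well under the 0.05 gap between chance and the
threshold. The acceptance script reruns the same pipeline end to end at a single
user-supplied seed.

## Known limitations

* The log-normal null is an approximation. On sparse or strongly
  heavy-tailed networks, random pairs whose only valid paths have z barely
  above zero produce association scores near 0 whose logs form a long left
  tail; the fitted normal then mis-covers the extreme quantiles, and
  uniformity checks of null p-values can fail at tight tolerances even
  when the implementation is exact. The packaged calibration test computes
  a Kolmogorov–Smirnov statistic against uniformity and documents this
  sensitivity; at real-network densities (many valid paths per pair) the
  approximation is much better behaved.
* The per-pattern normal fit is likewise an approximation; patterns with
  few sampled paths are excluded by the usability gate rather than
  modelled.
* Scores are built from categorical relations only. Binding affinities,
  interaction signs (agonist/antagonist) and edge weights are not part of
  the traversal model beyond the optional load-time affinity cutoff.
* Like any neighborhood method, the score cannot distinguish "no relation"
  from "no data": absent edges lower scores regardless of why they are
  absent.
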