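---
title: "Quantifying cytonuclear discordance with tree-set concordance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cytonuclear discordance with tree-set concordance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytonuclear)
```

## The problem

Mitochondrial genomes and nuclear loci can record genuinely different
evolutionary histories. In rapid radiations — *Myotis* bats are the
motivating case — short internal branches leave ancestral polymorphism
unsorted (incomplete lineage sorting, ILS), and hybridization can move a
mitochondrial genome wholesale across species boundaries. A single "best"
tree from either marker class then badly misrepresents the uncertainty. The
approach implemented here instead generates *many* defensible trees per
marker class (by varying matrix construction and estimation settings),
treats the resulting tree sets as the object of study, and asks whether the
classes occupy distinct regions of tree space.

`cytonuclear` implements that workflow end to end:

1. **Bipartition algebra** — splits, compatibility, unweighted
   Robinson–Foulds (RF) distances, strict majority-rule consensus with
   bipartition frequencies, and a topology census (equivalence classes at
   RF = 0).
2. **Tree space** — pairwise RF matrices, within/between marker-group
   summary statistics, classical metric MDS, hexagonal binning.
3. **Quartet concordance** — normalized quartet scores of a species tree
   against gene-tree sets by exhaustive enumeration.
4. **Matrix regimes** — completeness thresholds, length bins, random
   subsamples; concatenation with per-locus character sets and
   parsimony-informativeness accounting.
5. **Statistical binning** — support-filtered gene trees packed into
   balanced, pairwise-compatible supergene bins, with weighted and
   unweighted supergene-tree multisets.
6. **A transparent estimator** — Jukes–Cantor distances + neighbor joining
   with nonparametric bootstrap, and an average-internode-distance species
   tree summary (the ASTRID/NJst family).
7. **A synthetic-data generator** — multispecies-coalescent gene trees over
   a Yule species tree, a mitochondrial-like locus with reduced effective
   size and optional introgression, sequence simulation, and per-locus
   taxon missingness.

## Canonical forms and the split algebra

All cross-tree comparisons operate on unrooted, metadata-stripped trees:
branch lengths mean different things across estimators (substitutions,
coalescent units, nothing), so only topology is compared. A bipartition is
canonicalized to the side *not* containing the reference taxon (the
lexicographically smallest label). Under that convention two compatible
splits are always nested or disjoint, so any pairwise-compatible split set
is a laminar family and assembles into a tree by simple nesting — this is
how consensus trees are built, and it yields a canonical newick form
(children ordered by smallest descendant label) used for census keys and
deterministic output.

Design choices worth knowing:

* **RF distance** is the raw symmetric-difference count (no normalization),
  matching how "symmetrical differences" are usually reported. Trees with
  different leaf sets are restricted to shared taxa first (≥ 4 required).
  Polytomous trees are compared by the same rule; their split sets are just
  smaller.
* **Consensus threshold** is *strictly greater than* 0.5 by default.
  A split at exactly 50% is dropped; this guarantees the retained set is
  pairwise compatible without tie-breaking.
* **Census** membership requires the full shared taxon set — topology
  identity is undefined across different leaf sets, so trees with missing
  taxa are excluded and reported.
* **Newick dialect**: internal node labels are carried through and
  interpreted as bootstrap-style supports where numeric; negative branch
  lengths are rejected at parse, zero lengths allowed.

## Tree space

`embed_cmds()` is classical (Torgerson) metric MDS: double-centering of
squared distances and a top-\(d\) spectral decomposition, with a fixed sign
convention (the largest-magnitude coordinate on each axis is positive) so
results are fully deterministic. RF matrices are generally non-Euclidean;
negative eigenvalues are truncated and their total magnitude reported next
to the stress
\(\sqrt{\sum (\hat d_{ij} - d_{ij})^2 / \sum d_{ij}^2}\).
A nonlinear stochastic embedding could be substituted here, but the
scientific conclusion rests only on cluster separation, which a metric
embedding preserves; determinism and transparency won. `hexbin_counts()`
provides the density view over the embedding without any plotting
dependency.

The group summary reports mean within-class and between-class RF, the
minimum between-class distance, and counts of pairs *strictly* exceeding a
cutoff — the statistics that make "nuclear and mitochondrial trees occupy
distinct regions" precise: both within-class means well below the
between-class mean, and a strictly positive minimum between classes.

## Quartet concordance

The quartet topology induced by a tree on four taxa is read off the
four-point condition applied to topological (unit-edge) leaf-to-leaf
distances: the pairing with the strictly smallest distance sum is the
induced split; a three-way tie means the restriction is a star. The
normalized quartet score of a species tree \(S\) against gene trees
\(G_1,\dots,G_m\) is

\[
Q = \frac{\sum_i \#\{\text{resolved quartets of } G_i \text{ agreeing with } S\}}
         {\sum_i \#\{\text{resolved quartets of } G_i\}},
\]

an exact rational. Unresolved induced quartets are excluded from numerator
*and* denominator — a deliberate convention (not universal among quartet
tools) that keeps \(Q = 1\) attainable for multifurcating gene trees
consistent with the species tree. Gene trees with missing taxa contribute
only their own \(\binom{k}{4}\) quartets. Counting is exhaustive
enumeration, feasible to ~40 taxa (66,045 quartets at 37); correctness is
established against a brute-force restriction-based oracle at small n.

Under the multispecies coalescent, a quartet with internal branch \(T\)
(coalescent units) matches the species tree with probability
\(1 - \tfrac{2}{3}e^{-T}\); the test suite verifies the simulator against
this closed form at \(T \in \{0.5, 1, 2\}\), and a score near 0.5–0.6 over
many loci is exactly the "around half of loci conflict" regime typical of a
rapid radiation.

## Matrix regimes

* **Completeness**: a locus passes fraction \(f\) iff its taxon count is at
  least \(\lfloor f \cdot N \rfloor\) — the one rule consistent with the
  published 37-taxon spectrum (95% → 35, 85% → 31, …, 15% → 5). Regimes are
  nested by construction.
* **Length bins**: loci sorted by length (ties by id) and split into
  contiguous groups whose sizes differ by at most one. Bin boundaries are a
  free choice; deterministic equal-size deciles are used.
* **Random subsamples**: uniform draws without replacement within a
  replicate, replicates independent (distinct draws, collisions allowed),
  reproducible under seed.
* **Concatenation** pads absent taxa with `?` (gap `-` is preserved inside
  loci; both count as missing for statistics) and emits 1-based inclusive
  per-locus character intervals, written as relaxed PHYLIP, NEXUS charset
  blocks, or RAxML-style partition files.
* A site is **variable** if ≥ 2 distinct non-missing states occur,
  **parsimony-informative** if ≥ 2 states each occur in ≥ 2 sequences;
  gaps, N and ambiguity codes are missing.

## Statistical binning

Gene-tree error is the enemy of summary methods on short loci, so gene
trees are first collapsed: internal edges whose bootstrap support is not
*strictly above* the threshold (default 50) are contracted. Two collapsed
trees are incompatible iff any retained split of one conflicts with any
retained split of the other on their shared taxa (< 4 shared taxa: vacuously
compatible). This pairwise test is necessary but not sufficient for joint
compatibility of a whole bin — the standard binning heuristic — and every
assignment is re-verified pairwise post hoc.

Bins are built by greedy balanced coloring: nodes in descending-degree
order (ties by id) go to the currently smallest bin with no conflicting
member, capped at \(\lceil n/k \rceil\) so sizes differ by ≤ 1 whenever the
graph admits it; infeasible caps are relaxed minimally with a warning.
Automatic mode takes the smallest bin count the heuristic satisfies
starting from \(\lceil n/\text{target} \rceil\) (target size default 7) —
a heuristic, not an exact chromatic computation, and deterministic given
the input. With 3648 mutually compatible loci and 528 bins this yields
exactly 480 bins of 7 and 48 of 6. Weighted multisets replicate each
supergene tree by bin size, so the weighted cardinality always equals the
number of binned loci.

## The estimator

RAxML/ExaBayes-scale inference is out of scope by design; the package ships
a transparent estimator so the pipeline runs anywhere: Jukes–Cantor
distances \(d = -\tfrac34 \ln(1 - \tfrac43 p)\) over shared non-missing
sites (pairs at \(p \ge 3/4\) capped at a configurable maximum and
flagged), neighbor joining via `ape::nj` made deterministic by sorting taxa
first, with negative branch lengths clamped to zero, and site-resampling
bootstrap supports. The species-tree summary averages topological
internode distances over gene trees and resolves them with NJ; every taxon
pair must co-occur in at least one gene tree (a disconnected pair graph is
an error listing the groups; distance imputation is deliberately not
attempted). Externally estimated newick gene trees can be ingested
anywhere gene trees are consumed.

## What the generator emulates — and what it does not

The synthetic-data module draws a Yule species tree (branch lengths read as
coalescent units), simulates gene trees under the standard multispecies
coalescent (within each branch, \(k\) lineages coalesce at rate
\(\binom{k}{2}\) per coalescent unit; no recombination within loci, free
recombination between loci), and evolves sequences under JC (optionally
discrete-gamma rates). The mitochondrial locus is one non-recombining
locus with `ne_scale = 0.25` (haploid, uniparental inheritance) and
optional introgression events that reroute lineages from a recipient
branch to a contemporaneous donor branch with a given probability at a
given time (`time = NA` picks the midpoint of the branches' overlap
window). All randomness flows from one master seed through named
substreams, so any stage replays independently.

The study-scale preset (`sim_config()`) defaults to 37 taxa, 3648 loci of
~375 bp, retention 0.9, and `rate_scale = 0.0012` substitutions per site
per coalescent unit — calibrated once so the mean parsimony-informative
fraction across loci sits near 2.6%, the UCE-scale signal level. Desk-scale
runs in the analysis scripts and tests use fewer taxa/loci and a higher
rate (stated in each script) so that individual matrices carry enough
signal at small alignment sizes; the published-scale balanced-binning
arithmetic is exercised directly on the 3648-locus graph in the tests
rather than by simulating 3648 alignments.

What the generator does *not* emulate: sequencing error, assembly and
alignment artifacts, recombination within loci, demographic change through
time, base-composition or rate heterogeneity across lineages, and gene
duplication/paralogy. Passing tests on synthetic data therefore demonstrate
the correctness of the analysis machinery and the qualitative
ILS/introgression signatures, not robustness to every real-data pathology.

## Numerical and degenerate-input conventions

* Zero-length branches are legal everywhere (topology-only analyses ignore
  them); negative lengths are rejected at parse and clamped to zero out of
  NJ.
* Alignments with no variable sites yield a star tree with no supports.
* The JC saturation cap (default 5) and the greedy most-missing-taxon
  pruning in `estimate_alignment_tree()` keep concatenated matrices with
  pathological missingness estimable; both actions are flagged.
* Ties: locus sorts break ties by id; NJ tie-breaks are fixed by
  lexicographic taxon order; bin assignment breaks ties by bin index;
  census classes order by count then member id.
* The exceedance counts in the group summary use strict inequality
  ("more than" a cutoff).

## Problem sizes used in the shipped runs

The analysis scripts simulate 12 taxa × 150 loci (~375 bp), 39 nuclear
analysis trees across three regimes, 20 mitochondrial bootstrap analyses,
and 60 loci through the binning stage; the acceptance script uses 10 taxa ×
80 loci for the pipeline stage, 10,000 gene trees per branch length for the
coalescent checks, and 20 replicates of 200 loci for species-tree recovery.
These sizes were chosen as the smallest at which every qualitative
signature of interest (regime-to-regime topology variation, marker-class
separation, ILS-level quartet scores) is reliably expressed.

## Known limitations

* The binning incompatibility test is pairwise only (as in the standard
  heuristic); a bin can in principle hold a jointly incompatible triple
  whose pairs are compatible.
* Exhaustive quartet enumeration scales as \(\binom{n}{4}\) per gene tree;
  beyond ~40 taxa a subsampling or dynamic-programming scheme would be
  needed.
* The internode-distance summary requires every taxon pair to co-occur in
  some gene tree.
* Classical MDS of strongly non-Euclidean RF matrices can carry high
  stress; the embedding is a visualization aid, while the group summary
  statistics are computed on the exact distances.
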