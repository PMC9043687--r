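---
title: "Sequence-graph analysis of mimotope repertoires with igomeNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-graph analysis of mimotope repertoires with igomeNet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igomeNet)
```

## The problem

Deep panning of a 7-mer phage-display library on pooled serum antibodies
yields an *Igome*: tens to hundreds of thousands of unique mimotope
peptides that together form a functional image of the selecting antibody
repertoire. A single antibody paratope does not select one sequence but a
*footprint* — families of related peptides that all bind it detectably.
igomeNet models the Igome as an undirected sequence graph in which two
7-mers are connected when one can be transformed into the other by at
most 4 insertions/deletions, i.e. when they share a common (not
necessarily contiguous) subsequence of at least 5 residues. Footprints
then appear as dense neighborhoods and clusters, and differences between
two cohorts (here labeled `A`, patients, and `C`, controls) can be read
off as neighborhoods or clusters with a skewed cohort composition.

## The pipeline, stage by stage

**Ingestion** (`extract_inserts`, `filter_copy_number`,
`apply_exclusion_list`, `pool_libraries`). Reads are located between
their two flanking primers, discarded if *any* insert base has Phred
quality ≤ 32, translated, and counted. The copy-number window [3, 10]
(both ends inclusive) suppresses sequencing errors on one side and
overgrowing phage clones on the other; both bounds are arguments.
Target-unrelated peptides (plastic/streptavidin binders and fast
growers) are removed via a user-supplied exclusion list — predicting
them is out of scope for this package. Pooling takes a unique-sequence
union and records per-library membership flags, which later drive all
cohort statistics. The quality rule is applied per base rather than as a
read average: a single uncertain insert base corrupts the translated
7-mer, and the 3–10 copy window cannot rescue a sequence that was never
read correctly.

**String metrics and their calibration** (`seq_metric`, `roc_metric`,
`bootstrap_auc`, `select_edge_criterion`). Nine pairwise comparison
functions are provided (Hamming, LCS, Levenshtein, Damerau–Levenshtein,
optimal string alignment, q-gram, cosine, Jaccard, and global pairwise
alignment under BLOSUM62), the edit-distance family also in a
*property-recoded* variant in which the character-equality test is
replaced by membership in 15 overlapping amino-acid property groups
(e.g. M ≡ {M, I, L, V}). The relation is deliberately non-transitive
(F~Y and Y~H but not F~H), which is why recoding is only defined for
metrics whose recurrences compare residues at the point of comparison;
q-gram profile metrics would need a global relabeling that the
overlapping groups do not admit, so recoding them raises an error
rather than inventing semantics. Metrics are benchmarked by ROC analysis
on isospecific mimotope sets (groups of mimotopes known to bind the same
monoclonal antibody) versus pairs with a random public-library
reference, with the AUC bootstrapped over repeated negative draws using
common draws per round so metric comparisons are paired. On such data
the editing distances dominate, and the LCS distance is the cheapest of
them. The graph's edge criterion is not the Youden-optimal LCS length
(which is permissive) but the smallest LCS length whose specificity
clears a floor of 0.9 — one extra required common residue buys strict
isospecificity.

**The graph** (`build_adjacency`, `build_graph`, `graph_stats`,
`degree_distribution_fit`, `degree_stratified_assortativity`,
`path_length_profile`, `eigencentrality`). Adjacency is computed by an
exact C++ all-pairs scan with a residue-multiset prefilter (the multiset
intersection bounds the LCS from above, so most dissimilar pairs skip
the dynamic program); a plain-R double loop is packaged as the reference
implementation and the two are asserted equal in the tests, at n = 500
on every run. Sequences with no neighbor are dropped as singletons and
counted. Topology statistics include an exponential fit to the 50-bin
degree histogram, Newman degree assortativity, attribute assortativity
within 20 degree-stratified induced subgraphs (which separates genuine
attribute homophily from the mechanical contribution of degree), a
BFS-sampled shortest-path profile whose diameter is an exact value when
every vertex serves as a source and a labeled lower bound otherwise, and
eigenvector centrality by power iteration on A + I (the shift breaks
oscillation on bipartite components; tolerance 1e-10, scaled to max 1
per component).

**Differential repertoire** (`differential_neighborhoods`,
`recursive_louvain`, `cut_tree_partition`, `differential_clusters`).
Each vertex's *closed* neighborhood — the vertex plus its neighbors — is
treated as the smallest continuous fragment of a footprint; the center
belongs to its own footprint, which is why the closed form is the
default (configurable). Sequences found in both cohorts contribute half
a count to each side. Each neighborhood's `C` weight is tested against
the *global weighted* `C` fraction (not 0.5), with a two-sided
z-test of a proportion without continuity correction above 30 elements
and an exact binomial test otherwise (half-weights rounded to nearest,
ties to even — the exact test needs integers and this is the least
biased rounding). Benjamini–Hochberg correction runs over all vertices
at α = 0.05. Clustering applies Louvain recursively: each community is
re-clustered until it is smaller than twice the minimal workable size
(4), Louvain returns a single community, or the split's modularity falls
below 0.3 — the conventional floor for meaningful community structure;
without that floor the recursion shatters dense near-clique footprints
into fragments. The flat partition is the tree depth maximizing the
number of clusters of ≥ 4 vertices (ties to the shallower depth).
Per-cluster calls reuse the same composition test; the cluster-*count*
asymmetry between cohorts is summarized by the z-test against 0.5 (both
cohorts equally likely to dominate a cluster) and cluster sizes by a
rank-sum test. The z-test is used for the count summary at any n
because it is the variant consistent with the worked 3-of-20 example
(p ≈ 0.0018) that anchors this statistic.

**Cluster models** (`build_pssm`, `score_sequence`, `scan_epitopes`,
`exact_proteome_match`). A cluster's model is the simplest one: per
position, residue probabilities with a Laplace-style pseudocount of 1/20
per cell, scored as −log p and summed over the 7 positions, so lower
scores are better; reported `goodness` is the negated score so
thresholds read "higher is better". The default membership threshold is
the worst score among the cluster's own members — every training member
is recalled, which lands the models in a high-sensitivity regime while
random peptides remain far below threshold. Epitopes longer than 7
residues are scanned with a sliding window and the best frame is kept.
Proteome search deliberately does *not* use the PSSM (a 7-residue model
scanned over an entire proteome produces hits by the tens of thousands);
only exact, case-insensitive substring matches of cluster members are
reported, optionally collapsed to genes via the FASTA header token.

**Mapping and characterization** (`external_neighbor_counts`,
`extract_jregion_7mers`, `capture_recapture`, `overlap_enrichment`,
`mm_entropy`, `classify_entropy`, `partial_correlation`). External
libraries (public mimotopes `G`, background `B`, immunoglobulin
J-region 7-mers `I`) are mapped by one-vs-many neighbor counting under
the same edge criterion rather than by building a pooled giant graph.
Sampled diversity uses the Lincoln–Petersen estimator N = n1·n2/overlap
(Chapman's bias-corrected variant is available) with a 5–95% percentile
interval from parametric resampling of the overlap — hypergeometric
exactly, or its binomial limit when the estimated space exceeds 1e7.
Sequence complexity uses the Miller–Madow bias-corrected Shannon
entropy, which on 7-mers takes exactly 15 discrete values (one per
integer partition of 7); the four complexity classes are bounded at
1.57, 2.0 and 2.2 nats, chosen so that the discrete levels 2.37 (all
distinct), 2.105 (one pair), 1.84/1.76 (two pairs / a triplet) and
≤ 1.57 (three pairs or more repetition) fall into the intended bins.
Partial correlations residualize both variables on the controls by least
squares and are computed on log1p-transformed counts to stabilize
variance while keeping zeros.

## The synthetic generator: what it emulates and what it does not

`synthetic_config()` defines the study conditions all tests run under.
Planted *footprint families* are a seed 7-mer plus members one or two
substitutions/indels away, constrained to share a ≥ 5-residue
subsequence with the seed; 80% of members are single-edit variants, so a
family's interior is a near-clique — matching the dense, highly
connected neighborhoods real Igome graphs show. Residue composition is
biased in proportion to NNK-codon multiplicity, the bias a degenerate
codon library actually has. Each member enters cohort `A` with
probability 0.7 scaled by the family's `A` weight (and likewise `C`);
a shifted family's weight ratio is the 8-fold default
`shift_magnitude`, so its members end up mostly private to the
up-shifted cohort — presence/absence of unique sequences is exactly how
differential abundance manifests in unique-sequence libraries. The
defaults (40 families of 20–45 members, 20% of families shifted, 25% of
those toward `A`, libraries of 1,500/1,200/2,500/1,500 unique sequences
for A/C/G/B) give each shifted family enough present members (~20) for
the composition tests to have power at desk scale, and plant the same
asymmetry direction the motivating study reports (more specificities
lost than gained in patients). Copy numbers follow a zero-truncated
negative binomial (mu 4, size 1.2, capped at 50) so the 3–10 retention
window is exercised from both sides.

What the generator does **not** emulate: phage amplification kinetics
and negative-selection steps; the full-scale regime (hundreds of
thousands of vertices with mean degree in the hundreds — the defaults
produce ~1,500-vertex graphs with mean degree ~20); sequencing-error
structure beyond single low-quality bases; and any overlap structure
between *unrelated* families. Passing tests therefore demonstrate that
the machinery is correct and recovers planted structure under realistic
composition and noise — not that any particular biological effect size
in real data will be recovered.

## Numerical choices and degenerate inputs

- All randomized stages take explicit seeds; the pipeline derives
  per-stage seeds from one master seed so stages can be re-run
  individually.
- ROC curves sweep only observed distance values; ties are resolved by
  calling "distance ≤ t" positive; AUC is the trapezoid rule with (0,0)
  and (1,1) anchors. Degenerate all-equal scores return AUC 0.5 with a
  warning.
- An empty neighborhood tests at p = 1 with a warning; an overlap of 0
  makes the diversity estimate unbounded and is an error; a constant
  attribute makes assortativity undefined and is reported missing.
- Exponential degree fits require at least 3 positive-mass bins and
  refuse constant degree sequences.
- Power iteration failure to converge is an error with the component
  size in the message, never a silent wrong answer.

## Problem sizes

The test suite and the acceptance script run everything at desk scale:
~2,500-sequence pooled libraries (~1,500-vertex graphs, ~15,000 edges),
200 null replicates for the false-discovery check, 500-sequence
adjacency oracle comparisons, 20 bootstrap rounds for metric AUCs, and
two uniform samples of 217,442 and 3.0 million distinct 7-mers for the
capture–recapture control of the full 20^7 space. A full suite run
completes in about two minutes on one core.

## Known limitations

- The recursion floor of 0.3 modularity is a heuristic; graphs whose
  genuine substructure sits below it will be under-split.
- The exact binomial branch rounds half-weights; cohort-swap symmetry is
  exact only when no sequence is common to both cohorts.
- `pwa` alignment scores are negated when ranked as distances; its gap
  parameters (open 10, extend 4) follow the underlying alignment
  function's defaults and are exposed as arguments.
- Property recoding is undefined for profile metrics by design (see
  above).
- The diversity estimator assumes both samples are uniform draws from
  the same space; selected (non-random) libraries violate this and the
  estimate then reflects the *sampled* space, not the library's design
  space.
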