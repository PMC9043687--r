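# igomeNet

Sequence-graph analysis of antibody-repertoire mimotope libraries.

Deep panning a 7-mer phage-display library on pooled serum antibodies
produces an *Igome* — a large set of mimotope peptides that images the
selecting antibody repertoire. igomeNet turns such libraries into an
undirected sequence graph and reads repertoire structure off its
topology: two 7-mers are connected when their longest-common-subsequence
(LCS) distance is at most 4, i.e. when they share a subsequence of at
least 5 residues,

```
d_LCS(s1, s2) = |s1| + |s2| - 2 * LCS(s1, s2),    edge iff d_LCS <= 4.
```

Antibody *footprints* — the families of related peptides one paratope can
select — appear as dense neighborhoods and clusters of this graph. The
package is aimed at immunologists analysing deep-panning experiments
that compare two cohorts (labeled `A` and `C` throughout), and provides:

- **Ingestion**: FASTQ reads → counted 7-mer libraries (flanking-primer
  insert extraction, per-base Phred > 32 quality rule, stop-codon
  removal, copy-number window [3, 10], exclusion lists for
  target-unrelated peptides, pooling with membership flags).
- **String metrics & calibration**: Hamming/LCS/Levenshtein/
  Damerau–Levenshtein/OSA/q-gram/cosine/Jaccard/BLOSUM62 alignment, the
  edit-distance family also under amino-acid *property recoding* (15
  overlapping physicochemical groups); ROC/AUC benchmarking on
  isospecific mimotope sets with bootstrapped negatives and selection of
  the graph's edge criterion by a specificity floor.
- **Graph construction & topology**: exact C++ all-pairs adjacency with
  a prefilter (contractually identical to the packaged R reference),
  degree-distribution exponential fits, degree and attribute
  assortativity (including degree-stratified), sampled shortest-path
  profiles and diameters, eigencentrality by power iteration.
- **Differential repertoire**: per-neighborhood and per-cluster cohort
  composition tests under the half-split rule for shared sequences
  (z-test of a proportion above 30 elements, exact binomial below),
  Benjamini–Hochberg FDR, the induced subgraph of significant
  neighborhoods, recursive Louvain clustering with a modularity-floor
  stop, and tree cutting that maximizes workable (≥ 4-vertex) clusters.
- **Cluster models**: per-cluster position-specific scoring matrices
  (−log probability scores, member-recall threshold), sliding-window
  epitope scans, exact proteome matching with isoform collapsing.
- **Mapping & characterization**: one-vs-many neighbor counts against
  external libraries (public mimotopes, background, immunoglobulin
  J-region 7-mers), Lincoln–Petersen/Chapman capture–recapture diversity
  estimation with bootstrap intervals, overlap fold-enrichment,
  Miller–Madow entropy and the four-level complexity classification,
  partial correlations on log counts.
- **Synthetic data**: a generator that plants cross-reactivity families
  with cohort-specific abundance shifts, NNK-codon residue bias,
  zero-truncated negative-binomial copy numbers and FASTQ read
  simulation, so the whole pipeline is testable end to end without any
  downloads.

## Worked example

```r
library(igomeNet)

cfg <- pipeline_config(rng_seed = 42)   # synthetic study conditions
report <- run_pipeline(cfg)
print(report)
#> Igome analysis report: graph 1473 vertices / 14338 edges
#> Differential neighborhoods: 1473 vertices, 149 significant
#>   (70.5% C-called; global C fraction 48.4%)
#> Cluster calls: 47 clusters, 2 A-called, 4 C-called (count test p = 0.414)

str(report$recovery)
#> $ sensitivity        : num 0.809
#> $ false_positive_rate: num 0.000775
```

The run generates two cohort libraries with eight 8-fold abundance-shifted
families planted among forty, builds the LCS graph of the pooled unique
sequences (1,473 non-singleton vertices, 14,338 edges), tests every
closed neighborhood's cohort composition against the global weighted `C`
fraction, and clusters the graph recursively. Of the planted
shifted-family members, 80.9% sit in neighborhoods called significant in
the planted direction at FDR 0.05, while only 0.08% of unshifted
vertices are called — the pipeline recovers the planted repertoire
difference. More neighborhoods are `C`-called (70.5%) than the global
`C` share (48.4%), mirroring the planted asymmetry (more families
down-shifted in `A` than up-shifted).

Single-quantity helpers reproduce published reference arithmetic:

```r
overlap_enrichment(297028, 109617, 15223, 0.88e8)$fold
#> 41.14  — the A/C overlap is ~41-fold above chance for the sampled space

mm_entropy(c("ACDEFGH", "AACDEFG", "AACCDDE"))
#> 2.374  2.105  1.566   # nats
classify_entropy(c("ACDEFGH", "AACDEFG", "AACCDDE"))
#> very_high  high  very_low
```

See `vignettes/igome-analysis.Rmd` for the full account of the model,
the generator's design and every numerical choice.

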