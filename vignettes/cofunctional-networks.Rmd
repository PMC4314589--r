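---
title: "Building and assessing cofunctional gene networks with cofnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and assessing cofunctional gene networks with cofnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofnet)
```

## The problem

A large fraction of even the best-studied bacterial genomes carries no
experimentally supported pathway annotation. Cofunctional gene networks
attack this gap by guilt by association: if two genes repeatedly co-occur
in articles, co-express across microarray series, share rare protein
domains, are co-inherited across genomes, sit next to each other in many
genomes, or physically interact, they probably act in the same pathway.
None of these signals is reliable on its own, and their raw scores live on
incomparable scales. cofnet puts them on one scale by benchmarking each
against a curated gold standard, then integrates them into a single
weighted network that supports two predictions: new members of a pathway
or phenotype, and functions for an uncharacterized gene.

## The model

### Gold standard

Positive pairs are pairs of genes sharing at least one annotation term
after three filters: an evidence-code whitelist (default `IDA`, `IGI`,
`IMP` — direct assay, genetic interaction, mutant phenotype; electronic
annotations are too circular to train on), removal of a short explicit
list of very large transcription-related terms (`large_process_terms()`),
whose thousands of co-member pairs would dominate learning, and removal of
superpathway composites, which would assert associations *between*
pathways. Negative pairs are every other pair of annotated genes, so
`|pos| + |neg| = choose(n_annotated, 2)` always holds. The negative set is
quadratic and is therefore kept lazy — a count and a membership test —
rather than materialized (`negatives_from_annotation(materialize = FALSE)`
is the default).

Filtered terms are treated as nonexistent for *both* positives and
negatives: a pair sharing only an excluded large term counts as a
negative. The alternative (dropping such pairs from the universe) is not
what "genes that do not share any of the annotations" implies once the
annotation set is fixed.

### Log-likelihood scores

For a raw evidence set, links are sorted by score and partitioned into
bins, and each bin receives

    LLS = ln[ (pos_in_bin + c) / (neg_in_bin + c) ] - ln[ P/N ]

where `P`/`N` are the gold-standard totals. LLS = 0 means the bin's
positive fraction equals the genome-wide background; positive values mean
enrichment. Choices the estimator makes:

* **Equal-gold-count binning** (default 100 gold pairs per bin, the last
  bin absorbing the remainder): equal-width bins break down on the heavily
  skewed score distributions cocitation and neighborhood scores produce.
  The bin size trades resolution against variance; 100 gold pairs keeps
  the per-bin standard error of LLS near 0.1–0.2 nats.
* **Pseudocount** `c = 0.5` (Haldane–Anscombe) so pure bins stay finite.
  With `c = 0` a bin empty of gold pairs is an error, deliberately.
* **Piecewise-constant mapping**: a link receives its bin's LLS. Scores
  outside the modeled range clamp to the end bins with a logged count —
  extrapolating a fitted curve beyond observed evidence would manufacture
  confidence.
* **Retention rule**: an evidence set is kept iff its maximum bin LLS is
  positive *and* bin rank correlates positively with bin positive-fraction
  (one-sided Spearman, p < 0.05; skipped below 3 bins). The correlation
  screen is what "significant correlation between coexpression and
  cofunctional association" becomes when it has to be operational; it is
  configurable because it is a choice, not a given.

### Weighted-sum integration

Evidence sources overlap heavily (coexpression series with each other,
cocitation with everything literature-derived), so naive Bayes
over-counts. For each pair the surviving LLS values (those `>= T`) are
sorted descending and combined as

    WS = S0 + sum_{i>=1} Si / (D * i)

`D >= 1` discounts secondary evidence; `D = 1` is plain rank-discounted
addition, `D -> Inf` keeps only the best source. `T` is applied to the
individual summands *before* ranking — reading "for all S >= T" as a
filter on what enters the sum — so a weak source never occupies a rank.
Ties between equal LLS values break by evidence-code order for
deterministic output. The same machinery merges link sets *within* a data
type (per-series coexpression networks, Archaea/Bacteria profile networks,
the two neighborhood variants) before the across-type integration.

No tuning rule for `(D, T)` comes with the method, so `tune_ws()` invents
one and says so: grid search maximizing the area under the cumulative
accuracy-vs-coverage curve against a held-out, seeded half of the gold
positives. The curve bin size in the tuning objective should scale with
network size (~20–30 curve points; the default 100 links per bin suits
networks of a few thousand edges).

## Evidence scorers

Each scorer turns one standard input table into raw pair scores; all of
them feed `benchmark_linkset()` unchanged, and consistent relabeling of
genes leaves every score identical.

* **Cocitation (CC)** — upper-tail hypergeometric probability of the
  observed co-mention count given each gene's article count and the corpus
  size; raw score `-log10 p`. The corpus size should be the full article
  count, not just gene-mentioning articles.
* **Coexpression (CX)** — Pearson correlation per series; a series needs
  more than 8 samples, and each per-series link set is benchmarked and
  then WS-merged into one CX network. Zero-variance profiles are unscored
  rather than scored 0: a flat profile says nothing.
* **Domain co-occurrence (DC)** — each shared domain `d` contributes its
  rarity in bits, `-log2 f_d`, with `f_d` the proteome fraction carrying
  it. This concrete weighted-mutual-information form is a stated stand-in:
  any scorer with the same signature can replace it. Note the rarity
  weight means deleting a *non-carrier* protein lowers scores slightly
  (frequencies rise); the meaningful monotonicity — rarer shared domains,
  or more of them, never score lower — is what the tests pin down.
* **Phylogenetic profiles (PG)** — per-gene profiles over genomes are
  discretized into `k = 4` equal-frequency bins (midrank-based, so ties
  are stable) and scored by the mutual information of the joint histogram,
  in bits. Equal-frequency beats equal-width here for the same skewness
  reason as in LLS binning. When genome taxon labels are supplied, the
  Archaea-only and Bacteria-only columns yield two link sets that are
  WS-merged downstream; with only 122 Archaea against 1626 Bacteria, a
  pooled MI would be dominated by the bacterial signal.
* **Gene neighborhood (GN)** — two complementary scores. Distance-based:
  minus the median intergenic distance (bp) over co-occurrence genomes,
  different replicons charged a 1 Mb cap. Probability-based: binomial
  upper tail of the number of genomes where the orthologs are within
  `window = 1` slots, with per-genome null `q = min(1, 2W/(n_slots - 1))`
  averaged over the co-occurrence genomes (slot counts differ per genome;
  the binomial needs one `q`). Both need co-occurrence in at least 3
  genomes — below that, "conserved" proximity is noise. All these
  constants are this package's defaults, stated here because the cited
  methods do not travel with their parameters.
* **PPI (HT, LC)** — binary interactions get raw score 1 and form
  single-bin evidence: their entire LLS is learned from gold-standard
  overlap, which is exactly what one can honestly say about an unweighted
  edge list. Per-source sets are benchmarked separately before merging so
  a noisy screen cannot dilute a curated set.

## Assessment

Knockout-phenotype data provide validation independent of the annotation
used for training. A gene is assigned a stress phenotype when its growth
score falls strictly below −4 (`phenotypes_from_scores()`; the boundary
value itself is *not* a defect). Two views:

* **Cumulative accuracy vs coverage** — links sorted by weight, walked in
  bins of 1000 pairs; accuracy is the percentage of *evaluable* cumulated
  pairs (both endpoints phenotype-annotated) sharing a phenotype, coverage
  the percentage of the coding genome among cumulated genes. Restricting
  the denominator to evaluable pairs keeps the curve about ranking quality
  rather than about phenotype-data coverage; the alternative denominator
  is one flag away.
* **Leave-one-out AUC** — each member of a phenotype set is held out and
  ranked among candidates by summed edge weight to the remaining members;
  the Mann–Whitney AUC (midranks for ties; unconnected candidates all
  score 0) is averaged over members. The remaining members are excluded
  from the negatives — they are known positives of the same phenotype —
  and the candidate universe defaults to the network's genes. Note the
  statistic is a *sum* of weights, so it is invariant to positive
  rescaling of the weights but not to arbitrary monotone warps.
* **Paired comparison** — two networks' per-phenotype AUC vectors meet in
  a two-sided Wilcoxon signed-rank test, zero differences dropped. With 15
  or fewer informative pairs the p-value is exact by enumerating sign
  patterns on the midranks (tied magnitudes stay exact, where the textbook
  exact distribution would bail out to a normal approximation); beyond
  that, `stats::wilcox.test()`.

When networks of unequal size are compared, truncate each to its top-k
links first — size inflates apparent performance.

## Prediction tools

`find_new_members()` ranks non-query genes by summed LLS to the query set
(ties: more supporting edges, then gene id), after reporting how many
query genes the network contains and the query's internal leave-one-out
AUC — a low AUC warns that the query genes are not actually
interconnected, so the ranking means little. `infer_functions()` scores
each annotation term by the summed LLS from the query gene to neighbors
carrying the term (default evidence whitelist `IDA, IMP, IGI, IPI, IEP,
TAS`; ties: smaller term first, then id). The summed-LLS statistic is a
design choice where no published statistic exists;
`infer_functions_hyper()` offers hypergeometric neighbor enrichment behind
the same contract.

## What the synthetic generator does and does not emulate

`annotation_fixture(n, target)` builds disjoint clique terms whose
within-term pair counts sum *exactly* to the target (greedy largest
`choose(k,2)` below the remainder; overlapping 2-cliques when disjoint
ones cannot finish), singletons keeping every gene annotated. At the
published scale — 1835 genes, 10 804 sharing pairs — the decomposition is
terms of 147, 12, 4 and 2 genes plus 1670 singletons, and the negative
count is then the exact complement, 1 671 891. `evidence_fixture()` scores
a seeded sample of gold pairs from named class distributions (the default
positives N(2,1) vs negatives N(0,1) give cleanly separated but
overlapping evidence); negatives are sampled by unranking pair indices so
the quadratic set never materializes. `phenotype_fixture()` plants module
genes below the −4 threshold under their module's conditions at a defect
rate (default 0.9 in / 0.05 out — strong but imperfect penetrance).
`module_network()` plants dense high-LLS modules (N(3, 0.5)) over sparse
exponential background.

One root seed drives everything; each stage derives its own stream from
the seed plus a stage name, so adding a stage never shifts another's
draws, and identical calls are bit-reproducible.

What this buys: every operation in the package is exercised end to end,
from file formats to prediction, with known ground truth. What it does not
show: real cocitation counts are Zipf-tailed, microarray series are
batch-structured, profile matrices carry phylogenetic autocorrelation, and
real annotation terms overlap heavily rather than forming disjoint
cliques. Passing tests demonstrate correctness of the machinery and
sensible statistical behavior under controlled signal, not field
performance on any particular organism.

## Numerical choices and degenerate inputs

* Unordered pairs are stored canonically (`gene_a < gene_b`); self-pairs
  are dropped with a logged count; duplicate pairs keep the better score
  under the declared orientation.
* Network files sort by descending LLS with lexicographic tie-break, so
  write–read–write is byte-identical; weights are written at full double
  precision in natural-log units.
* Benchmark failure (too little gold overlap, or the retention rule) is a
  value, not an exception — pipelines drop weak evidence and continue.
* Constant profiles give MI 0 with a warning; genes missing from an input
  table give "no score" (`NA`), never silent zeros — except unconnected
  candidates in ranking contexts, where 0 is the honest score.
* `weighted_sum()` on an empty surviving stack yields no edge; `D < 1` is
  rejected outright (it would weight secondary evidence above primary).
* All simulation-backed tests run at deliberately small problem sizes —
  gold standards of 60–400 genes, evidence sets of 500–10 000 pairs, 20
  replicates — chosen so the full suite completes in well under a minute
  while the statistical properties under test (LLS recovery, integration
  gain, module retrieval) remain comfortably detectable.

## Known limitations

* The LLS mapping is piecewise-constant; an isotonic smoothing option
  exists but no continuous density-ratio estimation.
* `(D, T)` tuning is a pragmatic grid search against held-out gold; it
  makes no claim of matching how any published network chose its
  parameters.
* The probability-based neighborhood score uses a mean-`q` binomial
  rather than the exact Poisson–binomial across genomes.
* Identifier handling is deliberately dumb: gene ids are opaque strings,
  and no alias resolution is attempted.
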