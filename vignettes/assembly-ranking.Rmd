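---
title: "Reference-anchored evaluation and ranking of de novo transcriptome assemblies"
author: "transrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-anchored evaluation and ranking of de novo transcriptome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transrank)
```

## The problem

De novo transcriptome assembly of a non-model organism rarely produces one
assembly: different assemblers, k-mers, scaffolding, redundancy removal,
reconciliation and cross-platform merging steps combine into dozens or
hundreds of candidate transcriptomes, and no single contiguity statistic
(N50, say) reliably identifies the best one. The approach implemented here
anchors the decision to *reference transcriptomes* of well-annotated
related organisms: every candidate and every reference is summarized by
the same fifteen evaluation parameters, all individuals are projected into
a common standardized principal-component space — with the references as
*supplementary* individuals so they cannot distort the structure — and the
candidates are ranked by their **Mean Distance (MD)**, the average
Euclidean distance to the references in the retained component space. The
assembly whose parameter profile most resembles a well-characterised
transcriptome wins: MD close to 0 is best.

## The fifteen evaluation parameters

`build_metric_vector()` assembles one row per assembly from four evidence
blocks. Sequence statistics need only the FASTA; the other blocks consume
per-contig read-alignment summaries, protein annotation hits, and
single-copy ortholog statuses (the kind of tables produced by full-length
annotators and ortholog benchmarking tools, accepted directly or in the
BUSCO v3 `full_table` dialect).

| Parameter | Definition | Trend |
|---|---|---|
| AllTransSize | total length of all contigs (nt) | lower |
| N50 / N90 | contig length at which the descending cumulative sum reaches 50% / 90% of AllTransSize | higher |
| Contigs | contigs supported by ≥ 1 properly mapped read pair | lower |
| Contigs500 | same, restricted to contigs strictly > 500 nt | higher |
| MeanContigLen | mean length of the *useful* contigs (those counted by Contigs) | higher |
| Ns | count of N letters | lower |
| MeanGapLen | Ns / number of maximal N-runs | lower |
| DiffProts | distinct annotated proteins | higher |
| DiffComplProts | distinct proteins with a complete hit | higher |
| MissAssembl | % of annotated contigs with hits on both strands | lower |
| MeanContigCov | mean per-contig % of positions covered by reads | higher |
| ComplOrtho / FragOrtho / DuplOrtho | % of ortholog groups complete-in-one-contig / fragmented / duplicated | higher / higher / lower |

Several definitions were genuinely open and are pinned as follows.

* **MeanGapLen** is total Ns divided by the number of maximal runs of
  consecutive Ns. This reproduces the published interpretation that a
  value of 1 means indeterminations are isolated (randomly scattered)
  while larger values indicate real gaps, and it grows with true gap
  length. It is 0 when there are no Ns.
* **MeanContigCov** averages the per-contig breadth percentage over *all*
  contigs, uncovered contigs contributing 0 — reading "averaged for the
  full assembly" literally. `cov_denominator = "useful"` averages over
  the mapped contigs instead.
* **MeanContigLen** uses the useful contigs when alignment evidence is
  available and all contigs otherwise; the all-contig value is always
  kept as an attribute.
* **Contigs500** uses a strict `> 500` nt threshold and the same mapping
  requirement as Contigs. With single-end data, "at least one pair"
  degrades to "at least one mapped read" (`read_mode = "single"`).
* In SAM input, only primary mapped alignments count; a pair counts when
  the proper-pair flag is set and both mates map to the same contig.
* **Ns** counts the letter N case-insensitively; other ambiguity codes
  are ignored.
* **MissAssembl**'s denominator is the set of *annotated* contigs, since
  unannotated contigs carry no strand evidence either way.
* The trend column stores the printed direction of each parameter,
  including the (surprising) higher-better arrow on FragOrtho; trends are
  report annotation only and never enter the ranking, so the discrepancy
  between that arrow and the usual reading of fragmentation as a defect
  is surfaced in the report legend rather than resolved numerically.

## The strategy graph

`strategy_graph()` enumerates the combinatorial space of assembling
strategies as a dependency graph, without executing any assembler. The
short-read module yields, per assembler, primary (`ct`) and scaffolded
(`sc`) assemblies per k-mer plus, per stage, a concatenation across
k-mers, its 100%-identity redundancy-removed version and a reconciliation
(`_cat`, `_cd`, `_rcMin2`); with the default three assemblers and k-mers
25 and 35 this gives 30 assemblies. The long-read module contributes two
primaries and their reconciliation (`ctMIRA`, `ctEulK29`,
`ctMIRA_ctEulK29_rcCAP3`). The merging module combines the platforms in
three simultaneous modes — reads-reads, assembly-reads and
assembly-assembly — and brings the default total to 181.

Two points of the merging combinatorics are ambiguous in prose and are
exposed as configuration. The pinned defaults — assembly-assembly merges
pair each short-read assembly with the *reconciled* long-read assembly
only (`aa_partners = "reconciled"`), and the k-mer-graph assembly-reads
merger emits one node per k-mer (`ar_ray = "per_kmer"`) — are the single
reading that reproduces both published totals (30 and 181) and every
assembly name that appears in the published rankings. Each node carries
the four qualitative factors used downstream (program of the last step,
task, k-mer category, platform), and the tag grammar is invertible:
`parse_assembly_tag()` rebuilds any generated node from its name.

## The multivariate stage

`fit_pca_with_supplementary()` is a correlation PCA written for the
supplementary-individual contract:

* Each parameter is centred and scaled by the mean and **population**
  (1/n) standard deviation of the active rows, the convention of the
  multivariate analysis software this method standardises on
  (`sd_type = "sample"` is available).
* The active correlation matrix is eigendecomposed; eigenvalues sum to
  the number of parameters, and the population variance of the
  coordinates on dimension *k* equals eigenvalue *k* (both asserted to
  1e-9 in the tests against an independent SVD oracle).
* Supplementary rows are standardized with the *active* constants and
  projected with the same eigenvectors. They cannot affect the fitted
  structure; the test suite asserts bitwise identity of the model with
  and without them.
* PCA signs are arbitrary, so each eigenvector is flipped to make its
  largest-magnitude loading positive; all downstream code and tests are
  sign-stable.
* Three components are retained by default, matching the published
  retention choice; `var_threshold = 85` instead retains the smallest
  number of dimensions reaching that explained-variance percentage,
  since both the count and the percentage are stated.

`describe_dimensions()` correlates each parameter with the active
coordinates of each retained dimension (Pearson R, two-sided P from the t
statistic on n − 2 degrees of freedom) and flags pairs with P ≤ α
(default 0.05). No multiple-testing adjustment is applied — the filter is
defined as a plain per-pair threshold — and that fact is recorded in the
report metadata. Under permuted null parameters the filter retains ≈ 5%
of pairs, which the tests verify by simulation.

`cluster_assemblies()` performs hierarchical clustering on the retained
principal components only (never on the raw parameters), with Ward
linkage on Euclidean distances via `stats::hclust(method = "ward.D2")`,
whose merge order is checked merge-by-merge against a brute-force
inertia-based agglomeration oracle on small instances. Because the
upstream method delegates the "optimal" cluster count to its clustering
routine without printing a formula, the criterion is pinned explicitly
here: q maximizes the inertia-gain ratio Δ(q)/Δ(q+1) with
Δ(q) = W(q−1) − W(q), i.e. the partition just before the largest relative
collapse in between-cluster gain, searched over `q_range` (default 2 to
min(10, n−1), clipped with a warning when infeasible). Identical points
make the total inertia degenerate and are a hard error. References are
clustered jointly with assemblies by default — published figures show
references inside clusters — and can be excluded with a flag.

## Ranking

`rank_by_mean_distance()` computes Euclidean distances in the retained
space (the same space the clustering uses; `dims = "all"` is available),
averages them across the selected references with equal weights, and
ranks ascending with lexicographic tie-breaks. Restricting the reference
set — as one does when a distant reference distorts the distance scale —
changes only MD, never the per-reference columns. No reference is ever
excluded automatically: there is no principled quantitative trigger, so
the fit instead flags any reference whose mean distance to all assemblies
exceeds three times that of the closest reference, and leaves the
decision to the user.

## The synthetic-data generator

The generator exists so that every stage is testable end-to-end with no
external data. `make_base_transcriptome()` draws transcript lengths as
`min + (max − min) · Beta(1, shape)` — right-skewed, like real transcript
length distributions; the validation suite uses 300–1500 nt, shape 2 —
and attaches one complete protein per transcript and an ortholog group to
half of them, so the clean truth scores MissAssembl = 0, DuplOrtho = 0,
FragOrtho = 0, ComplOrtho = 100. `degrade()` applies four quality
degradations in a fixed, documented order (fragment → duplicate → gapify
→ chimerize; the order is deliberately not configurable so that a spec is
reproducible), keeping the evidence tables consistent with the degraded
FASTA and recording exact bookkeeping: injected N-runs are strictly
interior and non-adjacent, so the metric engine recovers exactly the
injected Ns and run count.

Alignment evidence is generated analytically — coverage breadth drawn as
a fraction of contig length (0.80–0.95 for faithful contigs, lower for
mutated duplicates and chimeras) — rather than by simulating and mapping
reads, because the metric calculators consume only the per-contig
summary. Consequently the generator does *not* emulate read error
models, expression levels, or splice-isoform structure, and passing
end-to-end tests demonstrates that the pipeline responds correctly to
contiguity, redundancy, gap and chimerism signals — not that it captures
every property of real RNA-seq evidence.

`make_parameter_matrix()` skips the sequence level entirely: Gaussian
clusters in a latent three-dimensional space, mapped to the fifteen
parameters by a fixed random linear map plus 0.1-sd observation noise,
with references planted in cluster 1. It is the direct fixture for the
multivariate stage.

## Validation conditions and problem sizes

The test suite fixes its study conditions once: calculator/oracle
agreement on 1,000 random assemblies; PCA identities on random 10 × 15
matrices; Ward/oracle equivalence on 6–12-point instances; a 1,000-run
null simulation at n = 30 for the correlation filter; 100 seeded trials
of a five-level degradation grid (fragmentation 0–3 breakpoints/kb,
duplication 0–60%, gaps 0–0.8 runs/kb, chimerism 0–30%, jointly
increasing) on 60-transcript transcriptomes, requiring non-decreasing MD
within ≥ 95% of trials; and cluster recovery at separation 10 with 30
individuals over 100 seeds, requiring mean adjusted Rand agreement
≥ 0.9. All randomness flows through explicit integer seeds, restoring the
caller's RNG state afterwards.

## Known limitations

* The pipeline evaluates evidence it is given; it does not run read
  mapping, protein annotation or ortholog benchmarking itself, and the
  quality of the ranking inherits the quality of those inputs.
* A parameter that is constant across all assemblies carries no
  information and would make the correlation PCA degenerate; the
  file-driven pipeline drops such parameters with a message, while the
  lower-level fit treats them as a hard error so silent degeneracy cannot
  slip through programmatic use.
* MD is a relative, set-dependent quantity: it depends on the set of
  assemblies that defined the PCA space, so values are comparable within
  one run, not across runs.
* With very few assemblies (the minimum is 3 active rows) the component
  space and the cluster-count criterion are weakly determined; rankings
  remain well-defined but clusters should be read with caution.
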