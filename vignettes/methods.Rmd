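---
title: "Methods: differential chromatin accessibility for CRM discovery"
author: "crmpeaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential chromatin accessibility for CRM discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cis-regulatory modules (CRMs) — enhancers, silencers, promoter-proximal
elements — are nucleosome-depleted in the cells where they are active, so
they appear as peaks of accessibility in ATAC-seq and DNase-seq. A peak
that is reproducibly *more* accessible in one embryonic lineage than in
the rest of the embryo is a strong CRM candidate for that lineage.
`crmpeaks` implements the peak-level statistics of such a comparative
design end to end: two independent assay designs (a cell-sorted
ATAC-style comparison of a purified lineage against the remaining cells,
and a whole-embryo DNase-style comparison of normal embryos against
embryos in which the lineage has been ablated), each with biological
replicates, analysed from replicate peak calls to annotated,
motif-characterised differential peaks.

Because the package is exercised entirely on synthetic data with planted
ground truth, every stage can be tested quantitatively: recall and
precision of planted differential peaks, calibration of the test under
the null, recovery of a planted transcription-factor motif, and exact
agreement of the interval algebra with per-base brute force.

## Reference peak set construction

Replicate peak calls disagree about boundaries. A replicate peak enters
the reference peak set (RPS) when at least 75% *of its own length* is
covered by the union of the other replicates' peaks — a non-reciprocal
criterion: the partner peaks are not required to be covered to 75% in
return. The reciprocal version would silently drop any peak called more
than 25% larger in one replicate, which is exactly the boundary noise the
criterion is meant to tolerate. Qualifying peaks from all replicates are
pooled and merged into disjoint intervals.

Two readings exist for three or more replicates: qualification against
the *union* of the other replicates (default, `qualify = "union"`) or
against *each* other replicate separately (`qualify = "each"`, strictly
more conservative). Both are provided; the union reading is the default
because it is the most permissive reading consistent with merging "across
samples".

Coordinates are 0-based half-open throughout (BED convention); GFF3 input
is converted on read. Intervals that share only an endpoint do not
overlap and are merged only when `merge_bookended = TRUE` (off by
default, making the usual BED merge-distance-0 ambiguity explicit). The
core primitives (`merge_union`, `overlap_fraction`) are vectorized
sorted-sweep implementations: a coverage prefix-sum makes the overlap
fraction of a query an O(log n) lookup, which keeps oracle-scale test
sweeps (thousands of random fixtures against per-base bitmaps) cheap.

## Quality gates

* **FRiP** (fraction of reads in peaks): reads overlapping any peak by at
  least 1 bp over total reads; samples below 0.4 fail the gate.
* **Depth equalization**: all samples are subsampled without replacement
  to the minimum depth — on read intervals directly, or on count-matrix
  columns by a multivariate hypergeometric draw (the two are
  distributionally equivalent).
* **Replicate concordance**: pairwise Pearson correlation of per-peak
  counts, log1p-transformed by default because raw accessibility counts
  are heavy-tailed and a single strong peak can dominate r (a `raw`
  option exists; the choice is a documented interpretation, as the
  design this emulates does not state the transform). A replicate whose
  mean correlation with its surviving same-condition partners is at or
  below 0.8 is excluded; exclusion is greedy (worst first, means
  recomputed) so one shuffled replicate cannot drag its concordant
  partners under the threshold. 0.9 marks "highly concordant".
* **Read counting**: each read is assigned to at most one RPS peak — the
  peak with the greatest overlap, ties to the leftmost — so counts never
  double-count a read (HTSeq-like behaviour on disjoint features).

## The differential test

Counts for peak *i* in sample *j* are modelled as negative binomial with
mean `s_j * exp(b_i + beta_i * x_j)` and fixed dispersion `alpha_i`,
where `x_j` indicates the tested condition. This is a deliberately
simplified NB pipeline: no Cox–Reid adjusted dispersion MAP, no
fold-change shrinkage, no outlier or independent filtering. The
downstream logic needs only `(log2FoldChange, p)` at nominal thresholds,
and the simplification is validated by simulation properties rather than
by output equality with any specific implementation (an independent
established implementation is used as a cross-check in the test suite).

* **Size factors** are median-of-ratios: the median over peaks of
  `count / geometric mean`, over peaks nonzero in all samples.
* **Dispersions** are method-of-moments per peak within condition,
  `max(0, (s^2 - mu)/mu^2)`, combined across conditions with
  `(n_c - 1)` weights, then shrunk toward a fitted mean–dispersion trend
  `a0 + a1/mu`. The default trend weight is 0.9: with two or three
  replicates per condition the per-peak estimate has only 2–4 degrees of
  freedom and is mostly noise, and at these design sizes strong pooling
  across peaks is what keeps the Wald p-values calibrated (measured
  type-I rate at p < 0.1 on a 10,000-peak 3v3 null: 0.17 with no
  shrinkage, 0.10 at weight 0.9). The weight is exposed for designs with
  many replicates or strongly peak-specific dispersion. Dispersions are
  floored at 1e-8.
* **Fitting** is Fisher scoring of the two-parameter model, vectorized
  across all peaks simultaneously (a closed-form 2x2 solve per peak per
  iteration), with the condition coefficient capped at |beta| = 15 nats
  so peaks that are all-zero in one condition stay finite. The standard
  error comes from the observed information at the optimum; the Wald
  statistic is `log2FC / SE` with a two-sided normal p-value. All-zero
  peaks report `baseMean = 0` and missing statistics.
* **Selection** uses nominal, unadjusted p-values — 0.1 for the 3v3
  DNase-style design and 0.2 for the 2v2 ATAC-style design, whose extra
  replicate loss inflates p-values — with the sign of the fold change
  matching the requested direction. Adjusted thresholds are exceedingly
  stringent when every peak in an RPS is tested; a BH option exists
  behind a flag.

A mathematical consequence worth stating: with calibrated p-values, the
expected false positives among selected peaks are about
`0.5 * alpha * n_null` (the direction filter halves the rate), so the
precision attainable at `p < 0.1` is bounded near
`TP / (TP + 0.05 * n_null)`. At the default planted fraction of 10%
that bound is ~0.7–0.85 depending on how conservative the test is at
low counts; precision beyond that is not achievable by *any* calibrated
test at a nominal threshold and would indicate miscalibration rather
than quality. The seeded regression tests pin recall (≥ 0.8 at planted
log2FC 2) and calibration (within 3 Monte-Carlo SE); the precision a
user should expect follows from the fraction of truly differential
peaks in their data, not from the test.

## Cross-assay merging

A differential peak from either assay joins the high-confidence
"overlapping differential" set when 75% or more of its own length is
covered by the other assay's differential peaks (non-reciprocal, both
directions evaluated); qualifying peaks from both sides are pooled and
merged. The operation is symmetric and its result is always contained in
the merged union of its inputs.

## Peak-to-gene annotation

Each peak is classified against its *closest* gene (minimal gap between
the peak interval and the gene span, distance 0 on overlap, ties to the
lexicographically smaller gene id), strand-aware, into five categories.
Writing d for the gap from the gene-oriented peak 3' end to the 5' end of
the first exon, and d' for the gap from the 3' end of the last exon to
the peak 5' end:

| category | rule |
|---|---|
| Promoter | 1 ≤ d ≤ 1,000 |
| WithinGeneBody | peak 5' end inside the gene span (subcategory exon/intron by that base) |
| Upstream | 1,000 < d ≤ 10,000 |
| Downstream | 1 ≤ d' ≤ 10,000 and no overlap |
| Distal | no portion of the peak within 10 kb of a gene |

"5'/3' end of the peak" means the peak boundary nearer the gene's 5'/3'
side, so for a minus-strand gene the roles of the peak's left and right
ends swap; a mirror-symmetry property test (reflect all coordinates,
flip all strands, categories must be unchanged) guards this. When
several rules match, precedence is Promoter > WithinGeneBody > Upstream
> Downstream > Distal; classification is only ever against the nearest
gene. A peak that engulfs its gene matches no boundary rule and is
assigned WithinGeneBody. The 10-kb proximity window is inclusive (a gap
of exactly 10,000 bp counts, where the gap is the number of bases
between the closest bases); both the window and the promoter distance
are parameters. Gene spans (not UTR-refined transcripts) define the
body; multiple transcripts of a gene are collapsed to one span on GFF3
read.

## Enrichment statistics

All enrichment tests are Fisher exact tests on 2x2 tables, two-sided, so
both enrichment and depletion are detected. **Fold enrichment is the
ratio of proportions** `(a/(a+b)) / (c/(c+d))`, not the odds ratio — the
two differ materially at the large proportions the proximity tables
produce, and the ratio-of-proportions reading matches how fold
enrichments are reported in this literature. Functional-category tests
count a gene once per category it belongs to and are Benjamini–Hochberg
adjusted across categories. Zero-margin tables are reported as missing
rather than forced.

Expression integration uses two classifiers. Temporal clusters are
assigned by the time of maximal expression: [0,10] hpf is cluster 1,
[18,24) cluster 4, [24,40) cluster 3, [40,72] cluster 2; an argmax in
the uncovered (10,18) gap is left unassigned rather than force-fit, and
ties take the earliest time. Expression classes are half-open FPKM bins:
[100, inf) high, [40,100) medium, [15,40) low, [0,15) very low. The
cluster windows are a binning proxy for what was originally a clustering
of developmental timecourses; the binning reproduces the window
definitions, not the clustering algorithm.

## Motif analysis

Scanning is log-odds against a position weight matrix with a pseudocount
mixed in proportionally to the background, both strands, every offset;
windows containing N are skipped. P-values are exact: the score matrix
is discretized to a 1/100-bit grid and the distribution of the score of
a random background word is built by dynamic programming (per-position
convolution), so `P(score >= s)` is an exact tail sum — verified in the
tests against exhaustive enumeration of all 4^6 words for 6-mers. A hit
is any window at or above the smallest score whose tail probability
meets the threshold (default 1e-4).

The two-step enrichment logic: a motif is called enriched in
differential peaks iff (i) differential sequences have significantly
more hit-containing sequences than their shuffled control
(one-sided Fisher, default alpha 0.05) and (ii) non-differential
sequences do *not* beat their own shuffled control. Step (ii) removes
motifs that are simply common in accessible chromatin. The control is a
per-sequence mononucleotide shuffle (seeded), preserving each sequence's
length and composition exactly; a dinucleotide-preserving
(Euler-path) shuffle is available behind `method = "dinucleotide"` for
sequences with strong dinucleotide structure. Presence/absence of at
least one hit per sequence is the enrichment statistic.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes,
at desk scale:

* a uniform-composition multi-scaffold genome (default 20 x 200 kb,
  GC 0.5);
* 200 non-overlapping gene models (1–5 exons, random strand), 40 of them
  labelled DE, each with an FPKM (lognormal around 40) and a Gaussian
  temporal profile whose peak time is drawn from the four cluster
  windows in proportions 104:136:155:25;
* 1,200 disjoint peaks with widths around 600 bp (giving ~18–20% genome
  coverage, matching the scale of a real RPS), 10% of them differential
  with log2 fold change 2, every differential peak placed within 10 kb
  of a DE gene;
* replicate peak calls as the master set with boundaries jittered by up
  to ±50 bp; 2 replicates per condition for the ATAC-style assay and 3
  for the DNase-style assay;
* NB counts at mean depth 200 and dispersion 0.05 with per-sample depth
  factors in [0.7, 1.3] **and a per-peak lognormal baseline strength
  (sdlog 1, mean 1)**. The baseline strength is essential: it is the
  shared signal biological replicates correlate on, and without it
  same-condition replicates of a flat landscape would be uncorrelated
  and every QC gate would (correctly) fail. Setting
  `peak_strength_sdlog = 0` restores the flat landscape for
  moment-checking tests;
* an optional read emitter (uniform placement inside peaks plus uniform
  background) targeting FRiP ~0.64, for FRiP and counting tests;
* a consensus motif site written into each differential peak with
  probability 0.6, leaving non-differential peaks untouched.

Counts are simulated at the peak level, not the read level, because the
pipeline's statistics operate on peak counts. Every generator is a pure
function of its configuration: per-stage seeds are derived from the
master seed, so any stage can be rerun independently and reruns are
byte-identical.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: Tn5 insertion and DNase cutting bias,
fragment-length structure, duplicate reads, mappability artifacts, GC
effects on counts, correlated peak co-accessibility, cell-mixture
contamination of sorted fractions, and genome-scale rarity of
differential peaks (real differential fractions are closer to 0.5% than
to the 10% planted here; the planted fraction is a test-harness choice
that keeps recall/precision estimable from hundreds rather than millions
of peaks).

## Problem sizes and numerical choices

The test suite runs the interval oracles on thousands of random
fixtures (per-base bitmaps on 2-kb domains), the differential
calibration and recovery on 10,000 peaks at 3v3, the Fisher oracle
exhaustively over all tables with total up to 26 plus random tables with
margins to 30, and motif recovery across 20 independent simulations —
sizes chosen so the full suite completes in minutes on one CPU while
keeping Monte-Carlo bands tight (3 SE at 10,000 peaks is ±0.9% on a 10%
rate). Other fixed numerical choices: motif score discretization 1/100
bit; dispersion floor 1e-8; |beta| cap 15 nats; Fisher-scoring step
clamp ±2 nats per iteration with convergence at 1e-10; read-assignment
ties to the leftmost peak; nearest-gene ties to the smaller gene id;
flat-profile cluster ties to the earliest time.

## Known limitations

* The Wald test loses power for peaks that are all-zero in one
  condition (the |beta| cap keeps them finite but the SE is large); a
  likelihood-ratio variant would handle these better.
* Median-of-ratios normalization assumes most peaks are not
  differential; designs where a large fraction of peaks move in one
  direction will bias size factors and hence fold changes.
* The annotation collapses transcripts to gene spans; promoter calls for
  genes with distant alternative first exons are approximate.
* The motif enrichment statistic (any hit per sequence, Fisher) ignores
  hit multiplicity and position, and the mononucleotide shuffle null
  ignores dinucleotide structure unless explicitly switched.
* The temporal-cluster binning assigns no cluster to profiles peaking in
  (10,18) hpf.
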