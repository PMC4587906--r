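---
title: "Variational copy-number segmentation of whole-exome read depth"
author: "vegawes package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variational copy-number segmentation of whole-exome read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegawes)
```

## The problem

Somatic copy-number variation — amplification or deletion of genomic
segments — is a central lesion class in tumor genomes. Whole-exome
sequencing (WES) covers only the targeted exons (roughly 1 % of the
genome), so copy number must be inferred from read depth over a
*sparse, irregularly spaced* set of intervals. The read depth of a
tumor sample, normalized by its matched normal, is summarized as one
log ratio per exon, and copy-number events appear as shifts in the
mean of that signal over runs of consecutive exons. The computational
task is therefore one-dimensional piecewise-constant segmentation —
but on a domain whose points are 100 bp apart in dense capture
regions and a megabase apart across capture deserts, a heterogeneity
that uniformly spaced array or whole-genome methods ignore.

## Preprocessing

For each exon $i$ with size $s_i$ bases and $RC_i$ aligned reads
(unique, primary, non-duplicate alignments, as produced by standard
per-interval depth-of-coverage tools), the average read coverage is

$$ARC_i = RC_i / s_i .$$

Coverage depends systematically on the GC fraction of the target:
it peaks at intermediate GC (roughly 35–65 %) and falls off at the
extremes. `gc_correct()` removes this bias by binned median
normalization: exons are grouped into GC bins (default 1 GC-percent
wide), and each exon's ARC is rescaled by the ratio of the global
median ARC to its bin's median ARC, so that after correction every
populated bin has the sample-wide median coverage. Bins with fewer
than 10 exons, or a zero median, are passed through unchanged —
with a 1 %-bin width that floor only matters on very small target
sets. The operation is idempotent, order-preserving and never
produces negative coverage. Correction is applied to tumor and
normal *independently*; a loess-type continuous fit would be a
reasonable alternative, but binned medians are simpler, monotone-free
and exactly idempotent, which makes their behaviour easy to audit.

The segmentation input is then, per exon,

$$LR_i = \log_2\!\left( ARC^{t}_i \,/\, ARC^{n}_i \right),$$

the log2 ratio of corrected tumor over corrected normal coverage.
Exons whose normal coverage falls below a floor (default 0.1
reads/base) or whose tumor coverage is zero have no interpretable
ratio; they are excluded from the signal and itemized in a report
rather than imputed, so downstream counts remain honest.

## The segmentation model

A chromosome's signal $u_0 \in \mathbb{R}^n$ ($n$ exons in genomic
order) is approximated by a piecewise-constant function: breakpoints
$\Gamma = \{b_1, \dots, b_{M+1}\}$ partition the exons into $M$
regions $R_1, \dots, R_M$, each fitted by its mean $u_i$. The fit
quality is the penalized least-squares energy

$$E(u, \Gamma) = \sum_{i=1}^{M} \sum_{j \in R_i} (u_{0,j} - u_i)^2
  \; + \; \lambda M ,$$

the one-dimensional piecewise-constant specialization of the
Mumford–Shah functional: residual error plus a price $\lambda$ per
region. Removing the breakpoint between adjacent regions $R_i$ and
$R_{i+1}$ raises the residual term by exactly

$$\hat\lambda_i^{(0)} \;=\;
  \frac{|R_i||R_{i+1}|}{|R_i| + |R_{i+1}|}\,(u_i - u_{i+1})^2$$

while saving one penalty $\lambda$, so the energy change of a merge
is $\hat\lambda_i^{(0)} - \lambda$. This identity drives both the
algorithm and its bookkeeping tests.

### The distance-aware merge cost

Exome data add one more consideration: two adjacent regions with
similar exon density are more plausibly one biological segment than
two regions whose densities differ wildly (a dense cluster abutting a
capture desert). Each region carries its *local average inter-exon
distance*,

$$d_i = \frac{1}{|R_i|} \sum_{j=\mathrm{first}}^{\mathrm{last}-1}
  |m_j - m_{j+1}| ,$$

the summed gaps between consecutive exon midpoints $m_j$ divided by
the number of exons in the region. Note the normalization is by the
exon count $|R_i|$, not the gap count $|R_i| - 1$; that per-exon
convention is adopted as the definition of the statistic here, and
singleton regions take $d_i = 0$. The full merge cost is

$$\hat\lambda_i = \hat\lambda_i^{(0)}
  + \alpha \, \log \max(|d_i - d_{i+1}|,\; \delta),$$

with the natural logarithm (any base change is absorbed into
$\alpha$) and a clamp $\delta$ (default $10^{-6}$ bp) that keeps the
cost finite when the two densities coincide. Similar densities make
the log term small or negative — cheaper merges — while a density
mismatch makes merging more expensive. The cost may be negative;
such pairs simply merge immediately at any $\lambda \ge 0$. With
$\alpha = 0$ the term vanishes and the algorithm is the classical
length/contrast merge used for uniformly spaced array data, which is
also the mode every coordinate-independent test uses.

### The merge schedule and stopping rule

`segment_chromosome()` starts from $n$ singleton regions and
$\lambda = 0$ and repeats:

1. find the adjacent pair with the smallest $\hat\lambda_i$
   (leftmost on ties, for determinism);
2. if $\hat\lambda_i < \lambda$, merge it — the merged region's mean
   is the length-weighted mean of its children and $d$ is recomputed
   over the merged span — and update the two affected neighbour
   costs;
3. otherwise advance $\lambda$ to $\min_i \hat\lambda_i + \varepsilon$
   (default $\varepsilon = 10^{-12}$) and record the advance.

The recorded $\lambda$ sequence is non-decreasing, since each advance
chases the current minimum pending cost. Merging stops when one
region remains, or when the *gap* between consecutive recorded
advances exceeds $\beta \nu$, where $\nu$ is the total variability of
the chromosome's signal and $\beta$ defaults to 0.5 (useful range
0.5–0.7): once the next merge would cost an order of the signal's own
variance more than the last one, further merging no longer buys a
commensurate energy decrease. Two boundary conventions matter and are
deliberate:

* $\nu$ is the sample variance of the raw per-chromosome log-ratio
  vector, computed before any other processing; a robust alternative
  (squared MAD) can be substituted by pre-scaling $\beta$.
* the first advance from the initial $\lambda = 0$ is never tested
  against the stop rule — the test applies between *recorded*
  advances. A constant signal (variance 0) therefore still collapses
  to a single region instead of stopping before its first merge.

The returned object records the region table, breakpoints, the
$\lambda$ trace, $\nu$, and `final_lambda`, the last recorded
advance, which is the regularization the returned partition was
fitted at.

The merge loop touches only the two neighbours of a merged pair, so
one chromosome costs $O(n)$ per sweep of the pending-cost vector and
in practice about 30 ms for 1,000 exons; a whole exome segments in
seconds.

### Validation against an exact minimizer

`dp_segment()` is an $O(n^2)$ dynamic program that computes the
*global* minimum of the energy at a fixed $\lambda$ (ties broken
toward fewer regions, then leftmost breakpoints); it is itself
validated against exhaustive enumeration of all $2^{n-1}$ partitions
at $n \le 10$. The test suite checks, on hundreds of fixed-seed
signals of up to 30 exons, that the greedy energy at `final_lambda`
is never below the DP optimum, and that it *equals* the optimum on
piecewise-constant signals whose level contrast is well above the
noise. One caveat is documented rather than hidden: on a few percent
of noisy step signals the DP attains an $O(\sigma^2)$-lower energy by
splitting a constant run at the greedy's final $\lambda$ — in every
such case flagged by the suite the greedy partition coincides with
the true step partition, so the difference is the global minimizer
overfitting noise, not a missed structure. Equality is exact in the
noiseless limit.

## Classification

Segments are labelled by their mean log ratio with strict
inequalities: amplified above 0.35, deleted below −0.25, normal
otherwise (boundary values are normal). These are the conventional
single-copy gain/loss thresholds for tumor/normal log2 ratios; both
are exposed as parameters.

## The synthetic benchmark generator

`simulate_chromosome()` emulates the standard synthetic design for
exome CNV benchmarking: chromosomes of 1,000 exons carrying $g$
altered genes of $N$ consecutive exons, consecutive genes at least
$D$ bp apart, with the full grid $g \in \{2, 5\}$, $N \in \{5, 20\}$,
$D \in \{10^4, 10^6\}$ for both amplification and deletion and 100
replicate chromosomes per condition (`simulate_benchmark_suite()`).
Signals are parametric: baseline exons draw
$\mathcal{N}(0, \sigma^2)$ noise and altered exons are shifted by a
constant — defaults $+\log_2(3/2) \approx 0.585$ (one copy gained on
a diploid background) and $-1$ (one copy lost), with $\sigma = 0.2$,
a mid-range figure for tumor/normal WES log ratios. Exons are 352 bp
(a typical mean capture-target size) with baseline gaps drawn
log-uniformly between 100 bp and 10 kb, reproducing the
density heterogeneity the distance term is designed for; the gap
upstream of each gene is widened as needed to enforce $D$. Everything
is reproducible from one integer seed, and replicate seeds are
derived deterministically from a master seed.

What the generator does *not* emulate: real capture noise is not
i.i.d. Gaussian — it has heavy tails, GC- and batch-correlated
waviness, and exon-to-exon variance that scales with coverage.
Passing the synthetic benchmark therefore demonstrates correct
recovery of the designed signal class (and exact breakpoint recovery
in the noiseless limit), not sample-level performance on real tumors,
which additionally depends on purity, ploidy and capture quality.

## Evaluation

Two complementary protocols, both at exon resolution because an
exon is the smallest unit the data type can resolve:

* **ROC/AUC** for the synthetic benchmark: every exon inherits its
  region's fitted mean (`exon_level_lr()`); a threshold sweep over
  the distinct fitted values yields TPR (altered exons called
  altered over all altered) and FPR (unaltered exons called altered
  over all unaltered), with the signal negated for deletion events so
  one sweep convention covers both. The trapezoidal AUC equals the
  tie-aware Mann–Whitney statistic, which the tests verify by brute
  force and against an independent ROC implementation.
* **Precision/recall/f-score** against SNP-array-style truth
  segments: each exon takes its called (label, log ratio) from the
  covering call segment and its truth pair from the truth segment
  covering its midpoint, classified with the same thresholds. An
  exon is a true positive when the labels agree *or* the two log
  ratios differ by at most 0.15 (inclusive; the comparison carries a
  $10^{-12}$ guard against decimal round-off). Precision and recall
  are reported separately for gains and losses; the f-score is the
  harmonic mean of the pooled precision and recall. Empty
  denominators report 0 with a warning rather than NaN, exons
  covered by no truth segment are excluded and counted, and
  per-chromosome results aggregate by unweighted mean
  (`aggregate_metrics()`), treating each unit equally regardless of
  its exon count.

## Degenerate inputs and numerical conventions

* empty signals, non-finite log ratios, inverted thresholds and
  mismatched vector lengths fail fast with named rows;
* single-exon chromosomes return one region and an empty
  $\lambda$ trace;
* cost ties merge the leftmost pair; DP ties prefer fewer regions;
* region statistics are maintained by prefix sums, so merged means
  and distances are exact to floating precision (the bookkeeping
  tests assert the energy identity to $10^{-9}$);
* coordinates are BED-convention 0-based half-open throughout, and
  midpoints $(start + end)/2$ may be half-integers.

## Problem sizes used by the test and acceptance suites

The shipped validation runs the full 16-condition benchmark at its
native size (100 chromosomes × 1,000 exons per condition — the
design is small enough that nothing needs scaling down), 200
fixed-seed DP-oracle comparisons at $n \le 30$, 20
enumeration-vs-DP checks at $n \le 10$, and a 360-exon engineered
GC-bias fixture; the whole suite completes in well under a minute.

## Known limitations

* Greedy merging is not a global minimizer; see the caveat above.
* No purity/ploidy correction and no probabilistic genotyping of the
  called states: labels are threshold calls on segment means.
* Single-sample (pair) analysis only; no joint multi-sample
  segmentation.
* The pipeline consumes per-exon count/coverage tables; alignment,
  duplicate marking and count extraction are upstream concerns.
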