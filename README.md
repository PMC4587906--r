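# vegawes

Copy-number variation (CNV) detection from whole-exome sequencing
(WES) read depth of paired tumor/normal samples, built around a
variational, bottom-up region-merging segmentation algorithm that is
aware of the irregular spacing of exome capture targets.

**Who it is for:** anyone with per-exon read counts or coverage for a
tumor and its matched normal (e.g. from GATK `DepthOfCoverage`-style
per-interval output) who wants segmented log2-ratio profiles and
amplified/deleted/normal calls — plus a fully synthetic benchmark for
validating the caller without any external data.

## The model

The per-exon signal is the GC-corrected log2 ratio
`LR_i = log2(ARC_t / ARC_n)` of tumor over normal average read
coverage (`ARC_i = RC_i / s_i`, reads per base). A chromosome's
signal `u0` of `n` exons is fitted by a piecewise-constant function:
breakpoints `Γ = {b1, …, b_{M+1}}` define `M` regions `R_i`, each
represented by its mean `u_i`, minimizing the one-dimensional
piecewise-constant Mumford–Shah energy

    E(u, Γ) = Σ_i Σ_{j ∈ R_i} (u0_j − u_i)²  +  λ M .

Segmentation proceeds bottom-up from `n` singleton regions: the
adjacent pair with the cheapest merge cost

    λ̂_i = |R_i||R_{i+1}| / (|R_i| + |R_{i+1}|) · (u_i − u_{i+1})²
          + α · log max(|d_i − d_{i+1}|, δ)

is merged whenever `λ̂_i < λ`; otherwise `λ` advances to
`min λ̂_i + ε`. Here `d_i` is the region's local average inter-exon
distance (mean gap between consecutive exon midpoints, normalized by
the exon count), so regions of similar capture density merge cheaply
while a density mismatch resists merging — the exome-specific term,
weighted by `α` (default 0.001; `α = 0` recovers the classical
length/contrast merge cost for uniformly spaced data). Merging stops
once the gap between consecutive `λ` advances exceeds `β·ν`
(`β = 0.5`, `ν` = variance of the chromosome's signal), i.e. when
further merging no longer buys a commensurate energy decrease.
Segments are then called amplified (`mean LR > 0.35`), deleted
(`< −0.25`) or normal.

An exact `O(n²)` dynamic-programming minimizer of the same energy
(`dp_segment()`) ships alongside the greedy algorithm purely for
validation.

## Worked example

Simulate one synthetic chromosome (1,000 exons, two amplified genes
of 20 exons each, log-ratio shift `log2(3/2) ≈ 0.585`, noise sd 0.2),
segment it, call it, and score it against its own truth:

```r
library(vegawes)

cfg <- simulation_config(g = 2, gene_length_exons = 20,
                         event = "amplification")
sim <- simulate_chromosome(cfg, seed = 7)
fit <- segment_chromosome(sim$lr)
calls <- classify_segments(fit)
calls[, c("start", "end", "n_exons", "seg_mean", "call")]
#>      start     end n_exons seg_mean      call
#> 1        0  743437     292 -0.00557    normal
#> 2   746242  760389       8 -0.25144   deleted
#> 3   760860  897209      55 -0.02611    normal
#> 4   897563  954403      21  0.54283 amplified
#> 5   955121 1725269     305 -0.00604    normal
#> 6  1725395 1764746      20  0.57309 amplified
#> 7  1764896 1788168      13  0.08087    normal
#> 8  1790030 1790382       1  0.80507 amplified
#> 9  1799866 2080623     106 -0.03525    normal
#> 10 2083395 2083747       1  0.66548 amplified
#> 11 2084326 2529481     178 -0.00868    normal

precision_recall_fscore(calls, sim$truth, exons = sim$targets)
#> precision (gain): 0.9302   recall (gain): 1.0000
#> precision (loss): 0.0000   recall (loss): 0.0000
#> f-score: 0.8791   (0 exon(s) excluded)

roc_auc(exon_level_lr(fit), sim$truth_mask, "amplification")
#> [1] 0.9977
```

Both simulated 20-exon amplifications are recovered at essentially
their true boundaries and close to the injected shift (segments 4
and 6; segment 4 absorbs one flanking noise exon). The remaining
non-normal calls illustrate how threshold calling behaves on noisy
means: two singleton exons whose noise exceeded 0.35, and one 8-exon
run whose mean dipped just below −0.25. At exon resolution that
yields perfect amplification recall, 0.93 amplification precision
and an AUC of 0.998; the loss-side scores are 0 (with a warning)
because this chromosome contains no true deletion. The same pipeline
runs from the shell:

```sh
vegawes simulate --g 2 --N 20 --D 10000 --event amplification \
    --seed 7 --out sim/
vegawes run --lr sim/lr.tsv --truth sim/truth.tsv --out results/
```

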