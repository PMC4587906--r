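# Fixtures and independent oracles shared across the test files.
# Everything is built in code; no stored data.

# A simple sorted exon table: n exons of the given size spaced by `gap`.
make_targets <- function(n, chrom = "chr1", size = 100, gap = 100,
                         gc = NULL) {
  start <- (seq_len(n) - 1L) * (size + gap)
  if (is.null(gc)) gc <- rep(0.5, n)
  data.frame(chrom = chrom, start = start, end = start + size,
             name = sprintf("e%03d", seq_len(n)), gc = gc)
}

# Piecewise-constant signal with Gaussian noise.
make_step_signal <- function(lens, levels, sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rep(levels, lens) + stats::rnorm(sum(lens), 0, sd)
}

# Independent oracle for the optimal segmentation energy: exhaustive
# enumeration of all 2^(n-1) partitions (n <= ~12).
enumerate_min_energy <- function(lr, lam) {
  n <- length(lr)
  stopifnot(n <= 14)
  best <- Inf
  for (m in 0:(2^(n - 1) - 1)) {
    cuts <- if (n > 1) which(bitwAnd(m, 2^(0:(n - 2))) > 0) else integer(0)
    firsts <- c(1L, cuts + 1L)
    lasts <- c(cuts, n)
    e <- lam * length(firsts)
    for (k in seq_along(firsts)) {
      v <- lr[firsts[k]:lasts[k]]
      e <- e + sum((v - mean(v))^2)
    }
    if (e < best) best <- e
  }
  best
}

# Independent AUC oracle: normalized Mann-Whitney U with ties counted
# one half.
mann_whitney_auc <- function(score, truth) {
  pos <- score[truth]
  neg <- score[!truth]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Replay a recorded merge log, recomputing the full energy before and
# after every merge; returns a data.frame of observed vs predicted
# energy changes.
replay_merges <- function(seg) {
  log <- seg$merge_log
  n <- length(seg$lr)
  firsts <- seq_len(n)  # current partition as sorted region starts
  out <- data.frame(observed = numeric(nrow(log)),
                    predicted = numeric(nrow(log)))
  part_energy <- function(firsts, lam) {
    lasts <- c(firsts[-1L] - 1L, n)
    segmentation_energy(data.frame(first = firsts, last = lasts),
                        lambda = lam, lr = seg$lr)
  }
  for (k in seq_len(nrow(log))) {
    lam <- log$lambda[k]
    e_before <- part_energy(firsts, lam)
    firsts <- setdiff(firsts, log$left_last[k] + 1L)
    e_after <- part_energy(firsts, lam)
    out$observed[k] <- e_after - e_before
    out$predicted[k] <- log$cost[k] - lam
  }
  out
}

# Coverage fixture with an engineered multiplicative GC bias:
# `n_per_bin` exons in each of the given GC percent bins, true
# coverage `base`, observed coverage base * bias(gc).
make_gc_biased_coverage <- function(gc_percents = seq(35, 64, by = 1),
                                    n_per_bin = 12, base = 2,
                                    seed = 11) {
  set.seed(seed)
  gc <- rep(gc_percents, each = n_per_bin) / 100
  n <- length(gc)
  ord <- sample.int(n)  # shuffle so bins are not contiguous
  gc <- gc[ord]
  bias <- 1.5 - abs(gc - 0.5)  # coverage peaks at mid GC
  targets <- make_targets(n, gc = gc)
  cov <- compute_arc(round(base * bias * 100), targets)
  cov
}
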