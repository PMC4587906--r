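#' Per-exon log ratio implied by a segmentation
#'
#' Every exon inherits the mean log ratio of the region that contains
#' it, giving the piecewise-constant fitted signal at exon resolution.
#'
#' @param seg A `vegawes_segmentation` (or a `data.frame` of regions
#'   with `first`, `last`/`n_exons`, `mean_lr`).
#' @return Numeric vector, one value per exon.
#' @export
exon_level_lr <- function(seg) {
  regions <- if (inherits(seg, "vegawes_segmentation")) seg$regions
             else as.data.frame(seg)
  if (is.null(regions) || nrow(regions) == 0L) {
    stop("exon_level_lr: segmentation has no regions")
  }
  n_exons <- if (!is.null(regions$n_exons)) regions$n_exons
             else regions$last - regions$first + 1L
  rep(regions$mean_lr, n_exons)
}

#' Exon-level ROC curve for a synthetic benchmark
#'
#' Sweeps a log-ratio threshold over the distinct segmented exon
#' values and reports, at each threshold, the true positive rate
#' (altered exons whose segmented value lies above the threshold, over
#' all altered exons) and the false positive rate (unaltered exons
#' above the threshold, over all unaltered exons). For deletion events
#' the signal is negated first, so "above the threshold" uniformly
#' means "called altered". The curve includes the (0,0) and (1,1)
#' endpoints; the trapezoidal area under it (equal to the normalized
#' Mann-Whitney U statistic, ties counted half) is attached as the
#' `auc` attribute.
#'
#' @param seg_lr Numeric vector of segmented per-exon log ratios
#'   (see [exon_level_lr()]).
#' @param truth_mask Logical vector, `TRUE` for exons inside altered
#'   regions; must contain both classes.
#' @param event `"amplification"` or `"deletion"`.
#' @return A `data.frame` with columns `threshold`, `fpr`, `tpr` and
#'   attribute `auc`; see also [roc_auc()].
#' @export
roc_curve <- function(seg_lr, truth_mask,
                      event = c("amplification", "deletion")) {
  event <- match.arg(event)
  truth_mask <- as.logical(truth_mask)
  if (length(seg_lr) != length(truth_mask)) {
    stop("roc_curve: seg_lr and truth_mask lengths differ")
  }
  if (!any(truth_mask) || all(truth_mask)) {
    stop("roc_curve: truth_mask must contain both altered and ",
         "unaltered exons")
  }
  score <- if (event == "deletion") -seg_lr else seg_lr

  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  pos <- truth_mask[ord]
  n_pos <- sum(pos)
  n_neg <- length(pos) - n_pos
  # last index of each distinct score value
  grp_end <- which(!duplicated(s, fromLast = TRUE))
  tpr <- cumsum(pos)[grp_end] / n_pos
  fpr <- cumsum(!pos)[grp_end] / n_neg
  curve <- data.frame(threshold = c(s[1L], s[grp_end]),
                      fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                utils::tail(curve$tpr, -1)) / 2)
  attr(curve, "auc") <- auc
  curve
}

#' Area under an exon-level ROC curve
#' @inheritParams roc_curve
#' @return The trapezoidal AUC (scalar in `[0, 1]`).
#' @export
roc_auc <- function(seg_lr, truth_mask,
                    event = c("amplification", "deletion")) {
  attr(roc_curve(seg_lr, truth_mask, event), "auc")
}

#' Exon-level precision, recall and f-score against ground truth
#'
#' Scores calls against SNP-array-style truth segments at exon
#' resolution. Every evaluated exon gets a called label and log ratio
#' from the segment that contains it, and a truth label and log ratio
#' from the truth segment covering its midpoint (classified with the
#' same thresholds). An exon is a true positive when the two labels
#' agree, or when the called and truth log ratios differ by at most
#' `lr_tolerance` (boundary inclusive). Then, per event type,
#' precision is the fraction of true positives among the exons the
#' algorithm called amplified (resp. deleted), and recall the fraction
#' among the exons the truth labels amplified (resp. deleted). The
#' f-score is the harmonic mean of the pooled (gain + loss) precision
#' and recall. Empty denominators yield 0 with a warning. Exons not
#' covered by any truth (or call) segment are excluded and counted in
#' the report.
#'
#' @param calls Called segments: a `data.frame` with `chrom`, `start`,
#'   `end`, `seg_mean` (e.g. from [classify_segments()] or
#'   [segment_genome()]).
#' @param truth Truth segments `chrom start end lr`
#'   (see [read_truth()]).
#' @param exons Exon table with `chrom`, `start`, `end` giving the
#'   evaluation resolution (e.g. the targets or the log-ratio table).
#' @param lr_tolerance Log-ratio agreement tolerance (default 0.15).
#' @param amp_threshold,del_threshold Classification thresholds
#'   applied to both calls and truth (defaults 0.35 / -0.25).
#' @return A list of class `vegawes_metrics`: `precision_gain`,
#'   `recall_gain`, `precision_loss`, `recall_loss`, `fscore`,
#'   `counts` (the underlying exon tallies) and `n_excluded`.
#' @export
precision_recall_fscore <- function(calls, truth, exons,
                                    lr_tolerance = 0.15,
                                    amp_threshold = 0.35,
                                    del_threshold = -0.25) {
  stopifnot(lr_tolerance >= 0, del_threshold < amp_threshold)
  mid <- exon_midpoints(exons)
  call_lr <- lookup_segment_lr(exons$chrom, mid, calls,
                               value_col = "seg_mean")
  truth_lr <- lookup_segment_lr(exons$chrom, mid, truth,
                                value_col = "lr")
  covered <- !is.na(call_lr) & !is.na(truth_lr)
  if (!any(covered)) {
    stop("precision_recall_fscore: no exon is covered by both calls ",
         "and truth")
  }
  n_excluded <- sum(!covered)
  call_lr <- call_lr[covered]
  truth_lr <- truth_lr[covered]

  call_lab <- call_label(call_lr, amp_threshold, del_threshold)
  truth_lab <- call_label(truth_lr, amp_threshold, del_threshold)
  # boundary inclusive, guarded against binary round-off of decimal
  # log-ratio differences
  tp <- call_lab == truth_lab |
    abs(call_lr - truth_lr) <= lr_tolerance + 1e-12

  frac <- function(num, den, what) {
    if (den == 0L) {
      warning("precision_recall_fscore: no exons for ", what,
              "; reporting 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  counts <- list(
    tp_called_amp = sum(tp & call_lab == "amplified"),
    called_amp = sum(call_lab == "amplified"),
    tp_truth_amp = sum(tp & truth_lab == "amplified"),
    truth_amp = sum(truth_lab == "amplified"),
    tp_called_del = sum(tp & call_lab == "deleted"),
    called_del = sum(call_lab == "deleted"),
    tp_truth_del = sum(tp & truth_lab == "deleted"),
    truth_del = sum(truth_lab == "deleted"))

  precision_gain <- frac(counts$tp_called_amp, counts$called_amp,
                         "precision (gain)")
  recall_gain <- frac(counts$tp_truth_amp, counts$truth_amp,
                      "recall (gain)")
  precision_loss <- frac(counts$tp_called_del, counts$called_del,
                         "precision (loss)")
  recall_loss <- frac(counts$tp_truth_del, counts$truth_del,
                      "recall (loss)")

  pooled_p <- frac(counts$tp_called_amp + counts$tp_called_del,
                   counts$called_amp + counts$called_del,
                   "pooled precision")
  pooled_r <- frac(counts$tp_truth_amp + counts$tp_truth_del,
                   counts$truth_amp + counts$truth_del,
                   "pooled recall")
  fscore <- if (pooled_p + pooled_r == 0) 0 else {
    2 * pooled_p * pooled_r / (pooled_p + pooled_r)
  }

  structure(list(precision_gain = precision_gain,
                 recall_gain = recall_gain,
                 precision_loss = precision_loss,
                 recall_loss = recall_loss,
                 fscore = fscore, counts = counts,
                 n_excluded = n_excluded),
            class = "vegawes_metrics")
}

#' @export
print.vegawes_metrics <- function(x, ...) {
  cat(sprintf("precision (gain): %.4f   recall (gain): %.4f\n",
              x$precision_gain, x$recall_gain))
  cat(sprintf("precision (loss): %.4f   recall (loss): %.4f\n",
              x$precision_loss, x$recall_loss))
  cat(sprintf("f-score: %.4f   (%d exon(s) excluded)\n",
              x$fscore, x$n_excluded))
  invisible(x)
}

#' Average metrics over chromosomes or samples
#'
#' Unweighted mean of each metric over a list of
#' [precision_recall_fscore()] results (one per chromosome or per
#' sample).
#'
#' @param metrics_list List of `vegawes_metrics`.
#' @return A named numeric vector of averaged metrics.
#' @export
aggregate_metrics <- function(metrics_list) {
  fields <- c("precision_gain", "recall_gain", "precision_loss",
              "recall_loss", "fscore")
  vapply(fields, function(f) {
    mean(vapply(metrics_list, function(m) m[[f]], numeric(1)))
  }, numeric(1))
}

# For each exon midpoint, the value of the segment containing it on
# the same chromosome (NA when uncovered). Half-open intervals:
# start <= mid < end.
lookup_segment_lr <- function(chrom, mid, segments, value_col) {
  out <- rep(NA_real_, length(mid))
  for (ch in unique(chrom)) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    if (nrow(seg) == 0L) next
    seg <- seg[order(seg$start), , drop = FALSE]
    sel <- which(chrom == ch)
    idx <- findInterval(mid[sel], seg$start)
    ok <- idx >= 1L & mid[sel] < c(seg$end, -Inf)[pmax(idx, 1L)]
    out[sel[ok]] <- seg[[value_col]][idx[ok]]
  }
  out
}
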