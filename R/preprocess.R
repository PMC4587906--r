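#' Average read coverage per exon
#'
#' Converts per-exon read counts into average read coverage (ARC):
#' `arc_i = rc_i / s_i`, where `s_i = end_i - start_i` is the exon size
#' in bases. This is the per-interval depth statistic produced by
#' standard depth-of-coverage tools; counts are assumed to come from
#' reads that survived mappability filtering upstream (unique, primary,
#' non-duplicate alignments).
#'
#' @param counts Numeric vector of non-negative read counts, aligned
#'   1:1 with `targets` rows.
#' @param targets Exon target `data.frame` (see [read_targets()]).
#' @return A coverage `data.frame`: the target columns plus `rc` and
#'   `arc`.
#' @examples
#' t <- data.frame(chrom = "chr1", start = 0, end = 200,
#'                 name = "e1", gc = 0.5)
#' compute_arc(100, t)$arc  # 0.5 reads per base
#' @export
compute_arc <- function(counts, targets) {
  targets <- validate_targets(targets)
  if (length(counts) != nrow(targets)) {
    stop("compute_arc: ", length(counts), " counts for ",
         nrow(targets), " targets")
  }
  if (any(counts < 0)) stop("compute_arc: negative read count")
  size <- targets$end - targets$start
  if (any(size < 1)) stop("compute_arc: zero-length exon")
  cov <- targets
  cov$rc <- as.numeric(counts)
  cov$arc <- cov$rc / size
  cov
}

#' GC-bias correction by binned median normalization
#'
#' Exons are grouped into GC bins of `bin_width` GC-percent; the ARC of
#' every exon in a bin is rescaled by (global median ARC) / (bin median
#' ARC), so that after correction every populated bin has the same
#' median coverage as the whole sample. Bins with fewer than
#' `min_bin_size` exons, or with a zero median, are passed through
#' uncorrected. The operation is idempotent and preserves exon order.
#'
#' Correction is applied to each sample (tumor, normal) independently.
#'
#' @param coverage Coverage `data.frame` with a `gc` column
#'   (see [compute_arc()]).
#' @param bin_width GC bin width in GC-percent (default 1).
#' @param min_bin_size Minimum exons per bin for correction
#'   (default 10).
#' @return The coverage `data.frame` with corrected `arc` (and an
#'   `arc_raw` column holding the input values).
#' @export
gc_correct <- function(coverage, bin_width = 1, min_bin_size = 10) {
  if (is.null(coverage$gc)) stop("gc_correct: coverage has no gc column")
  if (any(!is.finite(coverage$gc)) ||
      any(coverage$gc < 0) || any(coverage$gc > 1)) {
    stop("gc_correct: gc must be a finite fraction in [0, 1]")
  }
  arc <- coverage$arc
  if (all(arc == 0)) {
    stop("gc_correct: all ARC values are zero; no usable median")
  }
  bin <- floor(coverage$gc * 100 / bin_width)
  global_med <- stats::median(arc)
  bin_med <- tapply(arc, bin, stats::median)
  bin_n <- tapply(arc, bin, length)
  factor <- global_med / bin_med
  factor[bin_n < min_bin_size | bin_med == 0] <- 1
  out <- coverage
  if (is.null(out$arc_raw)) out$arc_raw <- arc
  out$arc <- arc * as.numeric(factor[as.character(bin)])
  out
}

#' Log2 tumor/normal coverage ratio per exon
#'
#' `lr_i = log2(arc_t_i / arc_n_i)` for exons whose normal-sample
#' coverage reaches `min_normal_arc` and whose tumor coverage is
#' positive; the remaining exons are excluded from the signal and
#' returned in a report. Tumor and normal must cover the same targets
#' in the same order.
#'
#' @param tumor,normal Coverage `data.frame`s over identical targets.
#' @param min_normal_arc Minimum normal-sample ARC (reads per base) for
#'   an exon to be kept (default 0.1).
#' @return A list with `lr` (log-ratio `data.frame`
#'   `chrom start end name lr`) and `excluded` (the dropped exons with
#'   a `reason` column).
#' @export
compute_lr <- function(tumor, normal, min_normal_arc = 0.1) {
  key_cols <- c("chrom", "start", "end")
  if (nrow(tumor) != nrow(normal) ||
      !isTRUE(all.equal(tumor[key_cols], normal[key_cols],
                        check.attributes = FALSE))) {
    stop("compute_lr: tumor and normal must cover the same targets ",
         "in the same order")
  }
  low_normal <- normal$arc < min_normal_arc
  zero_tumor <- tumor$arc <= 0
  keep <- !(low_normal | zero_tumor)

  lr <- tumor[keep, c("chrom", "start", "end", "name")]
  lr$lr <- log2(tumor$arc[keep] / normal$arc[keep])
  lr <- sort_by_position(lr)

  excluded <- tumor[!keep, c("chrom", "start", "end", "name")]
  excluded$reason <- ifelse(low_normal[!keep], "low_normal_arc",
                            "zero_tumor_arc")
  rownames(excluded) <- NULL
  list(lr = lr, excluded = excluded)
}

#' Full preprocessing of a tumor/normal coverage pair
#'
#' GC-corrects each sample independently, then computes the per-exon
#' log2 ratio signal.
#'
#' @inheritParams compute_lr
#' @inheritParams gc_correct
#' @param gc_correction Apply GC correction first (default `TRUE`;
#'   requires a `gc` column).
#' @return As [compute_lr()].
#' @export
preprocess_pair <- function(tumor, normal, gc_correction = TRUE,
                            bin_width = 1, min_bin_size = 10,
                            min_normal_arc = 0.1) {
  if (gc_correction) {
    tumor <- gc_correct(tumor, bin_width, min_bin_size)
    normal <- gc_correct(normal, bin_width, min_bin_size)
  }
  compute_lr(tumor, normal, min_normal_arc = min_normal_arc)
}
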