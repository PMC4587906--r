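#' Classify segments as amplified, deleted or normal
#'
#' A segment is called amplified when its mean log ratio lies strictly
#' above `amp_threshold`, deleted when strictly below `del_threshold`,
#' and normal otherwise (boundary values are normal). The defaults
#' 0.35 / -0.25 are the conventional single-copy gain/loss calling
#' thresholds for tumor/normal log2 ratios.
#'
#' @param seg A `vegawes_segmentation`, a SEG `data.frame` with a
#'   `seg_mean` column, or a bare numeric vector of segment means.
#' @param amp_threshold Amplification threshold (default 0.35).
#' @param del_threshold Deletion threshold (default -0.25).
#' @return For a `data.frame` input, the same `data.frame` with a
#'   `call` column (`"amplified"`, `"deleted"`, `"normal"`); for a
#'   segmentation object, its regions as a SEG-style `data.frame` with
#'   the `call` column; for a numeric vector, a character vector.
#' @export
classify_segments <- function(seg, amp_threshold = 0.35,
                              del_threshold = -0.25) {
  if (!(del_threshold < amp_threshold)) {
    stop("classify_segments: del_threshold must be below amp_threshold")
  }
  if (inherits(seg, "vegawes_segmentation")) {
    r <- seg$regions
    r$seg_mean <- r$mean_lr
    r$call <- call_label(r$seg_mean, amp_threshold, del_threshold)
    return(r)
  }
  if (is.data.frame(seg)) {
    if (is.null(seg$seg_mean)) {
      stop("classify_segments: data.frame needs a seg_mean column")
    }
    seg$call <- call_label(seg$seg_mean, amp_threshold, del_threshold)
    return(seg)
  }
  call_label(as.numeric(seg), amp_threshold, del_threshold)
}

call_label <- function(seg_mean, amp_threshold, del_threshold) {
  ifelse(seg_mean > amp_threshold, "amplified",
         ifelse(seg_mean < del_threshold, "deleted", "normal"))
}
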