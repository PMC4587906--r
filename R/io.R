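#' Read an exon target table
#'
#' Targets are BED-convention intervals (0-based, half-open) with a GC
#' fraction per exon, as a headered TSV with columns
#' `chrom  start  end  name  gc`.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `gc`, validated and sorted by position within each chromosome.
#' @export
read_targets <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "name", "gc"))
  validate_targets(df)
}

#' Write an exon target table
#' @param targets Target `data.frame` (see [read_targets()]).
#' @param path Output path.
#' @export
write_targets <- function(targets, path) {
  write_tsv(targets[, c("chrom", "start", "end", "name", "gc")], path)
}

#' Read a per-exon coverage table
#'
#' One sample's per-exon read counts and average read coverage, as a
#' headered TSV with columns `chrom  start  end  name  gc  rc  arc`
#' (`gc` optional).
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of per-exon coverage.
#' @export
read_coverage <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "name", "rc", "arc"))
  if (any(df$rc < 0) || any(df$arc < 0)) {
    stop("coverage table '", path, "': rc and arc must be non-negative")
  }
  df
}

#' Write a per-exon coverage table
#' @param coverage Coverage `data.frame` (see [read_coverage()]).
#' @param path Output path.
#' @export
write_coverage <- function(coverage, path) {
  keep <- intersect(c("chrom", "start", "end", "name", "gc", "rc", "arc"),
                    names(coverage))
  write_tsv(coverage[, keep], path)
}

#' Read a per-exon log-ratio table
#'
#' @param path Path to a headered TSV `chrom  start  end  name  lr`.
#' @return A validated log-ratio `data.frame` sorted by position.
#' @export
read_lr <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "name", "lr"))
  bad <- which(!is.finite(df$lr))
  if (length(bad)) {
    stop("log-ratio table '", path, "': non-finite lr at row ",
         bad[1L], " (", df$chrom[bad[1L]], ":", df$start[bad[1L]], ")")
  }
  sort_by_position(df)
}

#' Write a per-exon log-ratio table
#' @param lr Log-ratio `data.frame` (see [read_lr()]).
#' @param path Output path.
#' @export
write_lr <- function(lr, path) {
  write_tsv(lr[, c("chrom", "start", "end", "name", "lr")], path)
}

#' Read a SEG-style segment table
#'
#' @param path Path to a headered TSV
#'   `sample  chrom  start  end  num_exons  seg_mean`.
#' @return A `data.frame` of segments.
#' @export
read_seg <- function(path) {
  read_tsv_checked(path, c("sample", "chrom", "start", "end",
                           "num_exons", "seg_mean"))
}

#' Write a SEG-style segment table
#' @param seg Segment `data.frame` (see [read_seg()]); a `call` column,
#'   if present, is kept.
#' @param path Output path.
#' @export
write_seg <- function(seg, path) {
  keep <- intersect(c("sample", "chrom", "start", "end", "num_exons",
                      "seg_mean", "call"), names(seg))
  write_tsv(seg[, keep], path)
}

#' Read a ground-truth segment table
#'
#' SNP-array-style truth segments: a headered TSV
#' `chrom  start  end  lr`, non-overlapping and sorted per chromosome.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of truth segments.
#' @export
read_truth <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "lr"))
  df <- sort_by_position(df)
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)])) {
      stop("truth table '", path, "': overlapping segments on ", ch)
    }
  }
  df
}

#' Write a ground-truth segment table
#' @param truth Truth `data.frame` (see [read_truth()]).
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  write_tsv(truth[, c("chrom", "start", "end", "lr")], path)
}

## internal helpers ---------------------------------------------------------

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("'", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

sort_by_position <- function(df) {
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

validate_targets <- function(targets) {
  stopifnot(is.data.frame(targets))
  if (any(targets$start >= targets$end)) {
    stop("targets: every exon must satisfy start < end (size >= 1)")
  }
  if (!is.null(targets$gc) &&
      (any(targets$gc < 0) || any(targets$gc > 1))) {
    stop("targets: gc must be a fraction in [0, 1]")
  }
  targets <- sort_by_position(targets)
  for (ch in unique(targets$chrom)) {
    sub <- targets[targets$chrom == ch, ]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)])) {
      stop("targets: overlapping exons on ", ch)
    }
  }
  targets
}

#' Exon midpoints
#'
#' Midpoint of each interval, `(start + end) / 2` in bp (may be a
#' half-integer under the 0-based half-open convention).
#'
#' @param x A `data.frame` with `start` and `end` columns.
#' @return Numeric vector of midpoints.
#' @export
exon_midpoints <- function(x) (x$start + x$end) / 2

# Default autosome filter: drop sex chromosomes and mitochondria,
# tolerating both "chr1" and "1" naming.
is_autosome <- function(chrom) {
  core <- sub("^chr", "", chrom)
  !(toupper(core) %in% c("X", "Y", "M", "MT"))
}
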