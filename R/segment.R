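#' Segmentation parameters
#'
#' Tuning constants for the bottom-up merge.
#'
#' * `alpha` — weight of the inter-exon distance term in the merge
#'   cost. `alpha = 0` disables the term and gives the original
#'   aCGH-style (VEGA) cost, which depends only on region lengths and
#'   mean contrast. Default 0.001.
#' * `beta` — stopping constant: merging halts once the gap between
#'   consecutive lambda advances exceeds `beta * nu`, where `nu` is the
#'   total variability (sample variance) of the chromosome's lr
#'   values. Default 0.5 (useful range roughly 0.5-0.7).
#' * `epsilon` — amount by which lambda is advanced past the smallest
#'   pending merge cost when no pair is mergeable. Default 1e-12.
#' * `distance_floor` — lower clamp, in bp, for `|d_i - d_{i+1}|`
#'   inside the logarithm of the distance term, keeping the cost
#'   finite when two regions have identical exon density.
#'   Default 1e-6.
#'
#' @param alpha,beta,epsilon,distance_floor See description.
#' @return A list of class `vegawes_params`.
#' @export
segmentation_params <- function(alpha = 0.001, beta = 0.5,
                                epsilon = 1e-12,
                                distance_floor = 1e-6) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
            is.numeric(beta), length(beta) == 1L, beta > 0,
            is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0,
            is.numeric(distance_floor), length(distance_floor) == 1L,
            distance_floor > 0)
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon,
                 distance_floor = distance_floor),
            class = "vegawes_params")
}

#' Local average inter-exon distance of a region
#'
#' The mean gap between consecutive exon midpoints inside a region:
#' `d_i = sum_{j=first}^{last-1} |m_j - m_{j+1}| / |R_i|`. Note that
#' the denominator is the number of exons `|R_i|`, not the number of
#' gaps `|R_i| - 1`; singleton regions have `d = 0`.
#'
#' @param first,last Region bounds, 1-based inclusive exon indices.
#' @param midpoints Numeric vector of exon midpoints (bp) for the
#'   whole chromosome, position-sorted.
#' @return The local average distance in bp.
#' @examples
#' local_avg_distance(1, 3, c(100, 200, 400))  # (100 + 200) / 3
#' @export
local_avg_distance <- function(first, last, midpoints) {
  stopifnot(first >= 1L, last <= length(midpoints), first <= last)
  if (last == first) return(0)
  sum(abs(diff(midpoints[first:last]))) / (last - first + 1L)
}

#' Cost of merging two adjacent regions
#'
#' The dynamic-regularization merge cost
#' `lambda_hat = |R1||R2| / (|R1| + |R2|) * (u1 - u2)^2
#'   + alpha * log(max(|d1 - d2|, distance_floor))`
#' where `u` are region mean lr values, `|R|` region lengths in exons,
#' and `d` the local average inter-exon distances. With `alpha = 0`
#' the distance term vanishes and the cost is the classical
#' length-weighted squared mean contrast. The natural logarithm is
#' used; the cost may be negative when the two regions have very
#' similar exon density.
#'
#' @param len1,len2 Region lengths (number of exons).
#' @param mean1,mean2 Region mean lr values.
#' @param d1,d2 Local average inter-exon distances in bp
#'   (see [local_avg_distance()]).
#' @param params A [segmentation_params()] object.
#' @return The merge cost (scalar).
#' @export
merge_cost <- function(len1, len2, mean1, mean2, d1 = 0, d2 = 0,
                       params = segmentation_params()) {
  base <- (len1 * len2) / (len1 + len2) * (mean1 - mean2)^2
  if (params$alpha == 0) return(base)
  base + params$alpha * log(pmax(abs(d1 - d2), params$distance_floor))
}

#' Segment one chromosome's log-ratio signal
#'
#' Bottom-up piecewise-constant segmentation: starting from one region
#' per exon and `lambda = 0`, the adjacent pair with the smallest merge
#' cost is merged whenever that cost is below `lambda`; when no pair
#' qualifies, `lambda` is advanced to the smallest pending cost plus
#' `epsilon` (each advance is recorded in `lambda_trace`). The process
#' stops when a single region remains, or when the next advance would
#' exceed the last recorded one by more than `beta * nu` (`nu` = sample
#' variance of the lr values) — i.e. when further merging no longer
#' buys a commensurate energy decrease. Ties in the minimum cost are
#' broken toward the leftmost pair.
#'
#' @param signal Either a numeric vector of per-exon log ratios or a
#'   log-ratio `data.frame` (`chrom start end name lr`, one
#'   chromosome; see [read_lr()]).
#' @param midpoints Exon midpoints in bp (required when `signal` is a
#'   bare numeric vector and `alpha > 0`; derived from the intervals
#'   when `signal` is a `data.frame`).
#' @param params A [segmentation_params()] object.
#' @param keep_merge_log Record one row per merge (region bounds,
#'   cost, lambda at merge time) for auditing; off by default.
#' @return An object of class `vegawes_segmentation`: a list with
#'   `lr`, `midpoints`, `regions` (`data.frame` with `first`, `last`,
#'   `n_exons`, `mean_lr`, `avg_dist` and, when intervals are known,
#'   `chrom`, `start`, `end`), `breakpoints` (ordered exon indices
#'   `b_1 ... b_{M+1}`, region `i` spanning exons
#'   `b_i ... b_{i+1}-1`), `lambda_trace`, `nu`, `final_lambda` (the
#'   last recorded lambda advance — the regularization the returned
#'   partition was fitted at), and `params`.
#' @examples
#' seg <- segment_chromosome(c(0, 0, 0, 1, 1, 1),
#'                           midpoints = 1:6 * 100,
#'                           params = segmentation_params(alpha = 0))
#' seg$regions
#' @export
segment_chromosome <- function(signal, midpoints = NULL,
                               params = segmentation_params(),
                               keep_merge_log = FALSE) {
  intervals <- NULL
  if (is.data.frame(signal)) {
    if (length(unique(signal$chrom)) > 1L) {
      stop("segment_chromosome: signal spans multiple chromosomes; ",
           "use segment_genome()")
    }
    signal <- sort_by_position(signal)
    intervals <- signal
    midpoints <- exon_midpoints(signal)
    lr <- signal$lr
  } else {
    lr <- as.numeric(signal)
  }
  n <- length(lr)
  if (n == 0L) stop("segment_chromosome: empty signal")
  if (any(!is.finite(lr))) {
    stop("segment_chromosome: non-finite lr at exon ",
         which(!is.finite(lr))[1L])
  }
  if (is.null(midpoints)) {
    if (params$alpha != 0) {
      stop("segment_chromosome: exon midpoints are required when ",
           "alpha > 0")
    }
    midpoints <- seq_len(n)
  }
  if (length(midpoints) != n) {
    stop("segment_chromosome: midpoints/lr length mismatch")
  }

  fit <- vega_merge(lr, midpoints, params, keep_merge_log)
  regions <- fit$regions
  if (!is.null(intervals)) {
    regions$chrom <- intervals$chrom[1L]
    regions$start <- intervals$start[regions$first]
    regions$end <- intervals$end[regions$last]
  }
  structure(list(lr = lr, midpoints = midpoints, regions = regions,
                 breakpoints = c(regions$first, n + 1L),
                 lambda_trace = fit$lambda_trace, nu = fit$nu,
                 final_lambda = fit$final_lambda, params = params,
                 merge_log = fit$merge_log, intervals = intervals),
            class = "vegawes_segmentation")
}

# Core greedy merge. Regions live in flat arrays indexed by the id of
# their first exon; `cost[i]` is the cost of merging region i with its
# right neighbour (Inf once i is inactive or rightmost), so
# which.min() is the leftmost minimal pair.
vega_merge <- function(lr, midpoints, params, keep_merge_log = FALSE) {
  n <- length(lr)
  nu <- if (n > 1L) stats::var(lr) else 0
  if (!is.finite(nu)) nu <- 0

  # prefix sums: region mean and Eq.-style gap sum in O(1)
  ps <- cumsum(lr)
  cgap <- c(0, cumsum(abs(diff(midpoints))))  # cgap[k+1] = gaps 1..k

  first <- seq_len(n)
  last <- seq_len(n)
  nxt <- c(seq_len(n)[-1L], NA_integer_)
  prv <- c(NA_integer_, seq_len(n)[-n])
  rlen <- rep(1, n)
  rmean <- lr
  rd <- rep(0, n)

  alpha <- params$alpha
  floor_d <- params$distance_floor
  cost <- rep(Inf, n)
  if (n > 1L) {
    base <- 0.5 * diff(lr)^2
    cost[-n] <- if (alpha == 0) base else base + alpha * log(floor_d)
  }

  lam <- 0
  final_lambda <- 0
  trace <- numeric(0)
  log_rows <- if (keep_merge_log) vector("list", n - 1L) else NULL
  n_merges <- 0L

  pair_cost <- function(i, j) {
    base <- (rlen[i] * rlen[j]) / (rlen[i] + rlen[j]) *
      (rmean[i] - rmean[j])^2
    if (alpha == 0) base
    else base + alpha * log(max(abs(rd[i] - rd[j]), floor_d))
  }

  repeat {
    b <- which.min(cost)
    mc <- cost[b]
    if (!is.finite(mc)) {  # single region left
      final_lambda <- lam
      break
    }
    if (mc < lam) {
      j <- nxt[b]
      if (keep_merge_log) {
        n_merges <- n_merges + 1L
        log_rows[[n_merges]] <- c(left_first = first[b],
                                  left_last = last[b],
                                  right_last = last[j],
                                  cost = mc, lambda = lam)
      }
      last[b] <- last[j]
      rlen[b] <- rlen[b] + rlen[j]
      rmean[b] <- (ps[last[b]] - ps[first[b]] + lr[first[b]]) / rlen[b]
      rd[b] <- (cgap[last[b]] - cgap[first[b]]) / rlen[b]
      k <- nxt[j]
      nxt[b] <- k
      if (!is.na(k)) prv[k] <- b
      cost[j] <- Inf
      cost[b] <- if (is.na(k)) Inf else pair_cost(b, k)
      p <- prv[b]
      if (!is.na(p)) cost[p] <- pair_cost(p, b)
      next
    }
    lam_new <- mc + params$epsilon
    # stopping test between consecutive recorded lambda advances; the
    # first advance from the initial lambda = 0 is always taken
    if (length(trace) && (lam_new - lam) > params$beta * nu) {
      final_lambda <- lam
      break
    }
    lam <- lam_new
    trace <- c(trace, lam)
  }

  # region ids are the still-active firsts: walk the linked list
  ids <- integer(0)
  i <- 1L
  while (!is.na(i)) {
    ids <- c(ids, i)
    i <- nxt[i]
  }
  regions <- data.frame(first = first[ids], last = last[ids],
                        n_exons = as.integer(rlen[ids]),
                        mean_lr = rmean[ids], avg_dist = rd[ids])
  rownames(regions) <- NULL

  merge_log <- NULL
  if (keep_merge_log && n_merges > 0L) {
    merge_log <- as.data.frame(do.call(rbind, log_rows[seq_len(n_merges)]))
  }
  list(regions = regions, lambda_trace = trace, nu = nu,
       final_lambda = final_lambda, merge_log = merge_log)
}

#' @export
print.vegawes_segmentation <- function(x, ...) {
  cat("Segmentation of", length(x$lr), "exons into",
      nrow(x$regions), "region(s)\n")
  cat("  lambda advances:", length(x$lambda_trace),
      " final lambda:",
      if (length(x$lambda_trace)) signif(max(x$lambda_trace), 6) else 0,
      " nu:", signif(x$nu, 6), "\n")
  print(utils::head(x$regions, 10))
  if (nrow(x$regions) > 10) cat("  ...", nrow(x$regions) - 10, "more\n")
  invisible(x)
}

#' Piecewise-constant segmentation energy
#'
#' `E = sum_regions sum_exons (lr - region mean)^2 + lambda * M`,
#' the residual sum of squares of the piecewise-constant fit plus a
#' penalty `lambda` per region.
#'
#' @param seg A `vegawes_segmentation`, or a `data.frame`/list with
#'   `first` and `last` columns describing the regions.
#' @param lr The signal (taken from `seg` when it is a segmentation
#'   object).
#' @param lambda Penalty per region.
#' @return The energy value.
#' @export
segmentation_energy <- function(seg, lambda, lr = NULL) {
  if (inherits(seg, "vegawes_segmentation")) {
    lr <- seg$lr
    regions <- seg$regions
  } else {
    regions <- as.data.frame(seg)
    if (is.null(lr)) stop("segmentation_energy: lr required")
  }
  sse <- 0
  for (k in seq_len(nrow(regions))) {
    v <- lr[regions$first[k]:regions$last[k]]
    sse <- sse + sum((v - mean(v))^2)
  }
  sse + lambda * nrow(regions)
}

#' Segment a multi-chromosome log-ratio table
#'
#' Applies [segment_chromosome()] independently to every chromosome of
#' a log-ratio table (chromosomes never share regions) and binds the
#' results into a SEG-style segment table.
#'
#' @param lr Log-ratio `data.frame` (`chrom start end name lr`).
#' @param params A [segmentation_params()] object.
#' @param sample Sample label for the SEG output (default "sample").
#' @param autosomes_only Drop sex chromosomes and mitochondria before
#'   segmenting (default `TRUE`).
#' @return A list with `seg` (a SEG `data.frame`
#'   `sample chrom start end num_exons seg_mean`) and `segmentations`
#'   (named list of per-chromosome `vegawes_segmentation` objects).
#' @export
segment_genome <- function(lr, params = segmentation_params(),
                           sample = "sample", autosomes_only = TRUE) {
  lr <- sort_by_position(lr)
  if (autosomes_only) lr <- lr[is_autosome(lr$chrom), , drop = FALSE]
  if (nrow(lr) == 0L) stop("segment_genome: no exons to segment")
  chroms <- unique(lr$chrom)
  fits <- lapply(chroms, function(ch) {
    segment_chromosome(lr[lr$chrom == ch, , drop = FALSE], params = params)
  })
  names(fits) <- chroms
  seg <- do.call(rbind, lapply(chroms, function(ch) {
    r <- fits[[ch]]$regions
    data.frame(sample = sample, chrom = ch, start = r$start, end = r$end,
               num_exons = r$n_exons, seg_mean = r$mean_lr)
  }))
  rownames(seg) <- NULL
  list(seg = seg, segmentations = fits)
}
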