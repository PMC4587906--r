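#' Exact piecewise-constant segmentation at fixed lambda
#'
#' Dynamic-programming minimizer of the piecewise-constant energy
#' `E = sum_regions RSS + lambda * M` for a fixed penalty `lambda`:
#' the returned partition achieves the global minimum over all 2^(n-1)
#' segmentations. O(n^2) time, intended for validation of the greedy
#' merge on signals up to a few thousand exons. Ties in energy are
#' broken toward fewer regions, then toward leftmost breakpoints.
#'
#' @param lr Numeric vector of per-exon log ratios.
#' @param lambda Penalty per region (`>= 0`).
#' @param tol Absolute tolerance for tie detection (default 1e-12).
#' @return A list with `regions` (`data.frame` `first`, `last`,
#'   `n_exons`, `mean_lr`), `breakpoints`, and `energy` (the attained
#'   minimum of the energy).
#' @export
dp_segment <- function(lr, lambda, tol = 1e-12) {
  n <- length(lr)
  if (n == 0L) stop("dp_segment: empty signal")
  if (any(!is.finite(lr))) stop("dp_segment: non-finite lr")
  stopifnot(lambda >= 0)

  cs <- c(0, cumsum(lr))
  cs2 <- c(0, cumsum(lr^2))
  # sse of segment i..j (1-based, inclusive)
  sse <- function(i, j) {
    len <- j - i + 1
    cs2[j + 1] - cs2[i] - (cs[j + 1] - cs[i])^2 / len
  }

  fval <- c(0, rep(Inf, n))   # fval[j+1]: optimal energy of lr[1..j]
  kcnt <- c(0L, rep(0L, n))   # region count of the chosen optimum
  back <- integer(n)          # start of the last segment
  for (j in seq_len(n)) {
    i_all <- seq_len(j)
    len <- j - i_all + 1
    seg_sse <- cs2[j + 1] - cs2[i_all] - (cs[j + 1] - cs[i_all])^2 / len
    cand <- fval[i_all] + seg_sse + lambda
    best_i <- 1L
    best_v <- cand[1L]
    best_k <- kcnt[1L] + 1L
    if (j > 1L) {
      for (i in 2:j) {
        v <- cand[i]
        k <- kcnt[i] + 1L
        if (v < best_v - tol || (v <= best_v + tol && k < best_k)) {
          best_i <- i; best_v <- v; best_k <- k
        }
      }
    }
    fval[j + 1] <- best_v
    kcnt[j + 1] <- best_k
    back[j] <- best_i
  }

  firsts <- integer(0)
  j <- n
  while (j >= 1L) {
    i <- back[j]
    firsts <- c(i, firsts)
    j <- i - 1L
  }
  lasts <- c(firsts[-1L] - 1L, n)
  regions <- data.frame(first = firsts, last = lasts,
                        n_exons = lasts - firsts + 1L,
                        mean_lr = vapply(seq_along(firsts), function(k) {
                          mean(lr[firsts[k]:lasts[k]])
                        }, numeric(1)))
  list(regions = regions, breakpoints = c(firsts, n + 1L),
       energy = fval[n + 1])
}
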