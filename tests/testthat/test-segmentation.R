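test_that("local average distance follows the printed per-exon normalization", {
  # 3 exons, midpoints 100/200/400: gaps 100 + 200 over |R| = 3 exons
  expect_equal(local_avg_distance(1, 3, c(100, 200, 400)), 100)
  # singletons have no consecutive pair
  expect_equal(local_avg_distance(2, 2, c(100, 200, 400)), 0)
  # equally spaced, step 150, 4 exons: 3 gaps / 4 exons
  expect_equal(local_avg_distance(1, 4, c(0, 150, 300, 450)), 112.5)
})

test_that("merge cost reduces to the length-weighted contrast at alpha 0", {
  p0 <- segmentation_params(alpha = 0)
  expect_equal(merge_cost(3, 7, 0.4, 0.4, params = p0), 0)
  expect_equal(merge_cost(2, 3, 0, 1, params = p0), 1.2)
  # distance-aware cost adds alpha * log |d1 - d2| (natural log)
  p <- segmentation_params(alpha = 0.001)
  expect_equal(merge_cost(2, 3, 0, 1, d1 = 100, d2 = 1100, params = p),
               1.2 + 0.001 * log(1000))
  # identical densities hit the floor clamp instead of -Inf
  expect_equal(merge_cost(1, 1, 0, 0, d1 = 50, d2 = 50, params = p),
               0.001 * log(1e-6))
})

test_that("segmentation energy is residual sum of squares plus lambda per region", {
  one <- data.frame(first = 1L, last = 4L)
  expect_equal(segmentation_energy(one, lambda = 0.7, lr = rep(0.3, 4)),
               0.7)
  two <- data.frame(first = c(1L, 3L), last = c(2L, 4L))
  expect_equal(segmentation_energy(two, lambda = 0, lr = c(0, 0, 1, 1)),
               0)
  expect_equal(segmentation_energy(one, lambda = 0, lr = c(0, 0, 1, 1)),
               1)
})

test_that("constant and trivial signals collapse to a single region", {
  for (n in c(2, 5, 40)) {
    s <- segment_chromosome(rep(0.3, n),
                            params = segmentation_params(alpha = 0))
    expect_identical(nrow(s$regions), 1L)
    expect_equal(s$regions$mean_lr, 0.3)
  }
  s1 <- segment_chromosome(0.5, params = segmentation_params(alpha = 0))
  expect_identical(nrow(s1$regions), 1L)
  expect_length(s1$lambda_trace, 0)
  expect_error(segment_chromosome(numeric(0)), "empty")
  expect_error(segment_chromosome(c(0, NA, 1)), "non-finite")
})

test_that("a clean two-level signal yields two regions at the true breakpoint", {
  lr <- make_step_signal(c(10, 10), c(0, 1), sd = 0.01, seed = 42)
  s <- segment_chromosome(lr, params = segmentation_params(alpha = 0))
  expect_equal(s$regions$first, c(1L, 11L))
  expect_equal(s$breakpoints, c(1L, 11L, 21L))
  # and it attains the exact optimum at its final lambda
  d <- dp_segment(lr, s$final_lambda)
  expect_equal(segmentation_energy(s, s$final_lambda), d$energy)
  expect_equal(d$regions$first, c(1L, 11L))
})

test_that("merge bookkeeping matches the energy identity and region invariants", {
  p0 <- segmentation_params(alpha = 0)
  for (seed in 1:5) {
    set.seed(seed)
    lr <- rnorm(25, 0, 0.3) + rep(c(0, 1.2, 0.2), c(8, 9, 8))
    s <- segment_chromosome(lr, params = p0, keep_merge_log = TRUE)

    # lambda never decreases and merges only ever happen below it
    expect_true(all(diff(s$lambda_trace) >= 0))
    expect_true(all(s$merge_log$cost < s$merge_log$lambda))

    # every merge changes the energy by exactly cost - lambda (<= 0)
    rep_log <- replay_merges(s)
    expect_equal(rep_log$observed, rep_log$predicted, tolerance = 1e-9)
    expect_true(all(rep_log$predicted <= 0))

    # regions tile the signal and their stats are recomputable
    r <- s$regions
    expect_identical(r$first[1], 1L)
    expect_identical(r$last[nrow(r)], 25L)
    if (nrow(r) > 1) expect_equal(r$first[-1], r$last[-nrow(r)] + 1L)
    expect_equal(r$n_exons, r$last - r$first + 1L)
    for (k in seq_len(nrow(r))) {
      expect_equal(r$mean_lr[k], mean(lr[r$first[k]:r$last[k]]))
    }
  }
})

test_that("merged region means are the length-weighted child means", {
  set.seed(7)
  lr <- rnorm(30)
  mids <- cumsum(runif(30, 100, 5000))
  s <- segment_chromosome(lr, midpoints = mids,
                          keep_merge_log = TRUE)
  log <- s$merge_log
  for (k in seq_len(nrow(log))) {
    i1 <- log$left_first[k]:log$left_last[k]
    i2 <- (log$left_last[k] + 1L):log$right_last[k]
    merged <- mean(lr[c(i1, i2)])
    weighted <- (length(i1) * mean(lr[i1]) + length(i2) * mean(lr[i2])) /
      (length(i1) + length(i2))
    expect_equal(merged, weighted)
  }
})

test_that("distance-aware region statistics are recomputed over merged spans", {
  set.seed(21)
  mids <- cumsum(c(500, runif(19, 100, 10000)))
  lr <- rnorm(20, 0, 0.1)
  s <- segment_chromosome(lr, midpoints = mids)
  r <- s$regions
  for (k in seq_len(nrow(r))) {
    expect_equal(r$avg_dist[k],
                 local_avg_distance(r$first[k], r$last[k], mids))
  }
})

test_that("alpha 0 segmentation ignores exon coordinates entirely", {
  set.seed(9)
  lr <- rnorm(40, 0, 0.2) + rep(c(0, 1), each = 20)
  p0 <- segmentation_params(alpha = 0)
  mids <- cumsum(runif(40, 200, 8000))
  a <- segment_chromosome(lr, midpoints = mids, params = p0)
  b <- segment_chromosome(lr, midpoints = mids + 5e6, params = p0)
  d <- segment_chromosome(lr, midpoints = mids * 37 + 11, params = p0)
  expect_identical(a$regions$first, b$regions$first)
  expect_identical(a$regions$first, d$regions$first)
  expect_equal(a$lambda_trace, b$lambda_trace)
})

test_that("reversing the signal mirrors the segmentation at alpha 0", {
  set.seed(13)
  lr <- rnorm(30, 0, 0.15) + rep(c(0, 0.9, -0.4), each = 10)
  p0 <- segmentation_params(alpha = 0)
  fwd <- segment_chromosome(lr, params = p0)
  rev_ <- segment_chromosome(rev(lr), params = p0)
  n <- length(lr)
  mirrored_firsts <- sort(n + 1L - rev_$regions$last)
  expect_identical(fwd$regions$first, mirrored_firsts)
  expect_equal(sort(fwd$regions$mean_lr), sort(rev_$regions$mean_lr))
})

test_that("multi-chromosome tables segment per chromosome into a SEG table", {
  lr1 <- make_step_signal(c(8, 8), c(0, 1), sd = 0.02, seed = 1)
  lr2 <- make_step_signal(c(10, 6), c(0.2, -0.8), sd = 0.02, seed = 2)
  t1 <- make_targets(16, chrom = "chr1")
  t2 <- make_targets(16, chrom = "chr2")
  tab <- rbind(
    data.frame(t1[c("chrom", "start", "end", "name")], lr = lr1),
    data.frame(t2[c("chrom", "start", "end", "name")], lr = lr2))
  fit <- segment_genome(tab, params = segmentation_params(alpha = 0))
  expect_identical(sum(fit$seg$num_exons[fit$seg$chrom == "chr1"]), 16L)
  expect_identical(sum(fit$seg$num_exons[fit$seg$chrom == "chr2"]), 16L)
  expect_identical(nrow(fit$seg), 4L)
  # sex chromosomes are excluded by default
  tabX <- tab
  tabX$chrom[tabX$chrom == "chr2"] <- "chrX"
  fitX <- segment_genome(tabX, params = segmentation_params(alpha = 0))
  expect_identical(unique(fitX$seg$chrom), "chr1")
})
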