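test_that("exons inherit the mean log ratio of their region", {
  one <- data.frame(first = 1L, last = 5L, n_exons = 5L, mean_lr = 0.4)
  expect_equal(exon_level_lr(one), rep(0.4, 5))
  two <- data.frame(first = c(1L, 4L), last = c(3L, 5L),
                    n_exons = c(3L, 2L), mean_lr = c(0, 1))
  expect_equal(exon_level_lr(two), c(0, 0, 0, 1, 1))
  expect_error(exon_level_lr(two[0, ]), "no regions")
})

test_that("ROC endpoints, perfect and uninformative classifiers behave", {
  # perfect separation: passes through (0, 1), AUC 1
  curve <- roc_curve(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(any(curve$fpr == 0 & curve$tpr == 1))
  expect_equal(curve$fpr[1], 0)
  expect_equal(curve$tpr[1], 0)
  expect_equal(curve$fpr[nrow(curve)], 1)
  expect_equal(curve$tpr[nrow(curve)], 1)
  expect_equal(attr(curve, "auc"), 1)
  expect_equal(roc_auc(c(0.9, 0.1, 0.8, 0.2), c(TRUE, FALSE, TRUE, FALSE)),
               1)

  # constant score: a single tie group, AUC 1/2
  expect_equal(roc_auc(rep(0.3, 10), rep(c(TRUE, FALSE), 5)), 0.5)

  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "both")
  expect_error(roc_curve(1:3, c(TRUE, FALSE)), "length")
})

test_that("deletion events sweep the negated signal", {
  seg_lr <- c(-1, -0.9, 0, 0.1)
  mask <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(roc_auc(seg_lr, mask, event = "deletion"), 1)
  expect_equal(roc_auc(seg_lr, mask, event = "amplification"), 0)
})

test_that("trapezoidal AUC equals the brute-force Mann-Whitney statistic", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(10:50, 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(truth)) truth[1] <- TRUE
    if (all(truth)) truth[1] <- FALSE
    # duplicate-heavy scores exercise tie handling
    score <- sample(seq(-1, 1, by = 0.25), n, replace = TRUE)
    expect_equal(roc_auc(score, truth), mann_whitney_auc(score, truth))
  }
})

test_that("ROC is invariant to strictly monotone transforms of the score", {
  set.seed(4)
  score <- rnorm(60)
  truth <- rep(c(TRUE, FALSE), 30)
  a <- roc_auc(score, truth)
  expect_equal(roc_auc(2 * score + 5, truth), a)
  expect_equal(roc_auc(exp(score), truth), a)
  expect_equal(roc_auc(atan(score), truth), a)
})

test_that("exon-level AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  score <- rnorm(100) + rep(c(0, 1.5), 50)
  truth <- rep(c(FALSE, TRUE), 50)
  expect_equal(roc_auc(score, truth),
               as.numeric(pROC::auc(pROC::roc(truth, score,
                                              quiet = TRUE,
                                              direction = "<"))))
})

test_that("calls derived from the truth itself score perfectly", {
  sim <- simulate_chromosome(simulation_config(g = 5,
                                               event = "deletion"),
                             seed = 6)
  truth <- sim$truth
  calls <- data.frame(chrom = truth$chrom, start = truth$start,
                      end = truth$end, seg_mean = truth$lr)
  m <- suppressWarnings(
    precision_recall_fscore(calls, truth, exons = sim$targets))
  expect_equal(m$precision_loss, 1)
  expect_equal(m$recall_loss, 1)
  expect_equal(m$fscore, 1)
  expect_identical(m$n_excluded, 0L)
})

test_that("the log-ratio agreement tolerance is boundary inclusive", {
  exons <- make_targets(2)
  truth <- data.frame(chrom = "chr1", start = exons$start,
                      end = exons$end, lr = c(0.30, 0.30))
  # called 0.45: label amplified vs truth normal, but |0.45-0.30| = 0.15
  calls <- data.frame(chrom = "chr1", start = exons$start,
                      end = exons$end, seg_mean = c(0.45, 0.46))
  m <- suppressWarnings(
    precision_recall_fscore(calls, truth, exons = exons))
  expect_equal(m$counts$tp_called_amp, 1)   # 0.45 is TP, 0.46 is not
  expect_equal(m$precision_gain, 0.5)
})

test_that("empty denominators report zero with a warning", {
  exons <- make_targets(4)
  truth <- data.frame(chrom = "chr1", start = min(exons$start),
                      end = max(exons$end), lr = 0.8)
  calls <- data.frame(chrom = "chr1", start = min(exons$start),
                      end = max(exons$end), seg_mean = 0)
  suppressWarnings(
    expect_warning(m <- precision_recall_fscore(calls, truth,
                                                exons = exons),
                   "reporting 0"))
  expect_equal(m$recall_gain, 0)
  expect_equal(m$precision_gain, 0)  # nothing called amplified
  expect_equal(m$fscore, 0)
})

test_that("widening the tolerance never lowers any metric", {
  set.seed(44)
  sim <- simulate_chromosome(simulation_config(g = 5,
                                               gene_length_exons = 20),
                             seed = 44)
  fit <- segment_chromosome(sim$lr)
  calls <- classify_segments(fit)
  prev <- NULL
  for (tol in c(0, 0.05, 0.15, 0.3, 0.6)) {
    m <- suppressWarnings(
      precision_recall_fscore(calls, sim$truth, exons = sim$targets,
                              lr_tolerance = tol))
    vals <- unlist(m[c("precision_gain", "recall_gain",
                       "precision_loss", "recall_loss", "fscore")])
    if (!is.null(prev)) expect_true(all(vals >= prev - 1e-12))
    prev <- vals
  }
})

test_that("exons outside the truth are excluded and counted", {
  exons <- make_targets(6)
  truth <- data.frame(chrom = "chr1", start = exons$start[1],
                      end = exons$end[3], lr = 0)
  calls <- data.frame(chrom = "chr1", start = exons$start[1],
                      end = exons$end[6], seg_mean = 0)
  m <- suppressWarnings(
    precision_recall_fscore(calls, truth, exons = exons))
  expect_identical(m$n_excluded, 3L)
  truth_off <- transform(truth, chrom = "chr9")
  expect_error(precision_recall_fscore(calls, truth_off, exons = exons),
               "covered")
})

test_that("metric aggregation is the unweighted mean over units", {
  m1 <- structure(list(precision_gain = 1, recall_gain = 0.5,
                       precision_loss = 1, recall_loss = 1,
                       fscore = 0.8), class = "vegawes_metrics")
  m2 <- structure(list(precision_gain = 0, recall_gain = 0.5,
                       precision_loss = 0.5, recall_loss = 1,
                       fscore = 0.4), class = "vegawes_metrics")
  agg <- aggregate_metrics(list(m1, m2))
  expect_equal(unname(agg["precision_gain"]), 0.5)
  expect_equal(unname(agg["fscore"]), 0.6)
})
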