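#' Synthetic chromosome configuration
#'
#' Describes one benchmark condition: a chromosome of `n_exons`
#' targeted exons carrying `g` altered genes of `gene_length_exons`
#' consecutive exons each, consecutive genes separated by at least
#' `inter_gene_distance_bp` on the genome. Altered exons are shifted
#' by `shift` log2 units (defaults: `+log2(3/2) = 0.585` for a
#' single-copy gain, `-1` for a single-copy loss in a diploid
#' background) and every exon receives Gaussian noise of standard
#' deviation `noise_sd`. Exons are `exon_size_bp` wide with baseline
#' gaps drawn log-uniformly between `gap_min_bp` and `gap_max_bp`,
#' reproducing the density heterogeneity of exome capture designs.
#'
#' @param n_exons Exons per chromosome (default 1000).
#' @param g Number of altered genes (default 2; benchmark grid uses
#'   2 and 5).
#' @param gene_length_exons Exons per altered gene (default 5;
#'   benchmark grid uses 5 and 20).
#' @param inter_gene_distance_bp Minimum bp from one gene's end to the
#'   next gene's start (default 10000; grid uses 1e4 and 1e6).
#' @param event `"amplification"` or `"deletion"`.
#' @param shift Log-ratio shift of altered exons; default
#'   `log2(3/2)` for amplification, `-1` for deletion.
#' @param noise_sd Standard deviation of the per-exon Gaussian noise
#'   (default 0.2).
#' @param exon_size_bp Exon width in bp (default 352, a typical mean
#'   capture-target size).
#' @param gap_min_bp,gap_max_bp Range of the log-uniform baseline
#'   inter-exon gap (defaults 100 and 10000).
#' @param n_chromosomes Replicates per condition in
#'   [simulate_benchmark_suite()] (default 100).
#' @return A list of class `vegawes_sim_config`.
#' @export
simulation_config <- function(n_exons = 1000, g = 2,
                              gene_length_exons = 5,
                              inter_gene_distance_bp = 10000,
                              event = c("amplification", "deletion"),
                              shift = NULL, noise_sd = 0.2,
                              exon_size_bp = 352,
                              gap_min_bp = 100, gap_max_bp = 10000,
                              n_chromosomes = 100) {
  event <- match.arg(event)
  if (is.null(shift)) {
    shift <- if (event == "amplification") log2(3 / 2) else -1
  }
  cfg <- list(n_exons = as.integer(n_exons), g = as.integer(g),
              gene_length_exons = as.integer(gene_length_exons),
              inter_gene_distance_bp = inter_gene_distance_bp,
              event = event, shift = shift, noise_sd = noise_sd,
              exon_size_bp = exon_size_bp, gap_min_bp = gap_min_bp,
              gap_max_bp = gap_max_bp,
              n_chromosomes = as.integer(n_chromosomes))
  stopifnot(cfg$n_exons >= 1L, cfg$g >= 1L, cfg$gene_length_exons >= 1L,
            cfg$inter_gene_distance_bp > 0, cfg$noise_sd >= 0,
            cfg$exon_size_bp >= 1, cfg$gap_min_bp > 0,
            cfg$gap_max_bp >= cfg$gap_min_bp, cfg$n_chromosomes >= 1L)
  if (cfg$g * cfg$gene_length_exons >= cfg$n_exons) {
    stop("simulation_config: g * gene_length_exons must be < n_exons")
  }
  if (cfg$event == "amplification" && cfg$shift <= 0) {
    stop("simulation_config: amplification requires a positive shift")
  }
  if (cfg$event == "deletion" && cfg$shift >= 0) {
    stop("simulation_config: deletion requires a negative shift")
  }
  structure(cfg, class = "vegawes_sim_config")
}

#' Simulate one synthetic chromosome
#'
#' Realizes exon positions, places the altered genes, and draws the
#' per-exon log-ratio signal `lr_i = shift * altered_i + N(0, sd)`.
#' Gene placement spreads the genes over the exon index range (at
#' least one unaltered exon between genes) and then inflates the gap
#' upstream of each gene as needed so consecutive genes are at least
#' `inter_gene_distance_bp` apart on the genome. Fully reproducible
#' from `seed`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer RNG seed.
#' @param chrom Chromosome label for the emitted tables.
#' @return A list of class `synthetic_chromosome` with `targets`
#'   (exon table, with a synthetic `gc` column), `lr` (log-ratio
#'   `data.frame`), `truth_mask` (logical, `TRUE` inside altered
#'   genes), `truth` (tiling ground-truth segments
#'   `chrom start end lr`, altered genes at `shift` and background at
#'   0), `config`, and `seed`.
#' @export
simulate_chromosome <- function(config = simulation_config(), seed = 1L,
                                chrom = "chrS") {
  stopifnot(inherits(config, "vegawes_sim_config"))
  set.seed(seed)
  n <- config$n_exons
  g <- config$g
  N <- config$gene_length_exons

  # background run lengths around the g genes: g+1 runs summing to
  # n - g*N, interior runs >= 1 so genes stay disjoint
  n_bg <- n - g * N
  interior_min <- if (g > 1L) rep(c(0L, rep(1L, g - 1L), 0L), 1L) else c(0L, 0L)
  spare <- n_bg - sum(interior_min)
  runs <- interior_min + as.integer(stats::rmultinom(1, spare,
                                                     rep(1, g + 1L)))
  gene_first <- cumsum(runs[seq_len(g)] + c(0L, rep(N, g - 1L))) + 1L
  mask <- rep(FALSE, n)
  for (k in seq_len(g)) {
    mask[gene_first[k]:(gene_first[k] + N - 1L)] <- TRUE
  }

  # exon layout: fixed width, log-uniform baseline gaps
  gaps <- exp(stats::runif(n - 1L, log(config$gap_min_bp),
                           log(config$gap_max_bp)))
  gaps <- round(gaps)
  start <- cumsum(c(0, gaps + config$exon_size_bp))
  end <- start + config$exon_size_bp

  # enforce the genomic inter-gene distance D by widening the gap
  # just upstream of each gene that sits too close to its predecessor
  if (g > 1L) {
    D <- config$inter_gene_distance_bp
    for (k in 2:g) {
      f <- gene_first[k]
      prev_end <- end[gene_first[k - 1L] + N - 1L]
      deficit <- D - (start[f] - prev_end)
      if (deficit > 0) {
        idx <- f:n
        start[idx] <- start[idx] + deficit
        end[idx] <- end[idx] + deficit
      }
    }
  }

  gc <- round(stats::runif(n, 0.3, 0.7), 4)
  lr_val <- config$shift * mask + stats::rnorm(n, 0, config$noise_sd)

  name <- sprintf("exon_%04d", seq_len(n))
  targets <- data.frame(chrom = chrom, start = start, end = end,
                        name = name, gc = gc)
  lr <- data.frame(chrom = chrom, start = start, end = end,
                   name = name, lr = lr_val)

  r <- rle(mask)
  run_last <- cumsum(r$lengths)
  run_first <- run_last - r$lengths + 1L
  truth <- data.frame(chrom = chrom, start = start[run_first],
                      end = end[run_last],
                      lr = ifelse(r$values, config$shift, 0))

  structure(list(targets = targets, lr = lr, truth_mask = mask,
                 truth = truth, config = config, seed = seed),
            class = "synthetic_chromosome")
}

#' The standard synthetic benchmark grid
#'
#' All combinations of event type (amplification, deletion),
#' `g` in {2, 5}, gene length `N` in {5, 20} exons, and inter-gene
#' distance `D` in {1e4, 1e6} bp: 16 conditions.
#'
#' @return A `data.frame` with columns `event`, `g`, `N`, `D` and a
#'   `label` of the form `amplification_g2_N5_D1e+04`.
#' @export
benchmark_grid <- function() {
  grid <- expand.grid(D = c(1e4, 1e6), N = c(5L, 20L), g = c(2L, 5L),
                      event = c("amplification", "deletion"),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("event", "g", "N", "D")]
  grid$label <- sprintf("%s_g%d_N%d_D%s", grid$event, grid$g, grid$N,
                        format(grid$D, scientific = FALSE, trim = TRUE))
  grid
}

#' Simulate the full benchmark suite
#'
#' For every condition of [benchmark_grid()], generates
#' `base$n_chromosomes` replicate chromosomes with per-replicate seeds
#' derived deterministically from `seed`.
#'
#' @param base A [simulation_config()] whose `n_exons`, `shift` (left
#'   `NULL` to use the per-event default), `noise_sd`, layout and
#'   `n_chromosomes` fields apply to every condition.
#' @param seed Master integer seed.
#' @param conditions Optionally a subset of [benchmark_grid()] rows.
#' @return A named list (one element per condition label), each with
#'   `config` and `chromosomes` (list of [simulate_chromosome()]
#'   results).
#' @export
simulate_benchmark_suite <- function(base = simulation_config(),
                                     seed = 1L,
                                     conditions = benchmark_grid()) {
  set.seed(seed)
  reps <- base$n_chromosomes
  seeds <- matrix(sample.int(2147483646L, nrow(conditions) * reps),
                  nrow = nrow(conditions))
  out <- vector("list", nrow(conditions))
  names(out) <- conditions$label
  for (i in seq_len(nrow(conditions))) {
    cfg <- simulation_config(
      n_exons = base$n_exons, g = conditions$g[i],
      gene_length_exons = conditions$N[i],
      inter_gene_distance_bp = conditions$D[i],
      event = conditions$event[i], noise_sd = base$noise_sd,
      exon_size_bp = base$exon_size_bp, gap_min_bp = base$gap_min_bp,
      gap_max_bp = base$gap_max_bp, n_chromosomes = reps)
    out[[i]] <- list(
      config = cfg,
      chromosomes = lapply(seq_len(reps), function(r) {
        simulate_chromosome(cfg, seed = seeds[i, r],
                            chrom = sprintf("%s_rep%03d",
                                            conditions$label[i], r))
      }))
  }
  out
}
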