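#' Binned mutation series
#'
#' Per-bin mutation counts and per-generation rates for one experiment,
#' ordered clockwise from the origin (bin 1 starts at OriC).
#'
#' @param counts integer per-bin mutation counts, length `n_bins`.
#' @param total_generations total generations of the experiment (rates are
#'   `counts / total_generations`); `NA` allowed when only counts matter.
#' @param strain_id strain identifier.
#' @param direction `"cw"` (clockwise, the native order) or `"ccw"`.
#' @return an object of class `binned_series` with fields `strain_id`,
#'   `direction`, `counts`, `rates`, `total_generations`, `n_bins`.
#' @export
binned_series <- function(counts, total_generations = NA_real_,
                          strain_id = "strain", direction = c("cw", "ccw")) {
  direction <- match.arg(direction)
  counts <- as.numeric(counts)
  if (any(is.na(counts) | counts < 0))
    stop("counts must be nonnegative", call. = FALSE)
  total_generations <- as.numeric(total_generations)
  rates <- if (is.na(total_generations)) rep(NA_real_, length(counts))
           else counts / total_generations
  structure(list(strain_id = as.character(strain_id), direction = direction,
                 counts = counts, rates = rates,
                 total_generations = total_generations,
                 n_bins = length(counts)),
            class = "binned_series")
}

#' @export
print.binned_series <- function(x, ...) {
  cat(sprintf("<binned_series> %s (%s): %d bins, %d mutations%s\n",
              x$strain_id, x$direction, x$n_bins, round(sum(x$counts)),
              if (is.na(x$total_generations)) "" else
                sprintf(", %s generations",
                        format(x$total_generations, big.mark = ","))))
  invisible(x)
}

#' Bin mutations into the origin-anchored scheme
#'
#' @param records mutation-record `data.frame`.
#' @param genome a [genome_map()].
#' @param meta optional [experiment_meta()] supplying generations (for
#'   rates) and the strain id.
#' @return a [binned_series()] (clockwise).  `sum(counts)` always equals
#'   `nrow(records)`.
#' @export
bin_mutations <- function(records, genome, meta = NULL) {
  validate_mutations(records, genome)
  counts <- tabulate(assign_bin(records$position, genome),
                     nbins = genome$n_bins)
  binned_series(counts,
                total_generations = if (is.null(meta)) NA_real_
                                    else meta$total_generations,
                strain_id = if (is.null(meta)) "strain" else meta$strain_id)
}

#' Genome-wide mutation rate per generation (x 10^3)
#'
#' The pooled rate: total mutations divided by total generations, scaled
#' by 1000 for display alongside published rate tables.
#'
#' @param bps_count total number of BPSs.
#' @param generations total generations (> 0).
#' @return `1000 * bps_count / generations`, full precision.
#' @seealso [round_rate()] for the conventional display rounding.
#' @export
genome_rate <- function(bps_count, generations) {
  if (any(generations <= 0)) stop("generations must be > 0", call. = FALSE)
  1000 * bps_count / generations
}

#' Display rounding for rates
#'
#' Rates at or above 1 (x 10^3 per generation) are shown as integers,
#' rates below 1 with two decimals, the convention of published MA rate
#' tables.
#'
#' @param rate rate(s) on the x 10^3 scale.
#' @return rounded numeric vector.
#' @export
round_rate <- function(rate) {
  ifelse(abs(rate) >= 1, round(rate), round(rate, 2))
}

#' Bootstrap 95% confidence limits for the pooled rate
#'
#' Nonparametric percentile bootstrap over MA lines: lines are resampled
#' with replacement and the pooled rate (sum of counts over sum of
#' generations, x 10^3) recomputed for each replicate.  No distributional
#' assumption on among-line variation.
#'
#' @param per_line_counts integer mutation counts, one per line.
#' @param per_line_generations generations per line (same length).
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed integer seed for reproducibility.
#' @return named vector `c(low, high)` on the x 10^3 scale.
#' @export
rate_cl95 <- function(per_line_counts, per_line_generations,
                      n_boot = 10000L, seed = 1L) {
  n <- length(per_line_counts)
  if (n < 2) stop("need at least 2 lines for confidence limits",
                  call. = FALSE)
  if (length(per_line_generations) != n)
    stop("counts and generations must have equal length", call. = FALSE)
  if (n_boot < 1000) stop("n_boot must be >= 1000", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  boot <- 1000 * colSums(matrix(per_line_counts[idx], nrow = n)) /
    colSums(matrix(per_line_generations[idx], nrow = n))
  q <- stats::quantile(boot, c(0.025, 0.975), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Mean per-bin rate across experiments with 95% CL of the mean
#'
#' @param series_list list of [binned_series()] with equal `n_bins`.
#' @return `data.frame` with columns `bin`, `mean_rate`, `cl_low`,
#'   `cl_high` (t-interval on the across-experiment sample per bin).
#' @export
mean_rate_series <- function(series_list) {
  if (length(series_list) < 2)
    stop("need at least 2 series", call. = FALSE)
  nb <- unique(vapply(series_list, function(s) s$n_bins, integer(1)))
  if (length(nb) != 1)
    stop("series have mismatched bin counts", call. = FALSE)
  m <- do.call(rbind, lapply(series_list, function(s) s$rates))
  k <- nrow(m)
  mu <- colMeans(m)
  se <- apply(m, 2, stats::sd) / sqrt(k)
  tq <- stats::qt(0.975, df = k - 1)
  data.frame(bin = seq_len(nb), mean_rate = mu,
             cl_low = mu - tq * se, cl_high = mu + tq * se)
}

#' Bin a weighted genomic signal with reference-gene normalization
#'
#' Generic signal binning into the mutation bins: per-bin sums of weights
#' (e.g. RNA-Seq read counts at mapped positions) divided by the weight
#' mapped to a reference gene whose expression is constant across
#' conditions.  Replicate signals should be averaged before binning.
#'
#' @param positions 1-based genomic coordinates.
#' @param weights weight per position (same length).
#' @param genome a [genome_map()].
#' @param reference_gene_weight positive normalizer.
#' @return numeric per-bin normalized signal, length `n_bins`.
#' @export
bin_signal <- function(positions, weights, genome, reference_gene_weight) {
  if (reference_gene_weight <= 0)
    stop("reference_gene_weight must be > 0", call. = FALSE)
  if (length(positions) != length(weights))
    stop("positions and weights must have equal length", call. = FALSE)
  b <- assign_bin(positions, genome)
  sums <- vapply(seq_len(genome$n_bins),
                 function(i) sum(weights[b == i]), numeric(1))
  sums / reference_gene_weight
}

#' Pool several experiments into one reference series
#'
#' Generation-weighted pooling: per-bin counts are summed and divided by
#' the summed generations, so the pooled rate equals the
#' generation-weighted mean of the per-experiment rates.
#'
#' @param series_list list of [binned_series()] with generations set.
#' @param strain_id id for the pooled series.
#' @return a [binned_series()].
#' @export
pool_series <- function(series_list, strain_id = "pooled") {
  nb <- unique(vapply(series_list, function(s) s$n_bins, integer(1)))
  if (length(nb) != 1)
    stop("series have mismatched bin counts", call. = FALSE)
  gens <- vapply(series_list, function(s) s$total_generations, numeric(1))
  if (any(is.na(gens)))
    stop("all series need total_generations for pooling", call. = FALSE)
  counts <- Reduce(`+`, lapply(series_list, function(s) s$counts))
  binned_series(counts, total_generations = sum(gens),
                strain_id = strain_id)
}

#' Rate table for a set of experiments
#'
#' One row per experiment: mutation count, generations, pooled rate
#' (x 10^3 per generation) and bootstrap 95% confidence limits when
#' per-line data are available.
#'
#' @param experiments list; each element a list with fields `meta`
#'   ([experiment_meta()]) and `records` (mutation table), and optionally
#'   `per_line_counts`.
#' @param n_boot,seed passed to [rate_cl95()].
#' @return `data.frame` with columns `strain`, `n_lines`, `bps_count`,
#'   `generations`, `rate_per_gen_x1000`, `cl95_low`, `cl95_high`.
#' @export
rate_table <- function(experiments, n_boot = 10000L, seed = 1L) {
  rows <- lapply(experiments, function(e) {
    m <- e$meta
    cnt <- nrow(e$records)
    rate <- genome_rate(cnt, m$total_generations)
    cl <- c(low = NA_real_, high = NA_real_)
    if (!is.null(m$per_line_generations)) {
      plc <- if (!is.null(e$per_line_counts)) e$per_line_counts
             else as.numeric(table(factor(e$records$line_id,
                                          levels = unique(e$records$line_id))))
      if (length(plc) == length(m$per_line_generations))
        cl <- rate_cl95(plc, m$per_line_generations, n_boot, seed)
    }
    data.frame(strain = m$strain_id, n_lines = m$n_lines, bps_count = cnt,
               generations = m$total_generations,
               rate_per_gen_x1000 = rate,
               cl95_low = cl[["low"]], cl95_high = cl[["high"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
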