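# Synthetic mutation-accumulation data with known position-dependent
# mutation intensity.  The generator emulates the study design the
# pipeline is built for: many independent MA lines, Poisson mutation
# counts proportional to generations, and positions drawn from a
# relative intensity that is a cosine wave symmetric about the
# replication origin (optionally with a terminus-region elevation and
# trinucleotide hot-spot enrichment).  Every stage of the pipeline can
# then be checked against the ground-truth intensity.

#' Simulation specification
#'
#' @param genome a [genome_map()].
#' @param baseline_rate genome-wide BPS rate per generation (> 0).
#' @param wave_components list of components `list(amplitude, period_kb,
#'   phase)`; the relative intensity is
#'   `1 + sum_k a_k cos(2 pi d / p_k + phi_k)` where `d` is the clockwise
#'   distance from the origin (`symmetric = FALSE`) or the distance to
#'   the origin along the shorter arc (`symmetric = TRUE`, mirroring the
#'   wave across both replichores).
#' @param symmetric mirror the intensity about the origin (default TRUE).
#' @param terminus_bump optional `list(center_frac, width_bp, height)`:
#'   a Gaussian elevation centered `center_frac * length_bp` clockwise
#'   from the origin (0.5 = terminus).
#' @param n_lines number of independent MA lines.
#' @param generations_per_line generations per line.
#' @param hotspot optional `list(nac_multiplier)`: relative rate of
#'   A:T -> G:C transitions at 5'NAC3'/3'NTG5' sites versus other sites;
#'   a synthetic i.i.d.-uniform reference sequence is generated to place
#'   them.
#' @param seed integer seed; all randomness flows through it.
#' @return an object of class `sim_spec`.  Construction fails if the
#'   intensity is negative anywhere.
#' @export
sim_spec <- function(genome, baseline_rate, wave_components = list(),
                     symmetric = TRUE, terminus_bump = NULL,
                     n_lines = 40L, generations_per_line = 650,
                     hotspot = NULL, seed = 1L) {
  if (baseline_rate <= 0) stop("baseline_rate must be > 0", call. = FALSE)
  if (n_lines < 1) stop("need at least 1 line", call. = FALSE)
  for (wc in wave_components) {
    if (wc$amplitude < 0 || wc$period_kb <= 0)
      stop("wave component needs amplitude >= 0 and period_kb > 0",
           call. = FALSE)
  }
  spec <- structure(
    list(genome = genome, baseline_rate = baseline_rate,
         wave_components = wave_components, symmetric = isTRUE(symmetric),
         terminus_bump = terminus_bump, n_lines = as.integer(n_lines),
         generations_per_line = as.numeric(generations_per_line),
         hotspot = hotspot, seed = as.integer(seed)),
    class = "sim_spec")
  # validate nonnegativity on a 1-kb lattice
  grid <- seq(1, genome$length_bp, by = 1000)
  if (min(wave_intensity(spec, grid)) < 0)
    stop("wave intensity is negative; reduce amplitudes or add a bump",
         call. = FALSE)
  spec
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf("<sim_spec> %d lines x %.0f generations, rate %.3g/gen, %d wave component(s)%s, seed %d\n",
              x$n_lines, x$generations_per_line, x$baseline_rate,
              length(x$wave_components),
              if (x$symmetric) " (symmetric)" else "", x$seed))
  invisible(x)
}

#' Relative mutation intensity at genomic positions
#'
#' @param spec a [sim_spec()].
#' @param position_bp 1-based coordinate(s).
#' @return relative intensity (unit mean baseline), >= 0.
#' @export
wave_intensity <- function(spec, position_bp) {
  g <- spec$genome
  off <- clockwise_offset(position_bp, g)
  d <- if (spec$symmetric) pmin(off, g$length_bp - off) else off
  lam <- rep(1, length(off))
  for (wc in spec$wave_components) {
    p_bp <- wc$period_kb * 1000
    phase <- if (is.null(wc$phase)) 0 else wc$phase
    lam <- lam + wc$amplitude * cos(2 * pi * d / p_bp + phase)
  }
  tb <- spec$terminus_bump
  if (!is.null(tb)) {
    center <- tb$center_frac * g$length_bp
    dd <- pmin(abs(off - center), g$length_bp - abs(off - center))
    lam <- lam + tb$height * exp(-0.5 * (dd / tb$width_bp)^2)
  }
  lam
}

#' True expected per-bin intensity
#'
#' Mean of [wave_intensity()] over a 1-kb lattice within each bin; the
#' ground truth that recovered per-bin rates are compared against.
#'
#' @param spec a [sim_spec()].
#' @return numeric vector of length `n_bins`.
#' @export
true_bin_intensity <- function(spec) {
  g <- spec$genome
  grid <- seq(1, g$length_bp, by = 1000)
  lam <- wave_intensity(spec, grid)
  b <- assign_bin(grid, g)
  as.numeric(tapply(lam, factor(b, levels = seq_len(g$n_bins)), mean))
}

.random_reference <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# hot-spot site predicate on a reference string: A with 3' C, or T with
# 5' G (circular)
.is_hotspot_site <- function(reference, pos, len) {
  b <- base_at(reference, pos, len)
  (b == "A" & base_at(reference, pos + 1, len) == "C") |
    (b == "T" & base_at(reference, pos - 1, len) == "G")
}

#' Simulate a mutation-accumulation experiment
#'
#' Per line, the total mutation count is Poisson with mean
#' `generations_per_line * baseline_rate`; positions are drawn from the
#' relative intensity (sampled on a 1-kb lattice, then uniformly within
#' the chosen cell — the intensity varies on the >= 100-kb scale, so the
#' lattice is far below its resolution).  Duplicate positions are
#' allowed and counted separately, as in BPS tallies.  Without a
#' reference, ref/alt bases are uniform random (ref != alt); with
#' `hotspot` configured, a synthetic reference is generated, a fraction
#' `m * n_h / (m * n_h + (L - n_h))` of mutations (multiplier `m`,
#' `n_h` hot-spot sites) are placed on hot-spot sites by rejection
#' sampling and written as A>G / T>C transitions, and the rest on
#' non-hot-spot sites with ref matching the reference.
#'
#' @param spec a [sim_spec()].
#' @return object of class `synthetic_dataset`: list with `records`
#'   (mutation table), `meta` ([experiment_meta()]),
#'   `true_bin_intensity`, `reference` (or `NULL`), `spec`.  Identical
#'   output for identical seeds.
#' @export
simulate_experiment <- function(spec) {
  g <- spec$genome
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  n_lines <- spec$n_lines
  counts <- stats::rpois(n_lines, spec$generations_per_line *
                           spec$baseline_rate)
  total <- sum(counts)

  # intensity on a 1-kb lattice of cells; last cell may be short
  cell <- 1000
  starts <- seq(1, g$length_bp, by = cell)
  widths <- pmin(cell, g$length_bp - starts + 1)
  lam <- wave_intensity(spec, pmin(starts + widths %/% 2, g$length_bp)) *
    widths
  draw_positions <- function(k) {
    if (k == 0) return(numeric(0))
    ci <- sample.int(length(starts), k, replace = TRUE, prob = lam)
    starts[ci] + floor(stats::runif(k) * widths[ci])
  }

  reference <- NULL
  if (!is.null(spec$hotspot)) {
    reference <- .random_reference(g$length_bp)
    m <- spec$hotspot$nac_multiplier
    # Bernoulli(1/2 at A or T) x Bernoulli(1/4 neighbour): ~ L/8 sites
    pos_all <- draw_positions(total)
    hot <- .is_hotspot_site(reference, pos_all, g$length_bp)
    # accept non-hot sites with prob 1/m relative to hot sites
    keep <- hot | (stats::runif(total) < 1 / m)
    pos <- pos_all[keep]
    while (length(pos) < total) {
      extra <- draw_positions(2L * (total - length(pos)) + 10L)
      hot_e <- .is_hotspot_site(reference, extra, g$length_bp)
      keep_e <- hot_e | (stats::runif(length(extra)) < 1 / m)
      pos <- c(pos, extra[keep_e])
    }
    pos <- pos[seq_len(total)]
    ref <- base_at(reference, pos, g$length_bp)
    is_hot <- .is_hotspot_site(reference, pos, g$length_bp)
    alt <- character(total)
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(total)) {
      if (is_hot[i]) {
        alt[i] <- if (ref[i] == "A") "G" else "C"
      } else {
        alt[i] <- sample(setdiff(bases, ref[i]), 1L)
      }
    }
  } else {
    pos <- draw_positions(total)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, total, replace = TRUE)
    shift <- sample.int(3L, total, replace = TRUE)
    alt <- bases[((match(ref, bases) - 1L + shift) %% 4L) + 1L]
  }

  line_id <- rep(sprintf("line_%03d", seq_len(n_lines)), counts)
  records <- data.frame(line_id = line_id, position = as.numeric(pos),
                        ref = ref, alt = alt, stringsAsFactors = FALSE)
  meta <- experiment_meta(
    strain_id = "synthetic", n_lines = n_lines,
    total_generations = n_lines * spec$generations_per_line,
    per_line_generations = rep(spec$generations_per_line, n_lines),
    description = "synthetic MA experiment")
  structure(list(records = records, meta = meta,
                 true_bin_intensity = true_bin_intensity(spec),
                 reference = reference, spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d mutations, %d lines, %s generations\n",
              nrow(x$records), x$meta$n_lines,
              format(x$meta$total_generations, big.mark = ",")))
  invisible(x)
}

#' Preset emulating a mismatch-repair-deficient MA experiment
#'
#' Study-scale conditions scaled to a 40-line experiment: baseline rate
#' 0.113 BPS/generation (the pooled rate of the MMR-deficient collective,
#' 113 x 10^-3), 650 generations per line (26,000 total, ~3,000 expected
#' mutations), a symmetric two-component cosine wave with dominant period
#' 1,200 kb (~12 bins; amplitude 0.5 for a ~3-fold peak-to-trough swing)
#' plus a weak 600-kb harmonic, and a Gaussian terminus elevation.
#'
#' @param genome a [genome_map()] (default [ecoli_genome()]).
#' @param seed integer seed.
#' @return a [sim_spec()].
#' @export
mmr_like_preset <- function(genome = ecoli_genome(), seed = 1L) {
  sim_spec(
    genome = genome,
    baseline_rate = 0.113,
    wave_components = list(
      list(amplitude = 0.5, period_kb = 1200, phase = 0),
      list(amplitude = 0.15, period_kb = 600, phase = 0)),
    symmetric = TRUE,
    terminus_bump = list(center_frac = 0.5, width_bp = 250000,
                         height = 0.8),
    n_lines = 40L,
    generations_per_line = 650,
    seed = seed)
}
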