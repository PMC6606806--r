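# Clockwise/counterclockwise symmetry and region-stratified correlation
# tables.  A rate wave symmetric about the replication origin shows up
# two ways: the series read counterclockwise correlates with the series
# read clockwise, and the right replichore correlates with the mirrored
# left replichore.

#' Reverse a binned series to counterclockwise order
#'
#' `out[i] = in[n_bins + 1 - i]`: bin `n_bins` comes first because it is
#' the first bin encountered leaving the origin counterclockwise.  An
#' involution: applying it twice restores the input.
#'
#' @param series a [binned_series()] (or plain numeric vector).
#' @return the reversed series with the `direction` flag flipped.
#' @export
ccw_series <- function(series) {
  if (is.numeric(series)) return(rev(series))
  stopifnot(inherits(series, "binned_series"))
  out <- series
  out$counts <- rev(series$counts)
  out$rates <- rev(series$rates)
  out$direction <- if (series$direction == "cw") "ccw" else "cw"
  out
}

#' Pearson correlation over a region of bins
#'
#' Product-moment correlation of two per-bin series restricted to the
#' given bins, with a two-sided p-value from the exact t transform
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` (or a seeded permutation test).
#' Pearson's rho is invariant to affine rescaling of either argument, so
#' correlating rates, counts or proportions of pooled series is
#' equivalent.
#'
#' @param x,y numeric per-bin series (equal length).
#' @param bins integer bin indices to use (>= 3).
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm,seed permutation count and seed for
#'   `method = "permutation"`.
#' @return list with `rho`, `p_raw`, `n_bins_used`.
#' @export
pearson_region <- function(x, y, bins = seq_along(x),
                           method = c("t", "permutation"),
                           n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  bins <- as.integer(bins)
  if (any(bins < 1 | bins > length(x)))
    stop("bin index out of range", call. = FALSE)
  if (length(bins) < 3) stop("need at least 3 bins", call. = FALSE)
  xs <- x[bins]; ys <- y[bins]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("correlation undefined: constant series on region", call. = FALSE)
  if (method == "t") {
    ct <- stats::cor.test(xs, ys, method = "pearson")
    rho <- unname(ct$estimate)
    p <- ct$p.value
  } else {
    rho <- stats::cor(xs, ys)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    perm <- replicate(n_perm, stats::cor(xs, sample(ys)))
    p <- (1 + sum(abs(perm) >= abs(rho) - 1e-15)) / (n_perm + 1)
  }
  # perfect correlations give p = 0 exactly; clamp into (0, 1] so the
  # adjusted p-values stay in the BH domain
  list(rho = rho, p_raw = max(p, .Machine$double.xmin),
       n_bins_used = length(bins))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: after sorting ascending,
#' `q(i) = min_{j >= i} p(j) * m / j`, capped at 1 and restored to input
#' order.  Adjusted values are reported; callers flag significance
#' against a chosen FDR (0.25 in the correlation tables).
#'
#' @param p_values p-values in (0, 1].
#' @return adjusted p-values, same order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values) | p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Strain-versus-reference correlation table
#'
#' One row per strain and region: Pearson rho of the strain's per-bin
#' series against a reference series, restricted to each region of the
#' scheme (whole chromosome, right and left replichores, origin- and
#' terminus-proximal regions), with Benjamini-Hochberg adjustment applied
#' separately within each region column (comparisons within a column
#' share the reference, so columns are adjusted independently).
#'
#' @param strains named list of [binned_series()] (or per-bin numeric
#'   vectors).
#' @param reference the reference [binned_series()] (or numeric vector),
#'   e.g. the generation-weighted pool of the mismatch-repair-deficient
#'   experiments from [pool_series()].
#' @param scheme a [region_scheme()].
#' @param fdr FDR used for the significance flag (default 0.25).
#' @param use `"rates"` or `"counts"` when series objects are given
#'   (immaterial for rho; affects nothing but the stored values).
#' @return `data.frame` with columns `strain`, `region`, `rho`, `p_raw`,
#'   `p_adj`, `n_bins`, `significant_at_fdr`.
#' @export
correlation_table <- function(strains, reference, scheme, fdr = 0.25,
                              use = c("rates", "counts")) {
  use <- match.arg(use)
  as_vec <- function(s) if (is.numeric(s)) s else s[[use]]
  ref <- as_vec(reference)
  if (is.null(names(strains)))
    names(strains) <- vapply(strains, function(s)
      if (is.numeric(s)) "strain" else s$strain_id, character(1))
  rows <- list()
  for (nm in names(strains)) {
    sv <- as_vec(strains[[nm]])
    for (rg in names(scheme)) {
      pr <- pearson_region(sv, ref, bins = scheme[[rg]])
      rows[[length(rows) + 1L]] <-
        data.frame(strain = nm, region = rg, rho = pr$rho,
                   p_raw = pr$p_raw, n_bins = pr$n_bins_used)
    }
  }
  tab <- do.call(rbind, rows)
  tab$p_adj <- NA_real_
  for (rg in names(scheme)) {
    i <- tab$region == rg
    tab$p_adj[i] <- bh_adjust(tab$p_raw[i])
  }
  tab$significant_at_fdr <- tab$p_adj <= fdr
  tab <- tab[, c("strain", "region", "rho", "p_raw", "p_adj", "n_bins",
                 "significant_at_fdr")]
  attr(tab, "fdr") <- fdr
  tab
}

#' Right-versus-left replichore correlation table
#'
#' Pairs bin `i` (right replichore) with its mirror bin `n_bins + 1 - i`
#' (left replichore) and correlates the two half-series over the whole
#' pairing and its origin- and terminus-proximal strata.  A series
#' perfectly symmetric about the origin gives rho = 1 in every pairing.
#' BH adjustment is applied within each pairing column across strains.
#'
#' @param series_list a [binned_series()] or list of them (numeric
#'   vectors accepted).
#' @param genome a [genome_map()] (supplies the pairing); if `NULL`, the
#'   pairing is derived from the series length.
#' @param fdr FDR for the significance flag (default 0.25).
#' @param use `"rates"` or `"counts"`.
#' @return `data.frame` as in [correlation_table()], with `region` one of
#'   `whole`, `origin`, `terminus` (pairing strata).
#' @export
replichore_table <- function(series_list, genome = NULL, fdr = 0.25,
                             use = c("rates", "counts")) {
  use <- match.arg(use)
  if (inherits(series_list, "binned_series") || is.numeric(series_list))
    series_list <- list(series_list)
  as_vec <- function(s) if (is.numeric(s)) s else s[[use]]
  n <- length(as_vec(series_list[[1]]))
  if (is.null(genome))
    genome <- genome_map("generic", n * 1000, 1, n_bins = n)
  pr <- replichore_pairing(genome)
  if (is.null(names(series_list)))
    names(series_list) <- vapply(series_list, function(s)
      if (is.numeric(s)) "strain" else s$strain_id, character(1))
  rows <- list()
  for (nm in names(series_list)) {
    v <- as_vec(series_list[[nm]])
    right <- v[pr$right]
    left <- v[pr$left]
    for (rg in names(pr$pairings)) {
      idx <- pr$pairings[[rg]]
      res <- pearson_region(right, left, bins = idx)
      rows[[length(rows) + 1L]] <-
        data.frame(strain = nm, region = rg, rho = res$rho,
                   p_raw = res$p_raw, n_bins = res$n_bins_used)
    }
  }
  tab <- do.call(rbind, rows)
  tab$p_adj <- NA_real_
  for (rg in names(pr$pairings)) {
    i <- tab$region == rg
    tab$p_adj[i] <- bh_adjust(tab$p_raw[i])
  }
  tab$significant_at_fdr <- tab$p_adj <= fdr
  tab <- tab[, c("strain", "region", "rho", "p_raw", "p_adj", "n_bins",
                 "significant_at_fdr")]
  attr(tab, "fdr") <- fdr
  tab
}
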