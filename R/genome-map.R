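#' Circular chromosome geometry
#'
#' A `genome_map` describes the coordinate system of a circular bacterial
#' chromosome for origin-anchored analysis: its length, the 1-based
#' coordinate of the replication origin (OriC), and the number of bins the
#' circle is divided into.  Bin 1 starts at the origin and bins increase
#' clockwise (the direction of increasing genomic coordinate), wrapping at
#' `length_bp`.  Bin width is exactly `length_bp / n_bins`, so the bins
#' tile the circle with no remainder.
#'
#' @param name chromosome name.
#' @param length_bp chromosome length in bp (positive integer).
#' @param ori_position_bp 1-based coordinate of the replication origin.
#' @param n_bins number of bins (default 46, giving ~100-kb bins for the
#'   E. coli chromosome).
#' @param circular must be `TRUE`; kept explicit because all coordinate
#'   arithmetic assumes wraparound.
#' @return an object of class `genome_map`.
#' @examples
#' gm <- genome_map("chr", 4641652, 3925744)
#' bin_width_bp(gm)
#' @export
genome_map <- function(name, length_bp, ori_position_bp, n_bins = 46L,
                       circular = TRUE) {
  length_bp <- as.numeric(length_bp)
  ori_position_bp <- as.numeric(ori_position_bp)
  n_bins <- as.integer(n_bins)
  if (!isTRUE(circular))
    stop("only circular chromosomes are supported", call. = FALSE)
  if (is.na(length_bp) || length_bp < 1 || length_bp != floor(length_bp))
    stop("length_bp must be a positive integer", call. = FALSE)
  if (is.na(ori_position_bp) || ori_position_bp < 1 ||
      ori_position_bp > length_bp || ori_position_bp != floor(ori_position_bp))
    stop("ori_position_bp must lie in [1, length_bp]", call. = FALSE)
  if (is.na(n_bins) || n_bins < 4L)
    stop("n_bins must be >= 4", call. = FALSE)
  structure(
    list(name = as.character(name), length_bp = length_bp,
         ori_position_bp = ori_position_bp, n_bins = n_bins,
         circular = TRUE),
    class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("<genome_map> %s: %s bp, oriC at %s, %d bins of %.1f kb\n",
              x$name, format(x$length_bp, big.mark = ","),
              format(x$ori_position_bp, big.mark = ","),
              x$n_bins, bin_width_bp(x) / 1000))
  invisible(x)
}

#' Bin width in bp
#'
#' @param genome a [genome_map()].
#' @return `length_bp / n_bins` (generally not an integer).
#' @export
bin_width_bp <- function(genome) genome$length_bp / genome$n_bins

#' Default E. coli K-12 MG1655 genome map
#'
#' Reads the genome configuration shipped with the package
#' (`inst/extdata/ecoli_mg1655_genome.json`): 4,641,652 bp with OriC at
#' coordinate 3,925,744, divided into 46 origin-anchored bins.  These are
#' configuration values, not constants wired into the code; any genome can
#' be described with [genome_map()] or a JSON file via
#' [read_genome_config()].
#'
#' @param n_bins override the configured number of bins.
#' @return a `genome_map`.
#' @export
ecoli_genome <- function(n_bins = NULL) {
  path <- system.file("extdata", "ecoli_mg1655_genome.json",
                      package = "repliwave", mustWork = TRUE)
  gm <- read_genome_config(path)
  if (!is.null(n_bins)) gm$n_bins <- as.integer(n_bins)
  gm
}

#' Clockwise offset of a position from the replication origin
#'
#' @param position_bp 1-based genomic coordinate(s) in `[1, length_bp]`.
#' @param genome a [genome_map()].
#' @return 0-based clockwise offset(s) in `[0, length_bp)`:
#'   `(position_bp - ori_position_bp) mod length_bp`.
#' @export
clockwise_offset <- function(position_bp, genome) {
  position_bp <- as.numeric(position_bp)
  bad <- is.na(position_bp) | position_bp < 1 |
    position_bp > genome$length_bp | position_bp != floor(position_bp)
  if (any(bad))
    stop(sprintf("position out of range [1, %d]: %s", genome$length_bp,
                 paste(utils::head(position_bp[bad], 5), collapse = ", ")),
         call. = FALSE)
  (position_bp - genome$ori_position_bp) %% genome$length_bp
}

#' Assign genomic positions to origin-anchored bins
#'
#' Bins are half-open in offset space: bin `b` covers clockwise offsets
#' `[(b-1) * w, b * w)` with `w = length_bp / n_bins`.  Bin 1 starts at the
#' origin; bin `n_bins` ends just before it.  The floor is computed as
#' `floor(offset * n_bins / length_bp)` so that boundary assignment is
#' exact in integer arithmetic.
#'
#' @inheritParams clockwise_offset
#' @return integer bin indices in `1..n_bins`.
#' @export
assign_bin <- function(position_bp, genome) {
  off <- clockwise_offset(position_bp, genome)
  as.integer(floor(off * genome$n_bins / genome$length_bp)) + 1L
}

#' Region schemes over the bin circle
#'
#' Named collections of bin indices used to stratify correlations.  The
#' default scheme for 46 bins follows the standard replichore layout:
#' whole chromosome (bins 1-46), right replichore (bins 1-23, clockwise
#' from the origin), left replichore (bins 46 down to 24, counterclockwise
#' from the origin), origin-proximal region (bins 1-13 and 46-34) and
#' terminus-proximal region (bins 14-33).
#'
#' For general `n_bins` (even) the same construction is used: right =
#' `1..n/2`, left = `n..(n/2+1)`, origin = the ~28% of bins nearest the
#' origin on both sides, terminus = the complement.
#'
#' @param genome a [genome_map()].
#' @return an object of class `region_scheme`: a named list of integer
#'   bin-index vectors.
#' @export
region_scheme <- function(genome) {
  n <- genome$n_bins
  if (n %% 2L != 0L)
    stop("region schemes require an even number of bins", call. = FALSE)
  half <- n %/% 2L
  # origin arm length: 13 of 23 bins per replichore at n = 46
  arm <- as.integer(round(half * 13 / 23))
  structure(
    list(
      whole = seq_len(n),
      right_replichore = seq_len(half),
      left_replichore = seq.int(n, half + 1L),
      origin = c(seq_len(arm), seq.int(n - arm + 1L, n)),
      terminus = seq.int(arm + 1L, n - arm)
    ),
    n_bins = n, class = "region_scheme")
}

#' Look up the bins of a named region
#'
#' @param region_name one of the names in the scheme (e.g. `"whole"`,
#'   `"right_replichore"`, `"left_replichore"`, `"origin"`, `"terminus"`).
#' @param scheme a [region_scheme()].
#' @return integer vector of bin indices.
#' @export
region_bins <- function(region_name, scheme) {
  if (!region_name %in% names(scheme))
    stop(sprintf("unknown region '%s' (available: %s)", region_name,
                 paste(names(scheme), collapse = ", ")), call. = FALSE)
  scheme[[region_name]]
}

#' Replichore pairing of bins
#'
#' Pairs bin `i` on the right replichore with its mirror bin `n_bins+1-i`
#' on the left replichore (bin 1 with bin 46, 2 with 45, ...), the pairing
#' used for right-versus-left symmetry correlations.  The named pairings
#' stratify by region: `whole` = all `n/2` pairs, `origin` = the
#' origin-proximal pairs (1-13 vs 46-34 at 46 bins), `terminus` = the
#' terminus-proximal pairs (14-23 vs 33-24).
#'
#' @param genome a [genome_map()].
#' @return list with elements `right` (bin indices `1..n/2`), `left` (the
#'   mirrored indices `n..(n/2+1)`), and `pairings`, a named list of index
#'   vectors into the right/left vectors.
#' @export
replichore_pairing <- function(genome) {
  n <- genome$n_bins
  if (n %% 2L != 0L)
    stop("replichore pairing requires an even number of bins", call. = FALSE)
  half <- n %/% 2L
  arm <- as.integer(round(half * 13 / 23))
  list(
    right = seq_len(half),
    left = n + 1L - seq_len(half),
    pairings = list(
      whole = seq_len(half),
      origin = seq_len(arm),
      terminus = seq.int(arm + 1L, half)
    ))
}
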