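# Readers, writers and the end-to-end pipeline.  Formats are deliberately
# plain: TSV mutation tables, JSON genome configs and manifests,
# single-record FASTA references, and a minimal VCF dialect
# (CHROM/POS/REF/ALT) for interoperability with variant callers.

#' Read a genome configuration
#'
#' JSON with keys `name`, `length_bp`, `ori_position_bp` and optionally
#' `n_bins` (default 46).
#'
#' @param path JSON file path.
#' @return a [genome_map()].
#' @export
read_genome_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  genome_map(name = cfg$name, length_bp = cfg$length_bp,
             ori_position_bp = cfg$ori_position_bp,
             n_bins = if (is.null(cfg$n_bins)) 46L else cfg$n_bins)
}

#' Read mutation calls from TSV or VCF
#'
#' TSV: tab-separated with header `line_id`, `position`, `ref`, `alt`.
#' VCF: SNV rows of a standard VCF (CHROM/POS/REF/ALT; multi-allelic and
#' non-SNV rows rejected); the line id is taken from the first sample
#' column name or, failing that, the file name.  Malformed rows are
#' reported with their line numbers.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"` (default guessed from the extension).
#' @param genome optional [genome_map()] for coordinate validation.
#' @return validated mutation-record `data.frame`.
#' @export
read_mutations <- function(path, format = NULL, genome = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  format <- match.arg(format, c("tsv", "vcf"))
  if (format == "tsv") {
    rec <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character",
                             stringsAsFactors = FALSE)
    need <- c("line_id", "position", "ref", "alt")
    if (!all(need %in% names(rec)))
      stop(sprintf("%s: TSV header must contain %s", path,
                   paste(need, collapse = ", ")), call. = FALSE)
    pos <- suppressWarnings(as.numeric(rec$position))
    bad <- which(is.na(pos) | pos < 1 | pos != floor(pos) |
                   !(toupper(rec$ref) %in% c("A", "C", "G", "T")) |
                   !(toupper(rec$alt) %in% c("A", "C", "G", "T")) |
                   toupper(rec$ref) == toupper(rec$alt))
    if (!is.null(genome)) bad <- union(bad, which(pos > genome$length_bp))
    if (length(bad) > 0)
      stop(sprintf("%s: malformed mutation rows at data lines: %s", path,
                   paste(utils::head(sort(bad), 10), collapse = ", ")),
           call. = FALSE)
    mutation_records(rec$line_id, pos, rec$ref, rec$alt, genome)
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the vcfR package", call. = FALSE)
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                  dimnames = dimnames(fix))
    ref <- toupper(fix[, "REF"])
    alt <- toupper(fix[, "ALT"])
    bad <- which(nchar(ref) != 1 | nchar(alt) != 1 | grepl(",", alt))
    if (length(bad) > 0)
      stop(sprintf("%s: non-SNV or multi-allelic VCF rows: %s", path,
                   paste(utils::head(bad, 10), collapse = ", ")),
           call. = FALSE)
    samp <- colnames(v@gt)
    line_id <- if (!is.null(samp) && length(samp) > 1) samp[2]
               else sub("\\.vcf(\\.gz)?$", "", basename(path))
    mutation_records(rep(line_id, nrow(fix)),
                     as.numeric(fix[, "POS"]), ref, alt, genome)
  }
}

#' Write a mutation table as TSV
#'
#' @param records mutation-record `data.frame`.
#' @param path output path.
#' @export
write_mutations <- function(records, path) {
  utils::write.table(records[, c("line_id", "position", "ref", "alt")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a single-record FASTA reference
#'
#' @param path FASTA file.
#' @param genome optional [genome_map()]; the sequence length must equal
#'   `length_bp`.
#' @return the sequence as one upper-case character string.
#' @export
read_fasta_reference <- function(path, genome = NULL) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) != 1)
      stop("reference FASTA must contain exactly one record", call. = FALSE)
    seq <- toupper(as.character(ss[[1]]))
  } else {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    if (length(hdr) != 1)
      stop("reference FASTA must contain exactly one record", call. = FALSE)
    seq <- toupper(paste(lines[-hdr], collapse = ""))
  }
  if (!is.null(genome) && nchar(seq) != genome$length_bp)
    stop(sprintf("reference length %d != genome length %d", nchar(seq),
                 genome$length_bp), call. = FALSE)
  seq
}

#' Write a binned series as TSV
#'
#' Columns `bin`, `count`, `rate` plus any extra columns supplied.
#'
#' @param series a [binned_series()].
#' @param path output path.
#' @param extra optional `data.frame` of extra per-bin columns.
#' @export
write_binned_series <- function(series, path, extra = NULL) {
  df <- data.frame(bin = seq_len(series$n_bins), count = series$counts,
                   rate = signif(series$rates, 6))
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a coherence map as columnar text
#'
#' Long format: one row per (scale, bin) with the coherence, phase and an
#' in-coi flag.
#'
#' @param cm a [wavelet_coherence()] result.
#' @param path output path.
#' @export
write_coherence <- function(cm, path) {
  df <- data.frame(
    scale = rep(signif(cm$scales, 6), times = cm$n),
    period_bins = rep(signif(cm$periods, 6), times = cm$n),
    bin = rep(seq_len(cm$n), each = length(cm$scales)),
    coherence = signif(as.vector(cm$coherence), 6),
    phase = signif(as.vector(cm$phase), 6),
    in_coi = as.vector(cm$in_coi))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the wave-analysis pipeline end to end
#'
#' Bins the mutation calls of one experiment, computes the per-bin rates
#' and rate table, the wavelet smooth, the clockwise-versus-
#' counterclockwise wavelet coherence, the right-versus-left replichore
#' correlation table and, when a reference series is supplied, the
#' strain-versus-reference region correlation table.  All tables are
#' written as TSV under `out_dir` together with a JSON manifest recording
#' parameters and seed; rerunning with the same inputs and seed
#' reproduces the outputs byte for byte.
#'
#' @param records mutation-record `data.frame`.
#' @param genome a [genome_map()].
#' @param meta an [experiment_meta()].
#' @param out_dir output directory (created if missing).
#' @param reference_series optional [binned_series()] to correlate
#'   against; when `NULL` the comparison stage is skipped with a warning.
#' @param smooth_level,wavelet_order smoothing parameters
#'   (see [wave_smooth()]).
#' @param scales,omega0 coherence parameters (see [wavelet_coherence()]).
#' @param fdr FDR for significance flags (default 0.25).
#' @param seed seed recorded in the manifest and used by any resampling.
#' @return (invisibly) list with `series`, `smooth`, `coherence`,
#'   `replichore`, `versus_reference` (or `NULL`), `rate`, `manifest`.
#' @export
run_pipeline <- function(records, genome, meta, out_dir,
                         reference_series = NULL, smooth_level = 2L,
                         wavelet_order = 4L, scales = scale_grid(),
                         omega0 = 6, fdr = 0.25, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  series <- stage("bin", bin_mutations(records, genome, meta))
  sm <- stage("smooth", smooth_series(series, level = smooth_level,
                                      order = wavelet_order))
  write_binned_series(series, file.path(out_dir, "binned_series.tsv"),
                      extra = data.frame(smoothed = signif(sm$smoothed, 6)))
  rate <- stage("rates", {
    per_line <- table(factor(records$line_id,
                             levels = unique(records$line_id)))
    cl <- if (!is.null(meta$per_line_generations) &&
              length(per_line) == length(meta$per_line_generations) &&
              length(per_line) >= 2)
      rate_cl95(as.numeric(per_line), meta$per_line_generations,
                seed = seed)
    else c(low = NA_real_, high = NA_real_)
    data.frame(strain = meta$strain_id, n_lines = meta$n_lines,
               bps_count = nrow(records),
               generations = meta$total_generations,
               rate_per_gen_x1000 = genome_rate(nrow(records),
                                                meta$total_generations),
               cl95_low = cl[["low"]], cl95_high = cl[["high"]])
  })
  utils::write.table(rate, file.path(out_dir, "rate_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- stage("coherence",
              wavelet_coherence(series$rates, ccw_series(series)$rates,
                                scales = scales, omega0 = omega0))
  write_coherence(cm, file.path(out_dir, "cw_ccw_coherence.tsv"))
  rep_tab <- stage("replichore", replichore_table(series, genome,
                                                  fdr = fdr))
  utils::write.table(rep_tab, file.path(out_dir, "replichore_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  vs <- NULL
  if (!is.null(reference_series)) {
    vs <- stage("compare",
                correlation_table(stats::setNames(list(series),
                                                  meta$strain_id),
                                  reference_series, region_scheme(genome),
                                  fdr = fdr))
    utils::write.table(vs, file.path(out_dir, "versus_reference.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    warning("no reference series supplied; comparison stage skipped",
            call. = FALSE)
  }
  manifest <- list(
    package = "repliwave",
    version = as.character(utils::packageVersion("repliwave")),
    genome = genome[c("name", "length_bp", "ori_position_bp", "n_bins")],
    strain = meta$strain_id, n_mutations = nrow(records),
    total_generations = meta$total_generations,
    parameters = list(smooth_level = smooth_level,
                      wavelet_order = wavelet_order, omega0 = omega0,
                      scales = signif(scales, 6), fdr = fdr),
    seed = seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(series = series, smooth = sm, coherence = cm,
                 replichore = rep_tab, versus_reference = vs, rate = rate,
                 manifest = manifest))
}
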