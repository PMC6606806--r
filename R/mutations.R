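#' Mutation record tables
#'
#' A mutation table is a plain `data.frame` with columns `line_id`
#' (character), `position` (1-based bp), `ref` and `alt` (single bases in
#' A/C/G/T, `ref != alt`), one row per base-pair substitution (BPS) call.
#'
#' @param line_id character vector of MA line identifiers.
#' @param position 1-based genomic coordinates.
#' @param ref,alt reference and alternate bases.
#' @param genome optional [genome_map()]; when given, positions are
#'   validated against it.
#' @return a validated `data.frame` of mutation records.
#' @export
mutation_records <- function(line_id, position, ref, alt, genome = NULL) {
  rec <- data.frame(line_id = as.character(line_id),
                    position = as.numeric(position),
                    ref = toupper(as.character(ref)),
                    alt = toupper(as.character(alt)),
                    stringsAsFactors = FALSE)
  validate_mutations(rec, genome)
}

#' @rdname mutation_records
#' @param records a mutation-record `data.frame`.
#' @export
validate_mutations <- function(records, genome = NULL) {
  need <- c("line_id", "position", "ref", "alt")
  if (!all(need %in% names(records)))
    stop("mutation table must have columns line_id, position, ref, alt",
         call. = FALSE)
  bases <- c("A", "C", "G", "T")
  bad <- which(!(records$ref %in% bases) | !(records$alt %in% bases) |
                 records$ref == records$alt |
                 is.na(records$position) | records$position < 1 |
                 records$position != floor(records$position))
  if (!is.null(genome))
    bad <- union(bad, which(records$position > genome$length_bp))
  if (length(bad) > 0)
    stop(sprintf("invalid mutation records at rows: %s",
                 paste(utils::head(sort(bad), 10), collapse = ", ")),
         call. = FALSE)
  records
}

#' Experiment metadata
#'
#' Bookkeeping for one mutation-accumulation experiment: strain, number of
#' independent lines and generations of single-cell bottleneck growth.
#' Mutation rates are mutations per generation, so generations are the
#' denominator of every rate in the package.
#'
#' @param strain_id strain identifier.
#' @param n_lines number of independent MA lines.
#' @param total_generations summed generations over all lines.
#' @param per_line_generations optional vector of per-line generations;
#'   must have length `n_lines` and sum to `total_generations`.
#' @param description free-text description.
#' @return an object of class `experiment_meta`.
#' @export
experiment_meta <- function(strain_id, n_lines, total_generations,
                            per_line_generations = NULL, description = "") {
  n_lines <- as.integer(n_lines)
  total_generations <- as.numeric(total_generations)
  if (is.na(total_generations) || total_generations <= 0)
    stop("total_generations must be > 0", call. = FALSE)
  if (!is.null(per_line_generations)) {
    per_line_generations <- as.numeric(per_line_generations)
    if (length(per_line_generations) != n_lines)
      stop("per_line_generations must have length n_lines", call. = FALSE)
    if (abs(sum(per_line_generations) - total_generations) >
        1e-6 * max(1, abs(total_generations)))
      stop("per_line_generations must sum to total_generations",
           call. = FALSE)
  }
  structure(list(strain_id = as.character(strain_id),
                 description = as.character(description),
                 n_lines = n_lines,
                 total_generations = total_generations,
                 per_line_generations = per_line_generations),
            class = "experiment_meta")
}

#' @export
print.experiment_meta <- function(x, ...) {
  cat(sprintf("<experiment_meta> %s: %d lines, %s generations\n",
              x$strain_id, x$n_lines,
              format(x$total_generations, big.mark = ",")))
  invisible(x)
}
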