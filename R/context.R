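# Trinucleotide mutation-context classification.
#
# In mismatch-repair-deficient E. coli the BPS spectrum is dominated by
# A:T -> G:C transitions at 5'NAC3'/3'NTG5' sites: the mutated base is the
# A of a 5'NAC3' triplet read on either strand.  On the plus strand that
# is an A whose 3' neighbour is C; the complementary-strand case is a T
# whose 5' neighbour is G (the plus strand then reads 5'GTN3', whose
# complement is 5'NAC3' with the paired A mutated).  The chromosome is
# circular, so neighbours wrap around the sequence ends.

base_at <- function(reference, pos, len) {
  # circular 1-based lookup
  p <- ((pos - 1) %% len) + 1
  substring(reference, p, p)
}

#' Classify the trinucleotide context and class of a mutation
#'
#' @param records mutation-record `data.frame` (see [mutation_records()]).
#' @param reference single reference sequence as one character string
#'   (plus strand, A/C/G/T), with length equal to the genome length.
#'   Records are expected on the plus strand: `ref` must match the
#'   reference base at `position`.
#' @return the records with two added columns: `context` (`"hotspot_NAC"`
#'   if the mutated base is the A of a 5'NAC3' triplet on either strand,
#'   else `"other"`) and `class` (`"AT_to_GC_transition"` for A>G or T>C,
#'   else `"other"`).
#' @export
classify_context <- function(records, reference) {
  reference <- toupper(reference)
  len <- nchar(reference)
  validate_mutations(records)
  if (nrow(records) == 0) {
    records$context <- character(0)
    records$class <- character(0)
    return(records)
  }
  if (any(records$position > len))
    stop("record position beyond reference length", call. = FALSE)
  ref_base <- base_at(reference, records$position, len)
  mism <- which(ref_base != records$ref)
  if (length(mism) > 0)
    stop(sprintf("ref base does not match reference at rows: %s",
                 paste(utils::head(mism, 10), collapse = ", ")),
         call. = FALSE)
  next_base <- base_at(reference, records$position + 1, len)
  prev_base <- base_at(reference, records$position - 1, len)
  hot <- (records$ref == "A" & next_base == "C") |
         (records$ref == "T" & prev_base == "G")
  at_gc <- (records$ref == "A" & records$alt == "G") |
           (records$ref == "T" & records$alt == "C")
  records$context <- ifelse(hot, "hotspot_NAC", "other")
  records$class <- ifelse(at_gc, "AT_to_GC_transition", "other")
  records
}

#' Remove hot-spot A:T transitions
#'
#' Drops every record that is an A:T -> G:C transition at a
#' 5'NAC3'/3'NTG5' site, the filter used to test whether the chromosomal
#' rate wave merely reflects the distribution of these hot-spot triplets.
#' Row order of the survivors is preserved.
#'
#' @inheritParams classify_context
#' @return the filtered records (classification columns retained).
#' @export
filter_hotspots <- function(records, reference) {
  cls <- classify_context(records, reference)
  keep <- !(cls$context == "hotspot_NAC" & cls$class == "AT_to_GC_transition")
  out <- cls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reverse complement of a plus-strand sequence string
#'
#' @param seq character string of A/C/G/T.
#' @return the reverse complement.
#' @export
revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(toupper(seq), "")[[1]]), collapse = ""))
}
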