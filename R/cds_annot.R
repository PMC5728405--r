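# Coding-coordinate arithmetic for substitutions: CDS nucleotide position to
# codon index, and consequence annotation (silent/missense/nonsense) via the
# standard genetic code.  CDS positions are 1-based with the A of the ATG
# start codon at position 1.

#' Codon index and within-codon position of a CDS nucleotide
#'
#' `codon_index = floor((pos - 1)/3) + 1`;
#' `position_in_codon = ((pos - 1) mod 3) + 1`.  Codon c therefore covers
#' coding nucleotides `3c - 2 .. 3c`.
#'
#' @param cds_position 1-based coding nucleotide position(s), >= 1.
#' @return data.frame with `cds_position`, `codon_index`,
#'   `position_in_codon`.
#' @export
#' @examples
#' codon_of(301)   # codon 101, first codon position
#' codon_of(2509)  # codon 837
codon_of <- function(cds_position) {
  if (any(cds_position < 1) || any(cds_position != round(cds_position)))
    stop("cds_position must be a positive integer (1-based)", call. = FALSE)
  p <- as.integer(cds_position)
  data.frame(cds_position = p,
             codon_index = (p - 1L) %/% 3L + 1L,
             position_in_codon = (p - 1L) %% 3L + 1L)
}

#' Annotate a single-nucleotide substitution in a CDS
#'
#' Checks the reference base, swaps in the alternate base, and classifies
#' the consequence with the standard nuclear genetic code: `silent`
#' (synonymous), `missense`, `nonsense` (stop gained) or `stop_lost`.  For a
#' nonsense change, `truncated_length` is the number of residues retained
#' before the new stop, `codon_index - 1` (the stop replaces the residue).
#'
#' @param cds_sequence coding sequence (ACGT string), length divisible by 3,
#'   starting at the ATG.
#' @param cds_position 1-based position of the substitution.
#' @param ref,alt reference and alternate bases (single characters).
#' @return one-row data.frame: position, codon arithmetic, `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa`, `consequence`, `truncated_length`.
#' @export
annotate_substitution <- function(cds_sequence, cds_position, ref, alt) {
  cds_sequence <- toupper(cds_sequence)
  ref <- toupper(ref); alt <- toupper(alt)
  L <- nchar(cds_sequence)
  if (L %% 3 != 0) stop("CDS length must be divisible by 3", call. = FALSE)
  if (cds_position > L) stop("cds_position beyond CDS end", call. = FALSE)
  if (grepl("[^ACGT]", cds_sequence))
    stop("CDS must contain only A, C, G, T", call. = FALSE)
  stopifnot(ref %in% c("A", "C", "G", "T"), alt %in% c("A", "C", "G", "T"))
  at <- substr(cds_sequence, cds_position, cds_position)
  if (at != ref)
    stop("reference mismatch at position ", cds_position, ": CDS has ", at,
         ", expected ", ref, call. = FALSE)
  co <- codon_of(cds_position)
  start <- 3L * (co$codon_index - 1L) + 1L
  ref_codon <- substr(cds_sequence, start, start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, co$position_in_codon, co$position_in_codon) <- alt
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  consequence <- if (alt_aa == ref_aa) "silent"
    else if (alt_aa == "*") "nonsense"
    else if (ref_aa == "*") "stop_lost"
    else "missense"
  data.frame(cds_position = co$cds_position, codon_index = co$codon_index,
             position_in_codon = co$position_in_codon,
             ref_codon = ref_codon, alt_codon = alt_codon,
             ref_aa = ref_aa, alt_aa = alt_aa, consequence = consequence,
             truncated_length = if (consequence == "nonsense")
               co$codon_index - 1L else NA_integer_)
}
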