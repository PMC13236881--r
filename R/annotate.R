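#' Annotate cysteine residues in protein sequences
#'
#' ArsR-family repressors coordinate As(III) through cysteine thiols, so
#' the count and placement of Cys residues is the first-order predictor
#' of binding competence. This annotates each sequence with its length,
#' cysteine count and 1-based cysteine positions, for joining onto
#' affinity reports by label.
#'
#' @param sequences Path to an amino-acid FASTA file, a
#'   [Biostrings::AAStringSet], or a named character vector of sequences.
#' @return A tibble with columns `id`, `length`, `cysteine_count`,
#'   `cysteine_positions` (semicolon-separated 1-based positions; empty
#'   string when none).
#' @export
#' @examples
#' annotate_cysteines(c(x = "ACDC"))
annotate_cysteines <- function(sequences) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    sequences <- Biostrings::readAAStringSet(sequences)
  }
  if (inherits(sequences, "AAStringSet")) {
    ids <- names(sequences) %||% as.character(seq_along(sequences))
    seqs <- as.character(sequences)
  } else if (is.character(sequences)) {
    ids <- names(sequences) %||% as.character(seq_along(sequences))
    seqs <- unname(sequences)
  } else {
    abort("Supply a FASTA path, an AAStringSet, or a character vector.",
          class = "arsbind_invalid_argument")
  }
  if (length(seqs) == 0L) {
    abort("No sequences to annotate.", class = "arsbind_invalid_argument")
  }
  seqs <- toupper(seqs)
  # nucleotide heuristic: exclusively ACGTUN letters with >= 3 of the four
  # bases present (A, C, G and T are all also valid amino-acid codes)
  looks_nuc <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    if (length(ch) == 0) return(FALSE)
    all(ch %in% c("A", "C", "G", "T", "U", "N")) &&
      sum(c("A", "C", "G", "T", "U") %in% ch) >= 3
  }, logical(1))
  if (all(looks_nuc) && sum(nchar(seqs)) > 40) {
    warn("Sequences look nucleotide-like; cysteine annotation expects amino acids.")
  }
  purrr::map_dfr(seq_along(seqs), function(i) {
    pos <- which(strsplit(seqs[i], "")[[1]] == "C")
    tibble(
      id = ids[i],
      length = nchar(seqs[i]),
      cysteine_count = length(pos),
      cysteine_positions = paste(pos, collapse = ";")
    )
  })
}
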