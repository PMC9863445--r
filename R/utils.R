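## Small shared helpers. Sequences are stored as DNA (T, not U) throughout;
## RNA semantics (U, G:U wobbles) are applied at the target-scanning boundary.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA sequences
#'
#' Vectorised reverse complement over character vectors of DNA sequences
#' (alphabet ACGTN).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")   # "ACGT"
#' revcomp("AAACC")  # "GGTTT"
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## DNA -> RNA transliteration (T -> U), used for display and NN lookups.
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

## Split a single sequence into a character vector of bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## Random DNA sequence(s); relies on the caller having seeded the RNG.
random_dna <- function(n, len, probs = rep(0.25, 4)) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
}

## Stop unless all sequences are non-empty ACGT strings.
check_dna <- function(x, what = "sequence") {
  bad <- !grepl("^[ACGTacgt]+$", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters or is empty (first offender: '%s')",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(toupper(x))
}
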