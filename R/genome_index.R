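## Exact-match k-mer index over a genome. Queries return every occurrence of
## a pattern on either strand; a hit on the minus strand means the pattern
## equals the reverse complement of the genome slice at the reported
## coordinates. Built as a hash from every k-mer of the plus strand to its
## global offsets; a query seeds on its first k-mer and verifies candidates
## by direct substring comparison, so results are exact, not heuristic.

#' Build an exact k-mer index over a genome
#'
#' @param genome named character vector of chromosome/scaffold sequences, a
#'   `DNAStringSet`, or the path to a genome FASTA file.
#' @param k seed k-mer length; must not exceed the shortest query. Default 12,
#'   comfortably below the 24 nt lower piRNA bound.
#' @return an object of class `genome_index`.
#' @export
build_genome_index <- function(genome, k = 12L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      !grepl("^[ACGTNacgtn]+$", genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), sub("\\s.*$", "", names(genome)))
  }
  stopifnot(is.character(genome), length(genome) >= 1, !is.null(names(genome)))
  if (anyDuplicated(names(genome))) {
    stop("duplicate seq_id in genome: ",
         names(genome)[anyDuplicated(names(genome))], call. = FALSE)
  }
  genome <- toupper(genome)
  k <- as.integer(k)
  stopifnot(k >= 4L)
  lens <- nchar(genome)
  ## global offset of position 1 of each sequence in the virtual concatenation
  offsets <- cumsum(c(0L, head(lens, -1L)))
  names(offsets) <- names(genome)
  all_kmers <- character(0)
  all_pos <- integer(0)
  for (i in seq_along(genome)) {
    s <- genome[[i]]
    n <- lens[[i]]
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    all_kmers <- c(all_kmers, substring(s, starts, starts + k - 1L))
    all_pos <- c(all_pos, starts + offsets[[i]])
  }
  kmer_map <- list2env(split(all_pos, all_kmers), hash = TRUE,
                       parent = emptyenv())
  structure(list(sequences = genome, k = k, lens = lens, offsets = offsets,
                 kmer_map = kmer_map),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("Genome k-mer index:", length(x$sequences), "sequence(s),",
      sum(x$lens), "bp total, k =", x$k, "\n")
  invisible(x)
}

## Map a global offset back to (seq index, local 1-based position).
decode_offset <- function(index, gpos) {
  si <- findInterval(gpos, index$offsets + 1L)
  data.frame(seq_id = names(index$sequences)[si],
             start = as.integer(gpos - index$offsets[si]),
             stringsAsFactors = FALSE)
}

## Plus-strand occurrences of `pattern` allowing `max_mismatches` Hamming
## mismatches. Pigeonhole seeding: one of max_mismatches+1 disjoint k-mer
## chunks must be exact, so every true hit is found.
plus_strand_hits <- function(index, pattern, max_mismatches = 0L) {
  L <- nchar(pattern)
  k <- index$k
  n_chunks <- max_mismatches + 1L
  if (L < n_chunks * k) {
    stop("query of length ", L, " too short for k = ", k, " with ",
         max_mismatches, " mismatch(es)", call. = FALSE)
  }
  chunk_starts <- 1L + (seq_len(n_chunks) - 1L) * k
  cand <- integer(0)
  for (cs in chunk_starts) {
    seed <- substr(pattern, cs, cs + k - 1L)
    hits <- index$kmer_map[[seed]]
    if (!is.null(hits)) cand <- c(cand, hits - (cs - 1L))
  }
  cand <- sort(unique(cand))
  if (length(cand) == 0L) return(integer(0))
  ## verify candidates: stay inside one sequence, Hamming distance within cap
  ok <- logical(length(cand))
  for (i in seq_along(cand)) {
    gpos <- cand[i]
    if (gpos < 1L) next
    si <- findInterval(gpos, index$offsets + 1L)
    local <- gpos - index$offsets[si]
    if (local + L - 1L > index$lens[si]) next
    window <- substr(index$sequences[[si]], local, local + L - 1L)
    if (max_mismatches == 0L) {
      ok[i] <- window == pattern
    } else {
      d <- sum(seq_chars(window) != seq_chars(pattern))
      ok[i] <- d <= max_mismatches
    }
  }
  cand[ok]
}

#' Query a genome index for all occurrences of a pattern
#'
#' Returns every locus on either strand where the pattern occurs (optionally
#' within a Hamming-distance mismatch budget). Minus-strand loci are reported
#' in plus-strand coordinates of the matching slice.
#'
#' @param index a `genome_index`.
#' @param pattern a single DNA sequence (length >= `(max_mismatches+1) * k`).
#' @param max_mismatches allowed mismatches (default 0, exact).
#' @return `data.frame` with columns `seq_id`, `start` (1-based), `strand`.
#' @export
query_index <- function(index, pattern, max_mismatches = 0L) {
  pattern <- toupper(pattern)
  fwd <- plus_strand_hits(index, pattern, max_mismatches)
  rcp <- revcomp(pattern)
  rev <- plus_strand_hits(index, rcp, max_mismatches)
  ## a palindromic pattern matches both strands at the same slice
  out <- rbind(
    if (length(fwd)) cbind(decode_offset(index, fwd), strand = "+"),
    if (length(rev)) cbind(decode_offset(index, rev), strand = "-")
  )
  if (is.null(out)) {
    out <- data.frame(seq_id = character(), start = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  }
  out[order(out$seq_id, out$start, out$strand), , drop = FALSE]
}
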