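## Convenience wrapper chaining the discovery stages on one input bundle.

#' Run the piRNA discovery pipeline
#'
#' Chains collection, genome mapping, annotation-cascade classification,
#' piRNA calling and TPM normalisation. Downstream steps (group comparison,
#' differential screen, target scan, enrichment, network) take this result's
#' components directly.
#'
#' @param libraries named list of per-sample tag `data.frame`s (`tag_id`,
#'   `sequence`, `count`), e.g. from [read_fasta_counts()] per sample or a
#'   [simulate_world()] object's `libraries`.
#' @param genome named character vector / `DNAStringSet` / FASTA path.
#' @param annotation annotation `data.frame` (see [read_gff3()]).
#' @param library_sizes named vector of total clean sRNA reads per sample;
#'   defaults to the per-sample tag-count sums.
#' @param max_mismatches genome-mapping mismatch budget (default 0).
#' @param stranded strand-aware annotation overlap (default `TRUE`).
#' @param min_len,max_len piRNA length window (defaults 24, 33).
#' @param k k-mer size for the genome index.
#' @return list with `tags`, `index`, `mapped`, `classified`, `pirnas`
#'   (a `pirna_set`) and `expr` (an `expression_matrix`).
#' @export
run_pirna_pipeline <- function(libraries, genome, annotation,
                               library_sizes = NULL, max_mismatches = 0L,
                               stranded = TRUE, min_len = 24L, max_len = 33L,
                               k = 12L) {
  tags <- collect_libraries(libraries)
  if (is.null(library_sizes)) library_sizes <- colSums(tags$counts)
  index <- build_genome_index(genome, k = k)
  mapped <- map_tags(tags, index, max_mismatches = max_mismatches)
  classified <- classify_tags(mapped, annotation, stranded = stranded)
  pirnas <- call_pirnas(classified, min_len = min_len, max_len = max_len)
  expr <- tpm_normalize(pirnas$counts, library_sizes)
  list(tags = tags, index = index, mapped = mapped, classified = classified,
       pirnas = pirnas, expr = expr)
}
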