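## The filter cascade: map tags to the genome, label any tag overlapping an
## annotated small ncRNA feature (rRNA > tRNA > snRNA > snoRNA > scRNA >
## miRNA), and pass the remainder on as the piRNA candidate pool.

#' Map small-RNA tags to the genome
#'
#' Enumerates every genomic locus of every tag using an exact k-mer index
#' (optionally within a mismatch budget). Tags with zero loci are excluded
#' from the result and tallied in the mapping report, not treated as errors.
#'
#' @param x an `srna_tags` collection from [collect_libraries()].
#' @param index a [build_genome_index()] object.
#' @param max_mismatches allowed mismatches per alignment (default 0, exact).
#' @return an object of class `mapped_tags`: list with `tags` (the mapped
#'   subset, plus an `n_loci` column), `counts` (matching count matrix),
#'   `loci` (`data.frame` of `tag_id`, `seq_id`, `start`, `strand`) and
#'   `report` (input/mapped/unmapped totals).
#' @export
map_tags <- function(x, index, max_mismatches = 0L) {
  stopifnot(inherits(x, "srna_tags"), inherits(index, "genome_index"))
  hit_list <- lapply(x$tags$sequence, query_index, index = index,
                     max_mismatches = max_mismatches)
  n_loci <- vapply(hit_list, nrow, integer(1))
  keep <- n_loci > 0L
  loci <- do.call(rbind, lapply(which(keep), function(i) {
    cbind(tag_id = x$tags$tag_id[i], hit_list[[i]])
  }))
  if (is.null(loci)) {
    loci <- data.frame(tag_id = character(), seq_id = character(),
                       start = integer(), strand = character(),
                       stringsAsFactors = FALSE)
  }
  rownames(loci) <- NULL
  tags <- x$tags[keep, , drop = FALSE]
  tags$n_loci <- n_loci[keep]
  rownames(tags) <- NULL
  structure(list(tags = tags,
                 counts = x$counts[keep, , drop = FALSE],
                 loci = loci,
                 report = list(n_input = nrow(x$tags),
                               n_mapped = sum(keep),
                               n_unmapped = sum(!keep),
                               unmapped_ids = x$tags$tag_id[!keep])),
            class = "mapped_tags")
}

#' @export
print.mapped_tags <- function(x, ...) {
  cat("Mapped tags:", x$report$n_mapped, "of", x$report$n_input,
      "tags mapped (", x$report$n_unmapped, "unmapped )\n")
  invisible(x)
}

#' Classify mapped tags against an ncRNA annotation
#'
#' A tag whose loci overlap (by at least 1 bp) any annotated feature of a
#' filtered ncRNA class receives that class as its label; with several
#' overlapping classes the fixed cascade priority
#' rRNA > tRNA > snRNA > snoRNA > scRNA > miRNA decides. Tags overlapping
#' nothing in the filtered classes are labelled `candidate_pool`.
#'
#' @param mapped a `mapped_tags` object.
#' @param annotation annotation `data.frame` (see [read_gff3()]).
#' @param stranded if `TRUE` (default) an overlap must be on the feature's
#'   strand; if `FALSE` either strand counts.
#' @return an object of class `classified_tags`: `mapped` plus a `label`
#'   column on `tags`.
#' @export
classify_tags <- function(mapped, annotation, stranded = TRUE) {
  stopifnot(inherits(mapped, "mapped_tags"))
  tags <- mapped$tags
  label <- rep("candidate_pool", nrow(tags))
  ann <- annotation[annotation$biotype %in% FILTER_BIOTYPES, , drop = FALSE]
  if (nrow(ann) == 0L) {
    warning("annotation has no filtered ncRNA classes; all tags -> candidate_pool")
  } else if (nrow(mapped$loci) > 0L) {
    tag_len <- tags$length
    if (is.null(tag_len)) tag_len <- nchar(tags$sequence)
    len_of <- stats::setNames(tag_len, tags$tag_id)
    q <- GenomicRanges::GRanges(
      seqnames = mapped$loci$seq_id,
      ranges = IRanges::IRanges(start = mapped$loci$start,
                                width = len_of[mapped$loci$tag_id]),
      strand = mapped$loci$strand)
    s <- GenomicRanges::GRanges(
      seqnames = ann$seq_id,
      ranges = IRanges::IRanges(start = ann$start, end = ann$end),
      strand = ann$strand)
    ov <- GenomicRanges::findOverlaps(q, s, minoverlap = 1L,
                                      ignore.strand = !stranded)
    if (length(ov) > 0L) {
      hit_tag <- mapped$loci$tag_id[S4Vectors::queryHits(ov)]
      hit_bio <- ann$biotype[S4Vectors::subjectHits(ov)]
      ## cascade priority: lowest rank among all overlapped classes wins
      rank <- match(hit_bio, FILTER_BIOTYPES)
      best <- tapply(rank, hit_tag, min)
      idx <- match(names(best), tags$tag_id)
      label[idx] <- FILTER_BIOTYPES[best]
    }
  }
  tags$label <- label
  out <- mapped
  out$tags <- tags
  class(out) <- c("classified_tags", "mapped_tags")
  out
}

#' @export
print.classified_tags <- function(x, ...) {
  cat("Classified tags (cascade rRNA > tRNA > snRNA > snoRNA > scRNA > miRNA):\n")
  print(table(x$tags$label))
  invisible(x)
}

#' Write a classified tag table as TSV
#'
#' @param x a `classified_tags` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_classified_tsv <- function(x, path) {
  out <- data.frame(tag_id = x$tags$tag_id, sequence = x$tags$sequence,
                    length = nchar(x$tags$sequence), n_loci = x$tags$n_loci,
                    label = x$tags$label, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
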