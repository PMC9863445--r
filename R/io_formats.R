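## Readers and writers for the external formats the pipeline consumes:
## collapsed small-RNA FASTA (count dialect `id_xN`), raw FASTQ (collapsed on
## load), GFF3 annotation with a closed biotype vocabulary, and TSV tables.
## All coordinates are 1-based inclusive, matching GFF3.

BIOTYPES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA", "miRNA", "mRNA", "other")

## ncRNA classes removed by the filter cascade, in priority order.
FILTER_BIOTYPES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA", "miRNA")

#' Read a collapsed small-RNA FASTA with read counts
#'
#' Reads collapsed ("clean tag") small-RNA reads from FASTA. The read count of
#' each distinct sequence is encoded in the header using the common
#' `id_xCOUNT` dialect (e.g. `>t1_x57`). Headers lacking the `_x` suffix get
#' a count of 1 with a warning. Records with identical sequences are merged
#' and their counts summed, so the result has one row per distinct sequence.
#'
#' @param path path to a FASTA file.
#' @return a `data.frame` with columns `tag_id`, `sequence` (DNA, uppercase)
#'   and `count` (non-negative integer). Empty file returns zero rows with a
#'   warning.
#' @seealso [read_fastq_counts()] for raw reads, [write_fasta_counts()]
#' @export
read_fasta_counts <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(seqs) == 0L) {
    warning("empty FASTA file: ", path)
    return(data.frame(tag_id = character(), sequence = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  has_count <- grepl("_x[0-9]+$", ids)
  counts <- rep(1L, length(ids))
  counts[has_count] <- as.integer(sub("^.*_x([0-9]+)$", "\\1", ids[has_count]))
  if (any(!has_count)) {
    warning(sum(!has_count), " header(s) lack the '_x<count>' suffix; count 1 assumed")
  }
  bad <- grepl("_x$", ids) | grepl("_x[0-9]*[^0-9]+[0-9]*$", ids)
  if (any(bad)) {
    stop("malformed collapsed-read header at record ", which(bad)[1],
         ": '", headers[which(bad)[1]], "'", call. = FALSE)
  }
  tag_table(sub("_x[0-9]+$", "", ids), toupper(as.character(seqs)), counts)
}

#' Read raw small-RNA FASTQ and collapse to counted tags
#'
#' Identical read sequences are collapsed into one tag whose count is the
#' number of occurrences, yielding the same table shape as
#' [read_fasta_counts()].
#'
#' @param path path to a FASTQ file (uncompressed or gzip).
#' @return a `data.frame` with columns `tag_id`, `sequence`, `count`.
#' @export
read_fastq_counts <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  if (length(seqs) == 0L) {
    warning("empty FASTQ file: ", path)
    return(data.frame(tag_id = character(), sequence = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  tab <- table(toupper(as.character(seqs)))
  tag_table(paste0("t", seq_along(tab)), names(tab), as.integer(tab))
}

## Collapse (id, sequence, count) triplets to one row per distinct sequence,
## counts summed, deterministic sequence-sorted order.
tag_table <- function(ids, sequences, counts) {
  stopifnot(all(counts >= 0))
  agg <- tapply(counts, sequences, sum)
  agg <- agg[order(names(agg))]
  first_id <- tapply(ids, sequences, function(x) x[[1]])[names(agg)]
  data.frame(tag_id = unname(first_id), sequence = names(agg),
             count = as.integer(unname(agg)), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write a counted tag table as collapsed FASTA
#'
#' Inverse of [read_fasta_counts()]: headers are `tag_id_xCOUNT`.
#'
#' @param tags `data.frame` with columns `tag_id`, `sequence`, `count`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_counts <- function(tags, path) {
  x <- Biostrings::DNAStringSet(tags$sequence)
  names(x) <- sprintf("%s_x%d", tags$tag_id, as.integer(tags$count))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Combine per-sample tag tables into a library collection
#'
#' Merges per-sample collapsed-read tables (from [read_fasta_counts()] or the
#' synthetic generator) by sequence into a single tag set with a per-sample
#' count matrix. Tags get fresh deterministic ids in sequence-sorted order.
#'
#' @param libs named list of per-sample `data.frame`s (`tag_id`, `sequence`,
#'   `count`); the names are the sample ids.
#' @return an object of class `srna_tags`: a list with `tags` (a `data.frame`
#'   of `tag_id`, `sequence`) and `counts` (an integer matrix, one row per
#'   tag, one column per sample).
#' @export
collect_libraries <- function(libs) {
  stopifnot(is.list(libs), length(libs) >= 1, !is.null(names(libs)),
            !anyDuplicated(names(libs)))
  all_seq <- sort(unique(unlist(lapply(libs, `[[`, "sequence"))))
  counts <- matrix(0L, nrow = length(all_seq), ncol = length(libs),
                   dimnames = list(NULL, names(libs)))
  for (s in names(libs)) {
    lib <- libs[[s]]
    idx <- match(lib$sequence, all_seq)
    counts[idx, s] <- counts[idx, s] + as.integer(lib$count)
  }
  tags <- data.frame(tag_id = sprintf("tag_%06d", seq_along(all_seq)),
                     sequence = all_seq, stringsAsFactors = FALSE)
  rownames(counts) <- tags$tag_id
  structure(list(tags = tags, counts = counts), class = "srna_tags")
}

#' @export
print.srna_tags <- function(x, ...) {
  cat("Small-RNA tag collection:", nrow(x$tags), "distinct tags,",
      ncol(x$counts), "sample(s)\n")
  cat("  total reads per sample:\n")
  print(colSums(x$counts))
  invisible(x)
}

#' Read a GFF3 annotation into biotyped records
#'
#' Parses a GFF3 file into the closed biotype vocabulary used by the filter
#' cascade (`rRNA`, `tRNA`, `snRNA`, `snoRNA`, `scRNA`, `miRNA`, `mRNA`,
#' `other`). The biotype is taken from a `biotype=` attribute when present,
#' which overrides the `type` column; unknown biotypes map to `other`.
#' Records violating `start <= end` are rejected with a warning.
#'
#' @param path path to a GFF3 file.
#' @return a `data.frame` with columns `seq_id`, `start`, `end` (1-based
#'   inclusive), `strand` (`+`/`-`), `biotype`, `feature_id`.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(seq_id = character(), start = integer(), end = integer(),
                      strand = character(), biotype = character(),
                      feature_id = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8)) {
    stop("malformed GFF3 line ", which(nf < 8)[1], ": fewer than 8 columns",
         call. = FALSE)
  }
  get <- function(i) vapply(fields, function(f) f[[i]], character(1))
  attrs <- vapply(fields, function(f) if (length(f) >= 9) f[[9]] else "", character(1))
  type <- get(3)
  biotype <- ifelse(grepl("biotype=", attrs),
                    sub("^.*biotype=([^;]+).*$", "\\1", attrs), type)
  biotype[!biotype %in% BIOTYPES] <- "other"
  feature_id <- ifelse(grepl("ID=", attrs),
                       sub("^.*ID=([^;]+).*$", "\\1", attrs),
                       sprintf("feat_%d", seq_along(lines)))
  out <- data.frame(seq_id = get(1),
                    start = suppressWarnings(as.integer(get(4))),
                    end = suppressWarnings(as.integer(get(5))),
                    strand = get(7), biotype = biotype,
                    feature_id = feature_id, stringsAsFactors = FALSE)
  bad <- is.na(out$start) | is.na(out$end) | out$start < 1 | out$start > out$end
  if (any(bad)) {
    warning(sum(bad), " GFF3 record(s) with invalid coordinates rejected")
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write annotation records as GFF3
#'
#' @param ann annotation `data.frame` as returned by [read_gff3()].
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path, source = "piragut") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(ann) > 0) {
    writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                       ann$seq_id, source, ann$biotype, ann$start, ann$end,
                       ann$strand, ann$feature_id, ann$biotype), con)
  }
  invisible(path)
}

#' Read a gene-to-term mapping table
#'
#' @param path TSV with columns `gene_id`, `term_id`, `term_name`, `category`.
#' @return the mapping `data.frame`.
#' @export
read_term_map <- function(path) {
  tm <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "term_id", "term_name", "category")
  if (!all(need %in% names(tm))) {
    stop("term map must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  tm
}
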