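## piRNA candidate calling: from the candidate pool keep tags 24-33 nt long
## that map to exactly one genomic position, and compare the called sets
## across sample groups (shared / group-unique / full membership classes).

#' Call piRNA candidates from the classified candidate pool
#'
#' Retains exactly the candidate-pool tags whose length lies in the piRNA
#' window (24-33 nt by default) and that map to a unique genomic position.
#' Ids are assigned deterministically in sequence-sorted order as
#' `piR-<species_tag>-<serial>`.
#'
#' @param classified a `classified_tags` object.
#' @param min_len,max_len inclusive length window (defaults 24 and 33 nt).
#' @param species_tag short species tag used in the ids (default `"ace"`).
#' @return an object of class `pirna_set`: list with `pirnas` (`data.frame`
#'   of `pirna_id`, `sequence`, `length`, `seq_id`, `start`, `strand`) and
#'   `counts` (matrix, rows = piRNAs, cols = samples).
#' @export
call_pirnas <- function(classified, min_len = 24L, max_len = 33L,
                        species_tag = "ace") {
  stopifnot(inherits(classified, "classified_tags"))
  tags <- classified$tags
  len <- nchar(tags$sequence)
  keep <- tags$label == "candidate_pool" & len >= min_len & len <= max_len &
    tags$n_loci == 1L
  tags <- tags[keep, , drop = FALSE]
  counts <- classified$counts[keep, , drop = FALSE]
  ord <- order(tags$sequence)
  tags <- tags[ord, , drop = FALSE]
  counts <- counts[ord, , drop = FALSE]
  loci <- classified$loci[match(tags$tag_id, classified$loci$tag_id), , drop = FALSE]
  pirnas <- data.frame(
    pirna_id = sprintf("piR-%s-%06d", species_tag, seq_len(nrow(tags))),
    sequence = tags$sequence,
    length = nchar(tags$sequence),
    seq_id = loci$seq_id, start = loci$start, strand = loci$strand,
    stringsAsFactors = FALSE, row.names = NULL)
  rownames(counts) <- pirnas$pirna_id
  structure(list(pirnas = pirnas, counts = counts), class = "pirna_set")
}

#' @export
print.pirna_set <- function(x, ...) {
  cat("piRNA candidate set:", nrow(x$pirnas), "piRNAs,",
      ncol(x$counts), "sample(s)\n")
  if (nrow(x$pirnas) > 0) {
    cat("  length range:", min(x$pirnas$length), "-", max(x$pirnas$length), "nt\n")
  }
  invisible(x)
}

#' Compare piRNA presence across sample groups
#'
#' A piRNA is present in a group when its summed raw count over the group's
#' replicates reaches `min_count` (default 1, i.e. any read). Reports the
#' piRNAs shared by all groups, those unique to each group, and the full
#' membership table over all `2^g - 1` presence classes (UpSet-style).
#'
#' @param x a `pirna_set`.
#' @param manifest named character vector mapping sample id -> group.
#' @param min_count presence threshold on the group-summed raw count.
#' @return list of class `group_comparison` with elements `shared`
#'   (character), `unique_per_group` (named list), `membership`
#'   (`data.frame`: `pirna_id`, one logical column per group, `class`
#'   string), and `class_sizes` (named integer).
#' @export
compare_groups <- function(x, manifest, min_count = 1L) {
  stopifnot(inherits(x, "pirna_set"))
  samples <- colnames(x$counts)
  if (!all(samples %in% names(manifest))) {
    stop("manifest is missing samples: ",
         paste(setdiff(samples, names(manifest)), collapse = ", "), call. = FALSE)
  }
  groups <- unique(unname(manifest[samples]))
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  for (g in groups) {
    if (!any(manifest[samples] == g)) stop("group with zero samples: ", g, call. = FALSE)
  }
  present <- sapply(groups, function(g) {
    cols <- samples[manifest[samples] == g]
    rowSums(x$counts[, cols, drop = FALSE]) >= min_count
  })
  if (nrow(x$pirnas) == 1L) present <- matrix(present, nrow = 1,
                                              dimnames = list(NULL, groups))
  anywhere <- rowSums(present) > 0
  membership <- data.frame(pirna_id = x$pirnas$pirna_id, present,
                           stringsAsFactors = FALSE, check.names = FALSE)
  membership <- membership[anywhere, , drop = FALSE]
  membership$class <- apply(membership[, groups, drop = FALSE], 1, function(p) {
    paste(groups[p], collapse = "&")
  })
  rownames(membership) <- NULL
  shared <- membership$pirna_id[rowSums(membership[, groups, drop = FALSE]) ==
                                  length(groups)]
  unique_per_group <- lapply(groups, function(g) {
    membership$pirna_id[membership[[g]] &
                          rowSums(membership[, groups, drop = FALSE]) == 1]
  })
  names(unique_per_group) <- groups
  class_sizes <- table(membership$class)
  structure(list(shared = shared, unique_per_group = unique_per_group,
                 membership = membership,
                 class_sizes = stats::setNames(as.integer(class_sizes),
                                               names(class_sizes)),
                 groups = groups),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("piRNA set comparison over", length(x$groups), "groups:\n")
  cat("  shared by all:", length(x$shared), "\n")
  for (g in x$groups) {
    cat("  unique to", g, ":", length(x$unique_per_group[[g]]), "\n")
  }
  invisible(x)
}

#' Write a piRNA set as FASTA plus TSV
#'
#' @param x a `pirna_set`.
#' @param prefix path prefix; writes `<prefix>.fa` and `<prefix>.tsv`.
#' @return the two paths, invisibly.
#' @export
write_pirna_set <- function(x, prefix) {
  fa <- paste0(prefix, ".fa")
  seqs <- Biostrings::DNAStringSet(x$pirnas$sequence)
  names(seqs) <- x$pirnas$pirna_id
  Biostrings::writeXStringSet(seqs, fa)
  tsv <- paste0(prefix, ".tsv")
  out <- cbind(x$pirnas, as.data.frame(x$counts))
  write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa, tsv))
}
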