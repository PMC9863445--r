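## TPM normalisation in the small-RNA sense: tags per million,
## TPM = T * 1e6 / N with T the read count of the piRNA in a sample and N
## the sample's total clean small-RNA reads (not the piRNA-only sum, and no
## length normalisation).

#' TPM-normalise a piRNA count matrix
#'
#' Applies `tpm[i, s] = raw[i, s] * 1e6 / library_sizes[s]` element-wise.
#' The library size of a sample is its total clean small-RNA read count. If
#' `library_sizes` is `NULL` the per-sample column sums of `raw` are used as
#' a fallback, with a warning (they undercount whenever `raw` holds piRNAs
#' only).
#'
#' @param raw integer count matrix (rows = piRNAs or tags, cols = samples),
#'   or a `pirna_set` whose counts are used.
#' @param library_sizes named vector of total clean sRNA reads per sample.
#' @return object of class `expression_matrix`: list with `raw`, `tpm`,
#'   `library_sizes`.
#' @export
tpm_normalize <- function(raw, library_sizes = NULL) {
  if (inherits(raw, "pirna_set")) raw <- raw$counts
  stopifnot(is.matrix(raw), !is.null(colnames(raw)))
  if (any(raw < 0)) stop("negative counts", call. = FALSE)
  if (is.null(library_sizes)) {
    warning("library sizes not supplied; falling back to per-sample count sums")
    library_sizes <- colSums(raw)
  }
  if (!all(colnames(raw) %in% names(library_sizes))) {
    stop("missing library size for sample(s): ",
         paste(setdiff(colnames(raw), names(library_sizes)), collapse = ", "),
         call. = FALSE)
  }
  library_sizes <- library_sizes[colnames(raw)]
  if (any(library_sizes <= 0)) stop("library sizes must be > 0", call. = FALSE)
  tpm <- sweep(raw, 2, library_sizes, function(t, n) t * 1e6 / n)
  structure(list(raw = raw, tpm = tpm, library_sizes = library_sizes),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$raw), "features x", ncol(x$raw), "samples (TPM)\n")
  cat("  library sizes:", paste(names(x$library_sizes),
                                format(x$library_sizes, big.mark = ","),
                                collapse = "; "), "\n")
  invisible(x)
}

#' Write an expression matrix as TSV
#'
#' @param x an `expression_matrix`.
#' @param path output path; TPM values with raw counts alongside.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  out <- data.frame(pirna_id = rownames(x$tpm),
                    x$tpm,
                    stats::setNames(as.data.frame(x$raw),
                                    paste0(colnames(x$raw), "_raw")),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
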