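## Term enrichment of target gene sets: per term a 2x2 Fisher exact test of
## foreground membership against the annotated background, plus the rich
## factor (foreground genes in the term / background genes in the term).

#' Term enrichment by Fisher's exact test
#'
#' For every term with at least one foreground gene, tests the 2x2 table
#' `[[k, n-k], [K-k, N-n-(K-k)]]` where `k`/`K` are the foreground/background
#' genes annotated to the term and `n`/`N` the foreground/background sizes.
#' Two-sided by default; a one-sided over-representation mode is available.
#' Genes absent from the term map count toward `n` and `N` but no term. A
#' Benjamini-Hochberg `q_value` is emitted for information; the significance
#' flag uses the raw p at `p_cutoff`.
#'
#' @param foreground character vector of genes of interest (must be a subset
#'   of `background`).
#' @param background character vector of all annotated genes.
#' @param term_map `data.frame` with columns `gene_id`, `term_id`,
#'   `term_name`, `category` (e.g. BP/MF/CC/pathway).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @param p_cutoff significance threshold on the raw p (default 0.05).
#' @return `data.frame` of class `enrichment_table`, one row per term:
#'   `term_id`, `term_name`, `category`, `k`, `n`, `K`, `N`, `p_value`,
#'   `q_value`, `rich_factor`, `significant`; sorted by `p_value`.
#' @export
enrich <- function(foreground, background, term_map,
                   alternative = c("two.sided", "greater"), p_cutoff = 0.05) {
  alternative <- match.arg(alternative)
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background)) {
    stop("foreground is not a subset of background (e.g. '",
         setdiff(foreground, background)[1], "')", call. = FALSE)
  }
  tm <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  tm <- unique(tm[, c("gene_id", "term_id", "term_name", "category")])
  n <- length(foreground)
  N <- length(background)
  fg <- tm[tm$gene_id %in% foreground, , drop = FALSE]
  if (nrow(fg) == 0L) {
    out <- data.frame(term_id = character(), term_name = character(),
                      category = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_value = numeric(),
                      q_value = numeric(), rich_factor = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_table", "data.frame")
    return(out)
  }
  k_by_term <- table(fg$term_id)
  K_by_term <- table(tm$term_id)
  terms <- names(k_by_term)
  info <- tm[match(terms, tm$term_id), c("term_id", "term_name", "category")]
  k <- as.integer(k_by_term[terms])
  K <- as.integer(K_by_term[terms])
  p <- vapply(seq_along(terms), function(i) {
    tab <- matrix(c(k[i], n - k[i], K[i] - k[i], N - n - (K[i] - k[i])), 2, 2)
    stats::fisher.test(tab, alternative = alternative)$p.value
  }, numeric(1))
  out <- data.frame(term_id = info$term_id, term_name = info$term_name,
                    category = info$category, k = k, n = n, K = K, N = N,
                    p_value = p, q_value = stats::p.adjust(p, "BH"),
                    rich_factor = k / K, significant = p < p_cutoff,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat("Enrichment:", nrow(x), "terms tested;", sum(x$significant),
      "significant at raw p\n")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}
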