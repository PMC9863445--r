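## Structural characterisation of a called piRNA set: the length histogram
## over the 24-33 nt window and the 5' first-base bias (piRNAs in this
## species show a C bias, unlike the U bias of fly germline piRNAs).

#' Length distribution of a piRNA set
#'
#' Normalised histogram of piRNA lengths over the calling window. By default
#' each distinct piRNA sequence counts once (`unique_sequences`, what the
#' per-length percentages of a piRNA catalogue usually show); with
#' `read_counts` every read counts, summed over `samples`.
#'
#' @param x a `pirna_set`.
#' @param weight `"unique_sequences"` or `"read_counts"`.
#' @param samples samples to sum over for `read_counts` (default all).
#' @param min_len,max_len histogram window (defaults 24 and 33 nt).
#' @return named numeric vector of proportions over `min_len:max_len`,
#'   summing to 1.
#' @export
length_distribution <- function(x, weight = c("unique_sequences", "read_counts"),
                                samples = NULL, min_len = 24L, max_len = 33L) {
  stopifnot(inherits(x, "pirna_set"))
  weight <- match.arg(weight)
  if (nrow(x$pirnas) == 0L) stop("empty piRNA set", call. = FALSE)
  lens <- factor(x$pirnas$length, levels = min_len:max_len)
  w <- if (weight == "unique_sequences") {
    rep(1, nrow(x$pirnas))
  } else {
    if (is.null(samples)) samples <- colnames(x$counts)
    rowSums(x$counts[, samples, drop = FALSE])
  }
  tot <- tapply(w, lens, sum, default = 0)
  out <- tot / sum(tot)
  stats::setNames(as.numeric(out), names(tot))
}

#' First-base bias of a piRNA set
#'
#' Frequency of the 5'-terminal nucleotide, per length and pooled over all
#' lengths. Reported in RNA letters (A/C/G/U). Sequences whose first base is
#' not A/C/G/T are excluded with a warning.
#'
#' @param x a `pirna_set`.
#' @param weight `"unique_sequences"` (default) or `"read_counts"`.
#' @param samples samples to sum over for `read_counts`.
#' @return list of class `first_base_profile`: `per_length` (matrix, rows =
#'   lengths with at least one piRNA, cols = A/C/G/U, rows sum to 1),
#'   `pooled` (named numeric, sums to 1) and `argmax` (character; more than
#'   one entry on a tie).
#' @export
first_base_bias <- function(x, weight = c("unique_sequences", "read_counts"),
                            samples = NULL) {
  stopifnot(inherits(x, "pirna_set"))
  weight <- match.arg(weight)
  if (nrow(x$pirnas) == 0L) stop("empty piRNA set", call. = FALSE)
  fb <- substr(x$pirnas$sequence, 1, 1)
  ok <- fb %in% DNA_BASES
  if (any(!ok)) {
    warning(sum(!ok), " piRNA(s) with non-ACGT first base excluded")
  }
  w <- if (weight == "unique_sequences") {
    rep(1, nrow(x$pirnas))
  } else {
    if (is.null(samples)) samples <- colnames(x$counts)
    rowSums(x$counts[, samples, drop = FALSE])
  }
  fb <- factor(fb[ok], levels = DNA_BASES)
  len <- x$pirnas$length[ok]
  w <- w[ok]
  per_length <- tapply(w, list(len, fb), sum, default = 0)
  per_length <- per_length / rowSums(per_length)
  colnames(per_length) <- c("A", "C", "G", "U")
  pooled <- tapply(w, fb, sum, default = 0)
  pooled <- stats::setNames(as.numeric(pooled / sum(pooled)), c("A", "C", "G", "U"))
  top <- names(pooled)[pooled == max(pooled)]
  structure(list(per_length = per_length, pooled = pooled, argmax = top),
            class = "first_base_profile")
}

#' @export
print.first_base_profile <- function(x, ...) {
  cat("First-base profile (pooled):\n")
  print(round(x$pooled, 4))
  cat("dominant first base:", paste(x$argmax, collapse = " / "),
      if (length(x$argmax) > 1) "(tie)" else "", "\n")
  invisible(x)
}
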