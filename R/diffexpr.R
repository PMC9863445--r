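## Differential-expression screen between two sample groups on the TPM
## matrix, using the field's standard rule: |log2 fold change| >= 1 and
## p <= 0.05. The p-value comes from Welch's t test on the TPM replicates
## (default) or from the Audic-Claverie test on pooled raw counts. Also
## provides the 2^-ddCt relative-expression computation used for RT-qPCR
## cross-validation.

#' Screen differentially expressed piRNAs between two groups
#'
#' For each piRNA computes `log2fc = log2((mean TPM in B + eps) / (mean TPM
#' in A + eps))` and a p-value, then assigns a direction: `up` when
#' `log2fc >= lfc_cutoff` and `p <= p_cutoff`, `down` when
#' `log2fc <= -lfc_cutoff` and `p <= p_cutoff`, otherwise `ns`. Both
#' boundaries are inclusive. No rows are dropped; a Benjamini-Hochberg
#' `q_value` column is emitted for information only and plays no part in the
#' screen.
#'
#' @param expr an `expression_matrix` from [tpm_normalize()].
#' @param manifest named character vector sample -> group.
#' @param comparison character pair `c(A, B)`; fold changes are B over A.
#' @param method `"welch_t"` (Welch's t on TPM replicates; needs >= 2
#'   replicates per group) or `"audic_claverie"` (on pooled raw counts).
#' @param epsilon pseudocount added to both group means in TPM units
#'   (default 0.01) so that fold changes stay finite when one group is zero.
#' @param lfc_cutoff,p_cutoff screen thresholds (defaults 1 and 0.05).
#' @return `data.frame` of class `diffexpr_table` with columns `pirna_id`,
#'   `mean_a`, `mean_b`, `log2fc`, `p_value`, `q_value`, `direction`, plus
#'   attributes `comparison` and `method`.
#' @export
differential_screen <- function(expr, manifest, comparison,
                                method = c("welch_t", "audic_claverie"),
                                epsilon = 0.01, lfc_cutoff = 1, p_cutoff = 0.05) {
  stopifnot(inherits(expr, "expression_matrix"), length(comparison) == 2)
  method <- match.arg(method)
  stopifnot(epsilon > 0)
  samples <- colnames(expr$tpm)
  grp <- manifest[samples]
  a <- samples[!is.na(grp) & grp == comparison[1]]
  b <- samples[!is.na(grp) & grp == comparison[2]]
  if (length(a) == 0 || length(b) == 0) {
    stop("comparison group absent from manifest: ",
         comparison[if (length(a) == 0) 1 else 2], call. = FALSE)
  }
  if (method == "welch_t" && (length(a) < 2 || length(b) < 2)) {
    stop("welch_t needs >= 2 replicates per group", call. = FALSE)
  }
  ta <- expr$tpm[, a, drop = FALSE]
  tb <- expr$tpm[, b, drop = FALSE]
  mean_a <- rowMeans(ta)
  mean_b <- rowMeans(tb)
  log2fc <- log2((mean_b + epsilon) / (mean_a + epsilon))
  p <- if (method == "welch_t") {
    vapply(seq_len(nrow(ta)), function(i) welch_p(ta[i, ], tb[i, ]), numeric(1))
  } else {
    na_tot <- sum(expr$library_sizes[a])
    nb_tot <- sum(expr$library_sizes[b])
    vapply(seq_len(nrow(expr$raw)), function(i) {
      audic_claverie_p(sum(expr$raw[i, a]), sum(expr$raw[i, b]), na_tot, nb_tot)
    }, numeric(1))
  }
  direction <- rep("ns", length(p))
  direction[log2fc >= lfc_cutoff & p <= p_cutoff] <- "up"
  direction[log2fc <= -lfc_cutoff & p <= p_cutoff] <- "down"
  out <- data.frame(pirna_id = rownames(expr$tpm), mean_a = mean_a,
                    mean_b = mean_b, log2fc = log2fc, p_value = p,
                    q_value = stats::p.adjust(p, "BH"), direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "comparison") <- comparison
  attr(out, "method") <- method
  class(out) <- c("diffexpr_table", "data.frame")
  out
}

## Welch's t p-value with the degenerate cases closed: if both groups are
## exactly constant the test is undefined, so return 1 when the constants
## agree (no evidence of change) and 0 when they differ (change observed
## without replicate noise).
welch_p <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
}

## Audic-Claverie (1997) two-sided p for counts x (library N1) vs y (N2):
## under the null, y | x follows a negative binomial with size x + 1 and
## success probability N1 / (N1 + N2).
audic_claverie_p <- function(x, y, n1, n2) {
  prob <- n1 / (n1 + n2)
  lo <- stats::pnbinom(y, size = x + 1, prob = prob)        # P(Y <= y)
  hi <- 1 - stats::pnbinom(y - 1, size = x + 1, prob = prob) # P(Y >= y)
  min(1, 2 * min(lo, hi))
}

#' @export
print.diffexpr_table <- function(x, ...) {
  cmp <- attr(x, "comparison")
  cat("Differential screen", paste(cmp, collapse = " vs "),
      "(", attr(x, "method"), "):", nrow(x), "piRNAs;",
      sum(x$direction == "up"), "up,", sum(x$direction == "down"), "down\n")
  invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes `ddCt = (Ct_target,test - Ct_ref,test) - (Ct_target,ctrl -
#' Ct_ref,ctrl)` and the relative expression `2^-ddCt` used to compare a
#' target small RNA between a test and a control condition after
#' normalisation to a reference gene (e.g. snRNA U6).
#'
#' @param ct_target_test,ct_ref_test,ct_target_ctrl,ct_ref_ctrl qPCR cycle
#'   thresholds (finite numerics).
#' @return list with `delta_delta_ct` and `relative_expression`.
#' @export
#' @examples
#' ddct(25, 20, 24, 20)  # ddCt = 1, relative expression 0.5
ddct <- function(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl) {
  vals <- c(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl)
  if (!all(is.finite(vals))) stop("Ct values must be finite", call. = FALSE)
  dd <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  list(delta_delta_ct = dd, relative_expression = 2^(-dd))
}
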