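# Build a classified_tags object directly so length/locus edge cases are
# fully controlled.
fake_classified <- function(df, counts = NULL) {
  # df: sequence, n_loci, label
  tags <- data.frame(tag_id = sprintf("t%03d", seq_len(nrow(df))),
                     sequence = df$sequence, n_loci = df$n_loci,
                     label = df$label, stringsAsFactors = FALSE)
  if (is.null(counts)) {
    counts <- matrix(1L, nrow(df), 1, dimnames = list(tags$tag_id, "s1"))
  }
  loci <- data.frame(tag_id = rep(tags$tag_id, df$n_loci),
                     seq_id = "chr", strand = "+", stringsAsFactors = FALSE)
  loci$start <- seq_len(nrow(loci)) * 100L
  structure(list(tags = tags, counts = counts, loci = loci,
                 report = list(n_input = nrow(df), n_mapped = nrow(df),
                               n_unmapped = 0, unmapped_ids = character())),
            class = c("classified_tags", "mapped_tags"))
}

rand_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                              collapse = "")

test_that("length window and unique-position rule define the call", {
  set.seed(301)
  df <- data.frame(
    sequence = c(rand_seq(23), rand_seq(24), rand_seq(28), rand_seq(33),
                 rand_seq(34), rand_seq(28)),
    n_loci = c(1L, 1L, 2L, 1L, 1L, 1L),
    label = c("candidate_pool", "candidate_pool", "candidate_pool",
              "candidate_pool", "candidate_pool", "miRNA"),
    stringsAsFactors = FALSE)
  ps <- call_pirnas(fake_classified(df))
  # kept: the 24 nt unique tag and the 33 nt unique tag only
  expect_equal(sort(ps$pirnas$length), c(24L, 33L))
  expect_false(any(nchar(ps$pirnas$sequence) == 23))  # below window
  expect_false(df$sequence[3] %in% ps$pirnas$sequence) # multi-locus
  expect_false(df$sequence[6] %in% ps$pirnas$sequence) # filtered biotype
  expect_true(all(grepl("^piR-ace-", ps$pirnas$pirna_id)))
})

test_that("calling is invariant to input order", {
  set.seed(302)
  df <- data.frame(sequence = replicate(20, rand_seq(sample(24:33, 1))),
                   n_loci = 1L, label = "candidate_pool",
                   stringsAsFactors = FALSE)
  a <- call_pirnas(fake_classified(df))
  perm <- sample(nrow(df))
  b <- call_pirnas(fake_classified(df[perm, , drop = FALSE]))
  expect_equal(a$pirnas$sequence, b$pirnas$sequence)
  expect_equal(a$pirnas$pirna_id, b$pirnas$pirna_id)
})

test_that("group comparison matches exhaustive membership enumeration", {
  set.seed(303)
  n <- 50
  groups <- c("Ac4", "Ac5", "Ac6")
  manifest <- stats::setNames(rep(groups, each = 2),
                              paste0(rep(groups, each = 2), "_r", 1:2))
  # random presence pattern, then counts realizing it
  present <- matrix(runif(n * 3) < 0.6, n, 3, dimnames = list(NULL, groups))
  counts <- matrix(0L, n, 6, dimnames = list(NULL, names(manifest)))
  for (g in groups) {
    counts[present[, g], manifest == g] <-
      matrix(sample(0:5, sum(present[, g]) * 2, replace = TRUE),
             ncol = 2)
    # make sure at least one replicate is positive where present
    zero <- present[, g] & rowSums(counts[, manifest == g, drop = FALSE]) == 0
    counts[zero, which(manifest == g)[1]] <- 1L
  }
  seqs <- replicate(n, rand_seq(26))
  ps <- structure(list(
    pirnas = data.frame(pirna_id = sprintf("p%03d", 1:n), sequence = seqs,
                        length = 26L, seq_id = "chr", start = 1:n,
                        strand = "+", stringsAsFactors = FALSE),
    counts = counts), class = "pirna_set")
  rownames(ps$counts) <- ps$pirnas$pirna_id
  cmp <- compare_groups(ps, manifest)

  # oracle: enumerate all 2^3 - 1 membership classes by brute force
  truth_present <- sapply(groups, function(g)
    rowSums(counts[, manifest == g, drop = FALSE]) > 0)
  key <- apply(truth_present, 1, function(p) paste(groups[p], collapse = "&"))
  key <- key[key != ""]
  oracle_sizes <- table(key)
  expect_equal(sort(cmp$class_sizes),
               sort(stats::setNames(as.integer(oracle_sizes),
                                    names(oracle_sizes))))
  # shared and unique sets agree with direct logic
  expect_setequal(cmp$shared, ps$pirnas$pirna_id[rowSums(truth_present) == 3])
  for (g in groups) {
    expect_setequal(cmp$unique_per_group[[g]],
                    ps$pirnas$pirna_id[truth_present[, g] &
                                         rowSums(truth_present) == 1])
  }
  # class sizes cover every piRNA present in at least one group
  expect_equal(sum(cmp$class_sizes), sum(rowSums(truth_present) > 0))
  # shared and unique sets are disjoint
  for (g in groups) {
    expect_length(intersect(cmp$shared, cmp$unique_per_group[[g]]), 0)
  }
})

test_that("comparison needs at least two groups with samples", {
  ps <- structure(list(
    pirnas = data.frame(pirna_id = "p1", sequence = strrep("AC", 13),
                        length = 26L, seq_id = "chr", start = 1L,
                        strand = "+", stringsAsFactors = FALSE),
    counts = matrix(1L, 1, 2, dimnames = list("p1", c("a1", "a2")))),
    class = "pirna_set")
  expect_error(compare_groups(ps, c(a1 = "A", a2 = "A")), "2 groups")
})
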