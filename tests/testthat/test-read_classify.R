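make_world_bits <- function() {
  set.seed(202)
  g <- c(chr = paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
                     collapse = ""))
  list(genome = g, index = build_genome_index(g, k = 12))
}

tags_from_seqs <- function(seqs) {
  libs <- list(s1 = data.frame(tag_id = sprintf("t%d", seq_along(seqs)),
                               sequence = seqs, count = 1L,
                               stringsAsFactors = FALSE))
  collect_libraries(libs)
}

test_that("map_tags enumerates loci and reports unmapped tags", {
  wb <- make_world_bits()
  present <- substr(wb$genome[[1]], 101, 126)
  absent <- strrep("ACGT", 7)            # 28-mer almost surely absent
  x <- tags_from_seqs(c(present, absent))
  m <- map_tags(x, wb$index)
  expect_equal(m$report$n_input, 2)
  got <- m$loci[m$loci$tag_id == m$tags$tag_id[m$tags$sequence == present], ]
  expect_equal(got$start, 101L)
  if (m$report$n_unmapped == 1) {
    expect_false(absent %in% m$tags$sequence)
  }
})

test_that("mapped loci equal naive search for many random tags", {
  wb <- make_world_bits()
  set.seed(203)
  seqs <- unique(c(
    vapply(1:60, function(i) {   # planted
      st <- sample(3960, 1); L <- sample(20:30, 1)
      s <- substr(wb$genome[[1]], st, st + L - 1)
      if (runif(1) < 0.5) revcomp(s) else s
    }, character(1)),
    vapply(1:60, function(i) paste(sample(c("A", "C", "G", "T"), 25,
                                          replace = TRUE), collapse = ""),
           character(1))))
  x <- tags_from_seqs(seqs)
  m <- map_tags(x, wb$index)
  for (i in seq_len(nrow(m$tags))) {
    expect_equal(m$loci[m$loci$tag_id == m$tags$tag_id[i],
                        c("seq_id", "start", "strand")],
                 naive_search(wb$genome, m$tags$sequence[i]),
                 ignore_attr = TRUE)
  }
  expect_equal(m$report$n_mapped + m$report$n_unmapped, nrow(x$tags))
})

test_that("classification follows the cascade and the overlap rule", {
  wb <- make_world_bits()
  g <- wb$genome[[1]]
  # tag inside a tRNA feature; tag overlapping both rRNA and miRNA at
  # different loci; tag overlapping nothing
  t_trna <- substr(g, 210, 234)
  t_free <- substr(g, 3000, 3026)
  # plant one sequence at two loci so it overlaps rRNA at one and miRNA at
  # the other
  dual <- substr(g, 500, 525)
  gc <- strsplit(g, "")[[1]]
  gc[800:825] <- strsplit(dual, "")[[1]]
  g2 <- c(chr = paste(gc, collapse = ""))
  idx <- build_genome_index(g2, k = 12)
  ann <- data.frame(seq_id = "chr",
                    start = c(200L, 490L, 790L),
                    end = c(260L, 530L, 830L),
                    strand = "+",
                    biotype = c("tRNA", "miRNA", "rRNA"),
                    feature_id = c("t1", "m1", "r1"), stringsAsFactors = FALSE)
  x <- tags_from_seqs(c(t_trna, dual, t_free))
  cl <- classify_tags(map_tags(x, idx), ann)
  lab <- stats::setNames(cl$tags$label, cl$tags$sequence)
  expect_equal(unname(lab[t_trna]), "tRNA")
  expect_equal(unname(lab[dual]), "rRNA")   # cascade: rRNA beats miRNA
  expect_equal(unname(lab[t_free]), "candidate_pool")
})

test_that("every mapped tag gets exactly one label (partition invariant)", {
  p <- default_pipeline()
  cl <- p$classified
  expect_equal(length(cl$tags$label), nrow(cl$tags))
  expect_true(all(cl$tags$label %in% c("rRNA", "tRNA", "snRNA", "snoRNA",
                                       "scRNA", "miRNA", "candidate_pool")))
  expect_equal(sum(table(cl$tags$label)), nrow(cl$tags))
})

test_that("adding annotation never moves a tag into the candidate pool", {
  wb <- make_world_bits()
  set.seed(204)
  seqs <- vapply(1:30, function(i) {
    st <- sample(3900, 1); substr(wb$genome[[1]], st, st + 25)
  }, character(1))
  x <- tags_from_seqs(unique(seqs))
  m <- map_tags(x, wb$index)
  ann1 <- data.frame(seq_id = "chr", start = 1L, end = 1000L, strand = "+",
                     biotype = "snoRNA", feature_id = "f1",
                     stringsAsFactors = FALSE)
  ann2 <- rbind(ann1, data.frame(seq_id = "chr", start = 1001L, end = 2500L,
                                 strand = "+", biotype = "scRNA",
                                 feature_id = "f2", stringsAsFactors = FALSE))
  l1 <- classify_tags(m, ann1)$tags$label
  l2 <- classify_tags(m, ann2)$tags$label
  expect_true(all(!(l1 != "candidate_pool" & l2 == "candidate_pool")))
})

test_that("strandedness switch controls opposite-strand overlaps", {
  wb <- make_world_bits()
  s <- substr(wb$genome[[1]], 1200, 1227)
  x <- tags_from_seqs(revcomp(s))     # maps on the minus strand
  m <- map_tags(x, wb$index)
  ann <- data.frame(seq_id = "chr", start = 1190L, end = 1240L, strand = "+",
                    biotype = "rRNA", feature_id = "r", stringsAsFactors = FALSE)
  expect_equal(classify_tags(m, ann, stranded = TRUE)$tags$label,
               "candidate_pool")
  expect_equal(classify_tags(m, ann, stranded = FALSE)$tags$label, "rRNA")
})

test_that("empty annotation labels everything candidate_pool with a warning", {
  wb <- make_world_bits()
  x <- tags_from_seqs(substr(wb$genome[[1]], 50, 75))
  m <- map_tags(x, wb$index)
  empty_ann <- data.frame(seq_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          biotype = character(), feature_id = character(),
                          stringsAsFactors = FALSE)
  expect_warning(cl <- classify_tags(m, empty_ann), "candidate_pool")
  expect_equal(cl$tags$label, "candidate_pool")
})
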