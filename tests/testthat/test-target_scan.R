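rand_dna <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                              collapse = "")

test_that("an exact antisense match yields one perfect site", {
  set.seed(701)
  p <- rand_dna(28)
  mrna <- c(m1 = paste0(rand_dna(60), revcomp(p), rand_dna(60)))
  pir <- data.frame(pirna_id = "piX", sequence = p, stringsAsFactors = FALSE)
  sites <- scan_targets(pir, mrna)
  perfect <- sites[sites$n_mismatches == 0 & sites$n_gu_wobbles == 0, ]
  expect_equal(nrow(perfect), 1)
  expect_equal(perfect$site_start, 61L)
  expect_equal(perfect$penalty_score, 0)
  expect_equal(perfect$duplex_alignment, strrep("|", 28))
})

test_that("a window with four mismatches is rejected at the default cap", {
  set.seed(702)
  p <- rand_dna(26)
  site <- strsplit(revcomp(p), "")[[1]]
  # force 4 clean mismatches (avoiding accidental wobbles)
  for (pos in c(3, 9, 15, 21)) {
    pb <- substr(p, 26 - pos + 1, 26 - pos + 1)
    forbidden <- c(site[pos], revcomp(pb), if (pb == "G") "T", if (pb == "T") "G")
    site[pos] <- setdiff(c("A", "C", "G", "T"), forbidden)[1]
  }
  mrna <- c(m1 = paste0(rand_dna(30), paste(site, collapse = ""), rand_dna(30)))
  pir <- data.frame(pirna_id = "piX", sequence = p, stringsAsFactors = FALSE)
  sites <- scan_targets(pir, mrna)
  expect_false(any(sites$site_start == 31))
  # the same window passes once the cap is raised
  sites4 <- scan_targets(pir, mrna, max_mismatches = 4)
  expect_true(any(sites4$site_start == 31 & sites4$n_mismatches == 4))
})

test_that("the scanner equals a brute-force window enumerator on random instances", {
  set.seed(703)
  for (inst in 1:20) {
    n_pir <- sample(2:4, 1)
    pir <- data.frame(pirna_id = sprintf("pi%02d", seq_len(n_pir)),
                      sequence = vapply(sample(24:33, n_pir, replace = TRUE),
                                        rand_dna, character(1)),
                      stringsAsFactors = FALSE)
    mrnas <- stats::setNames(
      vapply(rep(120, 3), rand_dna, character(1)), sprintf("m%02d", 1:3))
    # plant one near-match so instances are not all empty
    pl <- sample(n_pir, 1)
    sc <- strsplit(revcomp(pir$sequence[pl]), "")[[1]]
    pos <- sample(length(sc), sample(0:3, 1))
    for (mp in pos) sc[mp] <- sample(c("A", "C", "G", "T"), 1)
    m1 <- strsplit(mrnas[[1]], "")[[1]]
    at <- sample(120 - length(sc), 1)
    m1[at:(at + length(sc) - 1)] <- sc
    mrnas[[1]] <- paste(m1, collapse = "")

    got <- scan_targets(pir, mrnas)
    want <- oracle_scan(pir, mrnas)
    key <- function(d) {
      o <- order(d$pirna_id, d$mrna_id, d$site_start)
      d[o, c("pirna_id", "mrna_id", "site_start", "n_mismatches",
             "n_gu_wobbles", "penalty_score")]
    }
    expect_equal(key(as.data.frame(got)), key(want), ignore_attr = TRUE)
  }
})

test_that("wobbles score half a mismatch and the seed region doubles penalties", {
  # piRNA 5'-...G at position 10; pair it with U (T in DNA) for a wobble
  p <- paste0("CA", strrep("C", 6), "AG", strrep("A", 16))  # G at position 10
  site <- strsplit(revcomp(p), "")[[1]]
  L <- nchar(p)
  site[L - 10 + 1] <- "T"            # G:U wobble outside the seed
  mrna <- c(m1 = paste0(strrep("G", 20), paste(site, collapse = ""),
                        strrep("G", 20)))
  pir <- data.frame(pirna_id = "piX", sequence = p, stringsAsFactors = FALSE)
  s <- scan_targets(pir, mrna)
  row <- s[s$site_start == 21, ]
  expect_equal(row$n_gu_wobbles, 1L)
  expect_equal(row$n_mismatches, 0L)
  expect_equal(row$penalty_score, 0.5)

  # same wobble inside the seed region (piRNA position 2-7) scores double
  p2 <- paste0("CG", strrep("A", 24))          # G at piRNA position 2
  site2 <- strsplit(revcomp(p2), "")[[1]]
  site2[nchar(p2) - 2 + 1] <- "T"
  mrna2 <- c(m1 = paste0(strrep("G", 10), paste(site2, collapse = ""),
                         strrep("G", 10)))
  s2 <- scan_targets(data.frame(pirna_id = "piY", sequence = p2,
                                stringsAsFactors = FALSE), mrna2)
  row2 <- s2[s2$site_start == 11, ]
  expect_equal(row2$penalty_score, 1.0)        # 0.5 x 2 seed weighting
})

test_that("duplex free energy matches hand-summed nearest-neighbor values", {
  params <- nn_params()
  # perfect GC-only duplex: initiation + 9 identical GG/CC stacks
  expect_equal(duplex_free_energy(strrep("G", 10), strrep("C", 10), params),
               4.09 + 9 * (-3.30), tolerance = 1e-9)
  # AU-only duplex: initiation + 9 AA/UU stacks + two terminal AU penalties
  expect_equal(duplex_free_energy(strrep("A", 10), strrep("T", 10), params),
               4.09 + 9 * (-0.90) + 2 * 0.45, tolerance = 1e-9)
  # random perfect duplexes against an independent table walk
  set.seed(704)
  for (i in 1:25) {
    p <- rand_dna(sample(8:30, 1))
    expect_equal(duplex_free_energy(p, revcomp(p), params),
                 oracle_perfect_dg(p, params), tolerance = 1e-9)
  }
  # fully mismatched duplex: initiation only (poly-A against poly-A pairs
  # A with A at every position)
  expect_equal(duplex_free_energy(strrep("A", 12), strrep("A", 12), params),
               params$init_penalty)
})

test_that("extending a perfect duplex never destabilizes it", {
  set.seed(705)
  for (i in 1:30) {
    p <- rand_dna(sample(10:30, 1))
    dg1 <- duplex_free_energy(p, revcomp(p))
    p2 <- paste0(p, sample(c("A", "C", "G", "T"), 1))
    dg2 <- duplex_free_energy(p2, revcomp(p2))
    expect_lte(dg2, dg1 + 1e-9)
  }
})

test_that("the free-energy filter is strict and order-preserving", {
  sites <- data.frame(pirna_id = c("a", "b", "c"), mrna_id = "m",
                      site_start = 1:3, site_seq = "ACGT",
                      duplex_alignment = "||||", n_mismatches = 0L,
                      n_gu_wobbles = 0L, penalty_score = 0,
                      delta_g = c(-25, -20, -19.99), stringsAsFactors = FALSE)
  class(sites) <- c("target_sites", "data.frame")
  kept <- filter_sites(sites, dg_cutoff = -20)
  expect_equal(kept$pirna_id, "a")      # -20 exactly is dropped
  expect_equal(kept$delta_g, -25)
})

test_that("target pairs deduplicate mRNAs per piRNA", {
  sites <- data.frame(pirna_id = c("a", "a", "a", "b"),
                      mrna_id = c("m1", "m1", "m2", "m1"),
                      site_start = c(1L, 50L, 7L, 3L), site_seq = "ACGT",
                      duplex_alignment = "||||", n_mismatches = 0L,
                      n_gu_wobbles = 0L, penalty_score = c(1, 0, 2, 0),
                      delta_g = c(-22, -30, -25, -28), stringsAsFactors = FALSE)
  class(sites) <- c("target_sites", "data.frame")
  pairs <- target_pairs(sites)
  expect_equal(nrow(pairs), 3)
  a_m1 <- pairs[pairs$pirna_id == "a" & pairs$mrna_id == "m1", ]
  expect_equal(a_m1$n_sites, 2L)
  expect_equal(a_m1$delta_g, -30)       # best site kept
})

test_that("dinucleotide shuffles preserve dinucleotide composition", {
  set.seed(706)
  dinucs <- function(x) {
    ch <- strsplit(x, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
  }
  for (i in 1:15) {
    s <- rand_dna(sample(24:33, 1))
    sh <- dinucleotide_shuffle(s)
    expect_equal(sort(dinucs(sh)), sort(dinucs(s)))
    expect_equal(nchar(sh), nchar(s))
  }
})

test_that("empirical edge p is small for a perfect planted site", {
  set.seed(707)
  p <- rand_dna(28)
  mrna <- c(m1 = paste0(rand_dna(40), revcomp(p), rand_dna(40)))
  pir <- data.frame(pirna_id = "piX", sequence = p, stringsAsFactors = FALSE)
  sites <- filter_sites(scan_targets(pir, mrna))
  sites <- empirical_edge_p(sites, pir, n_shuffle = 50)
  expect_true(all(sites$empirical_p > 0 & sites$empirical_p <= 1))
  perfect <- sites$empirical_p[sites$n_mismatches == 0 & sites$n_gu_wobbles == 0]
  expect_lte(perfect[1], 0.05)
})

test_that("a piRNA longer than the transcript yields no sites", {
  pir <- data.frame(pirna_id = "piX", sequence = strrep("ACGT", 8),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(scan_targets(pir, c(m1 = "ACGTACGT"))), 0)
})
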