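# Independent reference implementations (oracles) used to validate the
# package's optimized code paths, plus a memoized default synthetic world so
# several test files can share one build.

.world_cache <- new.env(parent = emptyenv())

default_world <- function() {
  if (is.null(.world_cache$world)) {
    .world_cache$world <- simulate_world(sim_config(seed = 42))
  }
  .world_cache$world
}

default_pipeline <- function() {
  if (is.null(.world_cache$pipeline)) {
    w <- default_world()
    .world_cache$pipeline <- run_pirna_pipeline(
      w$libraries, w$genome, w$annotation,
      library_sizes = stats::setNames(w$manifest$library_size,
                                      w$manifest$sample))
  }
  .world_cache$pipeline
}

# Naive string-search occurrence finder over both strands; independent of
# the k-mer index (uses gregexpr on the raw sequences).
naive_search <- function(genome, pattern) {
  hit_rows <- list()
  for (ch in names(genome)) {
    for (std in c("+", "-")) {
      pat <- if (std == "+") pattern else revcomp(pattern)
      m <- gregexpr(pat, genome[[ch]], fixed = TRUE)[[1]]
      if (m[1] != -1) {
        hit_rows[[length(hit_rows) + 1]] <- data.frame(
          seq_id = ch, start = as.integer(m), strand = std,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(seq_id = character(), start = integer(), strand = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$seq_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

COMP <- c(A = "T", C = "G", G = "C", T = "A")

# Brute-force window-by-window target enumeration, written independently of
# scan_targets: explicit loops, direct base-pair logic.
oracle_scan <- function(pirnas, mrnas, max_mm = 3, seed_lo = 2, seed_hi = 7) {
  rows <- list()
  for (pi in seq_len(nrow(pirnas))) {
    p <- strsplit(pirnas$sequence[pi], "")[[1]]
    L <- length(p)
    for (mn in names(mrnas)) {
      m <- strsplit(mrnas[[mn]], "")[[1]]
      if (L > length(m)) next
      for (st in 1:(length(m) - L + 1)) {
        mm <- 0; wob <- 0; pen <- 0
        for (i in 1:L) {             # piRNA position i pairs site pos L-i+1
          sb <- m[st + (L - i + 1) - 1]
          w <- if (i >= seed_lo && i <= seed_hi) 2 else 1
          if (sb == COMP[[p[i]]]) {
            # Watson-Crick
          } else if ((p[i] == "G" && sb == "T") || (p[i] == "T" && sb == "G")) {
            wob <- wob + 1; pen <- pen + 0.5 * w
          } else {
            mm <- mm + 1; pen <- pen + 1 * w
          }
        }
        if (mm <= max_mm) {
          rows[[length(rows) + 1]] <- data.frame(
            pirna_id = pirnas$pirna_id[pi], mrna_id = mn, site_start = st,
            n_mismatches = mm, n_gu_wobbles = wob, penalty_score = pen,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(pirna_id = character(), mrna_id = character(),
               site_start = integer(), n_mismatches = integer(),
               n_gu_wobbles = integer(), penalty_score = numeric(),
               stringsAsFactors = FALSE)
}

# Exhaustive two-sided Fisher p by direct hypergeometric summation with
# choose(); sums P(X = x) over all x whose point probability does not
# exceed that of the observed k (the two-sided rule fisher.test documents).
oracle_fisher_p <- function(k, n, K, N) {
  support <- max(0, n + K - N):min(n, K)
  pr <- vapply(support, function(x) {
    exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
  }, numeric(1))
  p_obs <- pr[match(k, support)]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Independent nearest-neighbor sum for a perfect (fully Watson-Crick)
# duplex, reading stacks straight out of the parameter table.
oracle_perfect_dg <- function(pirna_seq, params = nn_params()) {
  p <- strsplit(chartr("T", "U", pirna_seq), "")[[1]]
  comp_rna <- c(A = "U", C = "G", G = "C", U = "A")
  q <- vapply(p, function(b) comp_rna[[b]], character(1))
  dg <- params$init_penalty
  for (i in 1:(length(p) - 1)) {
    p1 <- paste0(p[i], q[i])
    p2 <- paste0(q[i + 1], p[i + 1])
    dg <- dg + params$stack_energies[p1, p2]
  }
  for (i in c(1, length(p))) {
    if (paste0(p[i], q[i]) %in% c("AU", "UA", "GU", "UG")) {
      dg <- dg + params$au_end_penalty
    }
  }
  dg
}

random_tag_table <- function(n, lens = 18:33) {
  data.frame(tag_id = sprintf("t%03d", seq_len(n)),
             sequence = vapply(sample(lens, n, replace = TRUE),
                               function(L) paste(sample(c("A", "C", "G", "T"),
                                                        L, replace = TRUE),
                                                 collapse = ""),
                               character(1)),
             count = sample(1:50, n, replace = TRUE),
             stringsAsFactors = FALSE)
}
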