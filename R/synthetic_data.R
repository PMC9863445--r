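## Self-contained synthetic test worlds with planted ground truth for every
## pipeline stage: a genome carrying planted piRNA loci (24-33 nt, 5'-C
## biased) and annotated contaminant ncRNA loci, three developmental groups
## (Ac4/Ac5/Ac6) x three replicate libraries with lognormal replicate noise
## and planted fold changes, transcripts carrying planted antisense target
## sites, and a gene-to-term map. Identical seeds give identical worlds.

#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_world()]. The
#' defaults describe the study design the generator emulates: three groups
#' of three replicate small-RNA libraries, ~300 planted piRNA loci with a
#' 5'-C bias, contaminants from each filtered ncRNA class, 4-fold planted
#' expression changes between consecutive groups, and transcripts carrying
#' planted antisense sites for every differentially expressed piRNA.
#'
#' @param seed integer RNG seed.
#' @param genome_length total genome size in bp (split over two scaffolds).
#' @param n_pirna_loci planted piRNA loci (includes the group-specific ones).
#' @param pirna_length_probs named probabilities over lengths 24..33.
#' @param first_base_probs named probabilities over A/C/G/T for the 5' base.
#' @param n_contaminant_loci loci planted per contaminant biotype.
#' @param groups group names, ordered by developmental stage.
#' @param replicates_per_group replicates per group.
#' @param library_size expected clean reads per sample.
#' @param de_fraction fraction of piRNAs given a planted fold change.
#' @param planted_log2fc magnitude of the planted log2 fold change.
#' @param replicate_noise_cv coefficient of variation of the multiplicative
#'   lognormal replicate noise.
#' @param n_group_specific piRNA loci expressed in exactly one group (per
#'   group; carved out of `n_pirna_loci`).
#' @param n_transcripts number of synthetic mRNAs.
#' @param transcript_length min/max transcript length.
#' @param planted_sites_per_de_pirna antisense sites planted per DE piRNA.
#' @param mismatches_in_planted_sites mismatches introduced into each
#'   planted site (0..3).
#' @param n_background_loci short (18-23 nt) unannotated reads, below the
#'   piRNA length window.
#' @param n_multimapper_loci piRNA-length reads planted at two genomic
#'   positions each, excluded by the unique-position rule.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       genome_length = 50000L,
                       n_pirna_loci = 300L,
                       pirna_length_probs = c(
                         "24" = 0.08, "25" = 0.10, "26" = 0.13, "27" = 0.16,
                         "28" = 0.16, "29" = 0.13, "30" = 0.09, "31" = 0.07,
                         "32" = 0.05, "33" = 0.03),
                       first_base_probs = c(A = 0.18, C = 0.5, G = 0.16, T = 0.16),
                       n_contaminant_loci = 8L,
                       groups = c("Ac4", "Ac5", "Ac6"),
                       replicates_per_group = 3L,
                       library_size = 50000L,
                       de_fraction = 0.1,
                       planted_log2fc = 2,
                       replicate_noise_cv = 0.2,
                       n_group_specific = 10L,
                       n_transcripts = 40L,
                       transcript_length = c(600L, 1500L),
                       planted_sites_per_de_pirna = 2L,
                       mismatches_in_planted_sites = 0L,
                       n_background_loci = 30L,
                       n_multimapper_loci = 5L) {
  stopifnot(abs(sum(pirna_length_probs) - 1) < 1e-9,
            abs(sum(first_base_probs) - 1) < 1e-9,
            de_fraction >= 0, de_fraction <= 1,
            length(groups) >= 2, replicates_per_group >= 1,
            mismatches_in_planted_sites >= 0, mismatches_in_planted_sites <= 3,
            n_pirna_loci > length(groups) * n_group_specific)
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_pirna_loci = as.integer(n_pirna_loci),
              pirna_length_probs = pirna_length_probs,
              first_base_probs = first_base_probs,
              n_contaminant_loci = as.integer(n_contaminant_loci),
              groups = groups,
              replicates_per_group = as.integer(replicates_per_group),
              library_size = as.integer(library_size),
              de_fraction = de_fraction, planted_log2fc = planted_log2fc,
              replicate_noise_cv = replicate_noise_cv,
              n_group_specific = as.integer(n_group_specific),
              n_transcripts = as.integer(n_transcripts),
              transcript_length = as.integer(transcript_length),
              planted_sites_per_de_pirna = as.integer(planted_sites_per_de_pirna),
              mismatches_in_planted_sites = as.integer(mismatches_in_planted_sites),
              n_background_loci = as.integer(n_background_loci),
              n_multimapper_loci = as.integer(n_multimapper_loci))
  class(cfg) <- "sim_config"
  cfg
}

## Contaminant locus lengths per biotype; miRNA loci are precursor-sized and
## yield mature-length (20-24 nt) reads.
CONTAMINANT_LOCUS_LEN <- c(rRNA = 120L, tRNA = 75L, snRNA = 110L,
                           snoRNA = 90L, scRNA = 100L, miRNA = 70L)

## Place segments of given lengths non-overlappingly (min 5 bp gaps) along a
## chromosome of length chrom_len; returns 1-based starts in placement order.
place_segments <- function(lens, chrom_len, min_gap = 5L) {
  k <- length(lens)
  if (k == 0L) return(integer(0))
  need <- sum(lens) + min_gap * (k + 1L)
  if (need > chrom_len) {
    stop("infeasible config: ", need, " bp of planted loci exceed scaffold of ",
         chrom_len, " bp", call. = FALSE)
  }
  slack <- chrom_len - need
  ## split the slack over k+1 inter-segment gaps
  cuts <- sort(sample.int(slack + 1L, k, replace = TRUE) - 1L)
  extra <- diff(c(0L, cuts))
  starts <- integer(k)
  pos <- 1L
  for (i in seq_len(k)) {
    pos <- pos + min_gap + extra[i]
    starts[i] <- pos
    pos <- pos + lens[i]
  }
  starts
}

## Multiplicative lognormal noise factors with mean 1 and the given cv.
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sigma) - sigma^2 / 2)
}

#' Generate a complete synthetic test world
#'
#' Generates a genome with planted piRNA, contaminant-ncRNA, background and
#' multimapper loci, a GFF3-style annotation of the contaminants, per-sample
#' collapsed read libraries with planted fold changes and replicate noise,
#' transcripts carrying planted antisense target sites for every DE piRNA,
#' a gene-to-term map, and truth tables tracing every read and site to its
#' planted origin. Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return list of class `sim_world` with elements `genome` (named character
#'   vector), `annotation` (`data.frame`), `transcripts` (named character),
#'   `term_map` (`data.frame`), `libraries` (named list of per-sample tag
#'   `data.frame`s), `manifest` (`data.frame`: `sample`, `group`,
#'   `library_size`), `truth` (list of `pirna_loci`, `contaminant_reads`,
#'   `background_reads`, `multimapper_reads`, `de`, `sites`) and `config`.
#' @export
simulate_world <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  groups <- cfg$groups
  n_groups <- length(groups)

  ## ---- planted sequences -------------------------------------------------
  lens <- sample(as.integer(names(cfg$pirna_length_probs)), cfg$n_pirna_loci,
                 replace = TRUE, prob = cfg$pirna_length_probs)
  pirna_seq <- vapply(lens, function(L) {
    paste0(sample(DNA_BASES, 1, prob = cfg$first_base_probs),
           random_dna(1, L - 1L))
  }, character(1))
  while (anyDuplicated(pirna_seq)) {
    i <- which(duplicated(pirna_seq))
    pirna_seq[i] <- vapply(lens[i], function(L) {
      paste0(sample(DNA_BASES, 1, prob = cfg$first_base_probs),
             random_dna(1, L - 1L))
    }, character(1))
  }
  biotypes <- names(CONTAMINANT_LOCUS_LEN)
  cont <- do.call(rbind, lapply(biotypes, function(b) {
    data.frame(biotype = b,
               sequence = random_dna(cfg$n_contaminant_loci,
                                     CONTAMINANT_LOCUS_LEN[[b]]),
               strand = sample(c("+", "-"), cfg$n_contaminant_loci,
                               replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  bg_seq <- vapply(sample(18:23, cfg$n_background_loci, replace = TRUE),
                   function(L) random_dna(1, L), character(1))
  mm_seq <- random_dna(cfg$n_multimapper_loci, 26L)

  ## ---- genome assembly ---------------------------------------------------
  ## every planted segment, multimappers twice
  seg <- data.frame(
    kind = c(rep("pirna", length(pirna_seq)),
             rep("contaminant", nrow(cont)),
             rep("background", length(bg_seq)),
             rep("multimapper", 2L * length(mm_seq))),
    idx = c(seq_along(pirna_seq), seq_len(nrow(cont)), seq_along(bg_seq),
            rep(seq_along(mm_seq), each = 2L)),
    sequence = c(pirna_seq, cont$sequence, bg_seq, rep(mm_seq, each = 2L)),
    stringsAsFactors = FALSE)
  seg <- seg[sample.int(nrow(seg)), , drop = FALSE]
  seg$chrom <- rep_len(c("scaf1", "scaf2"), nrow(seg))
  chrom_len <- c(scaf1 = cfg$genome_length %/% 2L,
                 scaf2 = cfg$genome_length - cfg$genome_length %/% 2L)
  genome <- vapply(names(chrom_len), function(ch) random_dna(1, chrom_len[[ch]]),
                   character(1))
  seg$start <- NA_integer_
  for (ch in names(chrom_len)) {
    on_ch <- which(seg$chrom == ch)
    starts <- place_segments(nchar(seg$sequence[on_ch]), chrom_len[[ch]])
    seg$start[on_ch] <- starts
    g <- seq_chars(genome[[ch]])
    for (i in seq_along(on_ch)) {
      sq <- seq_chars(seg$sequence[on_ch[i]])
      g[starts[i]:(starts[i] + length(sq) - 1L)] <- sq
    }
    genome[[ch]] <- paste(g, collapse = "")
  }

  ## ---- annotation of contaminant loci ------------------------------------
  cseg <- seg[seg$kind == "contaminant", , drop = FALSE]
  cidx <- cseg$idx
  annotation <- data.frame(
    seq_id = cseg$chrom, start = cseg$start,
    end = cseg$start + nchar(cseg$sequence) - 1L,
    strand = cont$strand[cidx], biotype = cont$biotype[cidx],
    feature_id = sprintf("%s_%02d", cont$biotype[cidx], cidx),
    stringsAsFactors = FALSE, row.names = NULL)

  ## ---- uniqueness audit of planted piRNA loci ----------------------------
  index <- build_genome_index(genome, k = 12L)
  pseg <- seg[seg$kind == "pirna", , drop = FALSE]
  pseg <- pseg[order(pseg$idx), , drop = FALSE]
  n_hits <- vapply(pirna_seq, function(s) nrow(query_index(index, s)),
                   integer(1), USE.NAMES = FALSE)
  gs <- rep(NA_character_, cfg$n_pirna_loci)
  if (cfg$n_group_specific > 0) {
    gs[seq_len(n_groups * cfg$n_group_specific)] <-
      rep(groups, each = cfg$n_group_specific)
  }
  pirna_loci <- data.frame(
    locus_id = sprintf("pirna_locus_%03d", seq_along(pirna_seq)),
    sequence = pirna_seq, length = lens,
    seq_id = pseg$chrom, start = pseg$start, strand = "+",
    unique = n_hits == 1L, group_specific = gs,
    stringsAsFactors = FALSE, row.names = NULL)

  ## ---- planted differential expression -----------------------------------
  eligible <- which(is.na(gs))
  n_de <- round(cfg$de_fraction * length(eligible))
  de_idx <- sample(eligible, n_de)
  comparisons <- lapply(seq_len(n_groups - 1L),
                        function(i) groups[c(i, i + 1L)])
  de <- data.frame(locus_id = pirna_loci$locus_id[de_idx],
                   comparison = vapply(
                     sample(length(comparisons), n_de, replace = TRUE),
                     function(i) paste(comparisons[[i]], collapse = ":"),
                     character(1)),
                   true_log2fc = sample(c(-1, 1), n_de, replace = TRUE) *
                     cfg$planted_log2fc,
                   stringsAsFactors = FALSE)

  ## ---- per-group expected abundances -------------------------------------
  base_mu <- stats::rlnorm(cfg$n_pirna_loci, meanlog = log(100), sdlog = 0.7)
  mu <- matrix(rep(base_mu, n_groups), ncol = n_groups,
               dimnames = list(pirna_loci$locus_id, groups))
  for (i in seq_len(nrow(de))) {
    cmp <- strsplit(de$comparison[i], ":", fixed = TRUE)[[1]]
    later <- which(groups == cmp[2]):n_groups
    mu[de$locus_id[i], later] <- mu[de$locus_id[i], later] * 2^de$true_log2fc[i]
  }
  for (i in which(!is.na(gs))) {
    mu[i, groups != gs[i]] <- 0
  }

  ## contaminant reads: fixed windows per locus, 3 distinct reads each
  cont_reads <- do.call(rbind, lapply(seq_len(nrow(cont)), function(i) {
    locus_len <- nchar(cont$sequence[i])
    rl <- if (cont$biotype[i] == "miRNA") sample(20:24, 3, replace = TRUE)
          else sample(18:30, 3, replace = TRUE)
    st <- vapply(rl, function(L) sample.int(locus_len - L + 1L, 1), integer(1))
    s <- substring(cont$sequence[i], st, st + rl - 1L)
    if (cont$strand[i] == "-") s <- revcomp(s)
    data.frame(biotype = cont$biotype[i],
               feature_id = sprintf("%s_%02d", cont$biotype[i], i),
               sequence = s, stringsAsFactors = FALSE)
  }))
  cont_reads <- cont_reads[!duplicated(cont_reads$sequence), , drop = FALSE]
  cont_reads <- cont_reads[!cont_reads$sequence %in% pirna_loci$sequence, ,
                           drop = FALSE]
  cont_mu <- stats::rlnorm(nrow(cont_reads), meanlog = log(100), sdlog = 0.7)
  bg_mu <- stats::rlnorm(length(bg_seq), meanlog = log(60), sdlog = 0.7)
  mm_mu <- stats::rlnorm(length(mm_seq), meanlog = log(60), sdlog = 0.7)

  ## scale everything so a sample's expected total is library_size
  expected_total <- mean(colSums(mu)) + sum(cont_mu) + sum(bg_mu) + sum(mm_mu)
  scale <- cfg$library_size / expected_total
  mu <- mu * scale
  cont_mu <- cont_mu * scale
  bg_mu <- bg_mu * scale
  mm_mu <- mm_mu * scale

  ## ---- draw libraries ----------------------------------------------------
  samples <- as.vector(t(outer(groups, seq_len(cfg$replicates_per_group),
                               function(g, r) sprintf("%s_r%d", g, r))))
  sample_group <- rep(groups, each = cfg$replicates_per_group)
  all_seq <- c(pirna_loci$sequence, cont_reads$sequence, bg_seq, mm_seq)
  all_ids <- c(pirna_loci$locus_id,
               sprintf("cont_%03d", seq_len(nrow(cont_reads))),
               sprintf("bg_%03d", seq_along(bg_seq)),
               sprintf("mm_%03d", seq_along(mm_seq)))
  libraries <- vector("list", length(samples))
  names(libraries) <- samples
  for (si in seq_along(samples)) {
    g <- sample_group[si]
    means <- c(mu[, g], cont_mu, bg_mu, mm_mu)
    noisy <- means * lognormal_noise(length(means), cfg$replicate_noise_cv)
    counts <- stats::rpois(length(noisy), noisy)
    keep <- counts > 0
    libraries[[si]] <- data.frame(tag_id = all_ids[keep],
                                  sequence = all_seq[keep],
                                  count = counts[keep],
                                  stringsAsFactors = FALSE)
  }
  manifest <- data.frame(sample = samples, group = sample_group,
                         library_size = vapply(libraries,
                                               function(l) sum(l$count),
                                               numeric(1)),
                         stringsAsFactors = FALSE, row.names = NULL)

  ## ---- transcripts with planted antisense sites --------------------------
  tr_len <- sample(cfg$transcript_length[1]:cfg$transcript_length[2],
                   cfg$n_transcripts, replace = TRUE)
  transcripts <- stats::setNames(
    vapply(tr_len, function(L) random_dna(1, L), character(1)),
    sprintf("mrna_%03d", seq_len(cfg$n_transcripts)))
  occupied <- lapply(transcripts, function(x) integer(0))
  sites <- list()
  for (i in seq_len(nrow(de))) {
    lid <- de$locus_id[i]
    pseq2 <- pirna_loci$sequence[pirna_loci$locus_id == lid]
    L <- nchar(pseq2)
    for (s in seq_len(cfg$planted_sites_per_de_pirna)) {
      site <- revcomp(pseq2)
      mm_pos <- integer(0)
      if (cfg$mismatches_in_planted_sites > 0) {
        mm_pos <- sample.int(L, cfg$mismatches_in_planted_sites)
        sc <- seq_chars(site)
        for (mp in mm_pos) {
          ## mutate to a base that is neither complementary nor a wobble
          ## partner of the piRNA base opposite this site position
          pb <- substr(pseq2, L - mp + 1L, L - mp + 1L)
          forbidden <- c(sc[mp], revcomp(pb),
                         if (pb == "G") "T", if (pb == "T") "G")
          sc[mp] <- sample(setdiff(DNA_BASES, forbidden), 1)
        }
        site <- paste(sc, collapse = "")
      }
      ## find a free position in a random transcript
      for (attempt in seq_len(50)) {
        mr <- sample(names(transcripts), 1)
        tl <- nchar(transcripts[[mr]])
        if (tl < L + 2L) next
        pos <- sample.int(tl - L + 1L, 1)
        if (any(abs(occupied[[mr]] - pos) < L + 5L)) next
        tc <- seq_chars(transcripts[[mr]])
        tc[pos:(pos + L - 1L)] <- seq_chars(site)
        transcripts[[mr]] <- paste(tc, collapse = "")
        occupied[[mr]] <- c(occupied[[mr]], pos)
        sites[[length(sites) + 1L]] <- data.frame(
          locus_id = lid, mrna_id = mr, position = pos,
          n_mismatches = cfg$mismatches_in_planted_sites,
          site_seq = site, stringsAsFactors = FALSE)
        break
      }
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites) else data.frame(
    locus_id = character(), mrna_id = character(), position = integer(),
    n_mismatches = integer(), site_seq = character(), stringsAsFactors = FALSE)

  ## ---- gene-to-term map --------------------------------------------------
  term_pool <- data.frame(
    term_id = c("path:wnt", "path:tgfb", "path:hippo", "path:jakstat",
                sprintf("GO:%07d", 1:8)),
    term_name = c("Wnt signaling pathway", "TGF-beta signaling pathway",
                  "Hippo signaling pathway", "Jak-STAT signaling pathway",
                  "cellular process", "localization", "binding",
                  "transporter activity", "membrane part", "synapse part",
                  "biological regulation", "metabolic process"),
    category = c(rep("pathway", 4), "BP", "BP", "MF", "MF", "CC", "CC",
                 "BP", "BP"),
    stringsAsFactors = FALSE)
  term_map <- do.call(rbind, lapply(names(transcripts), function(g) {
    n_terms <- sample(1:4, 1)
    rows <- term_pool[sample.int(nrow(term_pool), n_terms), , drop = FALSE]
    cbind(gene_id = g, rows)
  }))
  rownames(term_map) <- NULL

  structure(list(genome = genome, annotation = annotation,
                 transcripts = transcripts, term_map = term_map,
                 libraries = libraries, manifest = manifest,
                 truth = list(pirna_loci = pirna_loci,
                              contaminant_reads = cont_reads,
                              background_reads = data.frame(
                                sequence = bg_seq, stringsAsFactors = FALSE),
                              multimapper_reads = data.frame(
                                sequence = mm_seq, stringsAsFactors = FALSE),
                              de = de, sites = sites,
                              group_means = mu),
                 config = cfg),
            class = "sim_world")
}

#' @export
print.sim_world <- function(x, ...) {
  cat("Synthetic small-RNA world (seed", x$config$seed, "):\n")
  cat("  genome:", sum(nchar(x$genome)), "bp over", length(x$genome),
      "scaffolds;", nrow(x$truth$pirna_loci), "planted piRNA loci\n")
  cat("  contaminant loci:", nrow(x$annotation), "; samples:",
      nrow(x$manifest), "; transcripts:", length(x$transcripts), "\n")
  cat("  planted DE piRNAs:", nrow(x$truth$de), "; planted target sites:",
      nrow(x$truth$sites), "\n")
  invisible(x)
}

#' Write a synthetic world to disk
#'
#' Emits genome and transcript FASTA, annotation GFF3, per-sample collapsed
#' read FASTA under `reads/`, a manifest TSV, the term map TSV, and the
#' truth tables as TSV under `truth/`.
#'
#' @param world a `sim_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(file.path(dir, "reads"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  g <- Biostrings::DNAStringSet(world$genome)
  Biostrings::writeXStringSet(g, file.path(dir, "genome.fa"))
  tr <- Biostrings::DNAStringSet(world$transcripts)
  Biostrings::writeXStringSet(tr, file.path(dir, "transcripts.fa"))
  write_gff3(world$annotation, file.path(dir, "annotation.gff3"))
  write.table(world$term_map, file.path(dir, "term_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(world$manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (s in names(world$libraries)) {
    write_fasta_counts(world$libraries[[s]],
                       file.path(dir, "reads", paste0(s, ".fa")))
  }
  for (tname in setdiff(names(world$truth), "group_means")) {
    write.table(world$truth[[tname]],
                file.path(dir, "truth", paste0(tname, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Simulate a piRNA count matrix without a genome
#'
#' A lightweight generator for the count model alone (no genome, annotation
#' or sequences): lognormal base abundances, planted fold changes for a
#' subset of rows between two groups, multiplicative lognormal replicate
#' noise, Poisson counting. Used to study the operating characteristics of
#' the differential screen at scale.
#'
#' @param n_pirnas number of rows.
#' @param n_reps replicates per group.
#' @param groups two group names.
#' @param library_size expected reads per sample across the simulated rows.
#' @param de_fraction fraction of rows with a planted fold change.
#' @param planted_log2fc signed or unsigned log2 fold change magnitude;
#'   planted rows get a random sign.
#' @param cv replicate noise coefficient of variation.
#' @param seed RNG seed.
#' @return list with `counts` (matrix), `library_sizes`, `manifest` (named
#'   vector sample -> group) and `truth` (`data.frame`: `pirna_id`, `is_de`,
#'   `true_log2fc`).
#' @export
simulate_counts <- function(n_pirnas = 1000L, n_reps = 3L,
                            groups = c("A", "B"), library_size = 1e6,
                            de_fraction = 0, planted_log2fc = 2,
                            cv = 0.2, seed = 1L) {
  set.seed(seed)
  stopifnot(length(groups) == 2)
  base_mu <- stats::rlnorm(n_pirnas, meanlog = log(100), sdlog = 0.7)
  is_de <- rep(FALSE, n_pirnas)
  true_lfc <- rep(0, n_pirnas)
  n_de <- round(de_fraction * n_pirnas)
  if (n_de > 0) {
    idx <- sample.int(n_pirnas, n_de)
    is_de[idx] <- TRUE
    true_lfc[idx] <- sample(c(-1, 1), n_de, replace = TRUE) * abs(planted_log2fc)
  }
  mu_a <- base_mu * library_size / sum(base_mu)
  mu_b <- mu_a * 2^true_lfc
  samples <- c(sprintf("%s_r%d", groups[1], seq_len(n_reps)),
               sprintf("%s_r%d", groups[2], seq_len(n_reps)))
  counts <- matrix(0L, n_pirnas, 2L * n_reps,
                   dimnames = list(sprintf("piR-sim-%06d", seq_len(n_pirnas)),
                                   samples))
  for (r in seq_len(n_reps)) {
    counts[, r] <- stats::rpois(n_pirnas, mu_a * lognormal_noise(n_pirnas, cv))
    counts[, n_reps + r] <- stats::rpois(n_pirnas,
                                         mu_b * lognormal_noise(n_pirnas, cv))
  }
  list(counts = counts,
       library_sizes = colSums(counts),
       manifest = stats::setNames(rep(groups, each = n_reps), samples),
       truth = data.frame(pirna_id = rownames(counts), is_de = is_de,
                          true_log2fc = true_lfc, stringsAsFactors = FALSE))
}
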