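## Antisense target scanning: every ungapped window of every mRNA is tested
## against the reverse complement of each piRNA; windows within the mismatch
## budget (3 by default) are scored with a penalty (mismatch 1, G:U wobble
## 0.5, doubled inside the piRNA seed region, positions 2-7) and a
## nearest-neighbor duplex free energy. Retained target sites must be more
## stable than the free-energy cutoff (strictly below -20 kcal/mol).

#' Scan mRNAs for piRNA target sites
#'
#' Exhaustively evaluates every ungapped window of each transcript against
#' the antisense of each piRNA. A window is a candidate site when its number
#' of mismatches is at most `max_mismatches`; G:U wobbles count 0.5 toward
#' the penalty score but (by default) not against the mismatch cap. The
#' penalty of each position is doubled inside the seed region (piRNA
#' positions 2-7). Each candidate also gets a nearest-neighbor duplex free
#' energy from [duplex_free_energy()].
#'
#' @param pirnas a `pirna_set`, or a `data.frame` with columns `pirna_id`,
#'   `sequence` (DNA).
#' @param mrnas named character vector of transcript sequences (DNA), or a
#'   `DNAStringSet`, or path to a transcript FASTA.
#' @param max_mismatches mismatch cap per site (default 3).
#' @param seed_region inclusive piRNA position window whose penalties are
#'   doubled (default `c(2, 7)`).
#' @param gu_counts_as_mismatch if `TRUE`, wobbles also count against the
#'   mismatch cap.
#' @param params nearest-neighbor table from [nn_params()].
#' @return `data.frame` of class `target_sites` with columns `pirna_id`,
#'   `mrna_id`, `site_start` (1-based on the mRNA), `site_seq`,
#'   `duplex_alignment` (per piRNA position 5'->3': `|` Watson-Crick, `o`
#'   wobble, `x` mismatch), `n_mismatches`, `n_gu_wobbles`, `penalty_score`,
#'   `delta_g` (kcal/mol). Sorted by `(penalty_score, delta_g)`.
#' @export
scan_targets <- function(pirnas, mrnas, max_mismatches = 3L,
                         seed_region = c(2L, 7L),
                         gu_counts_as_mismatch = FALSE, params = nn_params()) {
  if (inherits(pirnas, "pirna_set")) pirnas <- pirnas$pirnas
  stopifnot(all(c("pirna_id", "sequence") %in% names(pirnas)))
  if (is.character(mrnas) && length(mrnas) == 1L && file.exists(mrnas[[1]]) &&
      !grepl("^[ACGTNacgtn]+$", mrnas[[1]])) {
    mrnas <- Biostrings::readDNAStringSet(mrnas)
  }
  if (methods::is(mrnas, "DNAStringSet")) {
    mrnas <- stats::setNames(as.character(mrnas), sub("\\s.*$", "", names(mrnas)))
  }
  stopifnot(is.character(mrnas), !is.null(names(mrnas)))
  if (length(mrnas) == 0L) stop("no transcripts supplied", call. = FALSE)
  mrnas <- toupper(mrnas)
  res <- list()
  for (pi in seq_len(nrow(pirnas))) {
    pseq <- toupper(pirnas$sequence[pi])
    L <- nchar(pseq)
    rcpc <- seq_chars(revcomp(pseq))
    ## penalty weight per window position j (pairs piRNA position L - j + 1)
    ppos <- L - seq_len(L) + 1L
    wt <- ifelse(ppos >= seed_region[1] & ppos <= seed_region[2], 2, 1)
    for (mi in seq_along(mrnas)) {
      m <- mrnas[[mi]]
      n <- nchar(m)
      if (L > n) next
      starts <- seq_len(n - L + 1L)
      mm_cnt <- integer(length(starts))
      wob_cnt <- integer(length(starts))
      pen <- numeric(length(starts))
      cols <- vector("list", L)
      for (j in seq_len(L)) {
        col <- substring(m, starts + j - 1L, starts + j - 1L)
        cols[[j]] <- col
        is_wc <- col == rcpc[j]
        is_wob <- (rcpc[j] == "C" & col == "T") | (rcpc[j] == "A" & col == "G")
        is_mm <- !is_wc & !is_wob
        mm_cnt <- mm_cnt + is_mm
        wob_cnt <- wob_cnt + is_wob
        pen <- pen + wt[j] * (1 * is_mm + 0.5 * is_wob)
      }
      eff <- mm_cnt + if (gu_counts_as_mismatch) wob_cnt else 0L
      cand <- which(eff <= max_mismatches)
      if (length(cand) == 0L) next
      site_seq <- substring(m, starts[cand], starts[cand] + L - 1L)
      align <- vapply(cand, function(ci) {
        sym <- vapply(seq_len(L), function(j) {
          col <- cols[[j]][ci]
          if (col == rcpc[j]) "|"
          else if ((rcpc[j] == "C" && col == "T") || (rcpc[j] == "A" && col == "G")) "o"
          else "x"
        }, character(1))
        ## report along the piRNA 5'->3' (window position L pairs piRNA pos 1)
        paste(rev(sym), collapse = "")
      }, character(1))
      dg <- vapply(site_seq, function(s) duplex_free_energy(pseq, s, params),
                   numeric(1), USE.NAMES = FALSE)
      res[[length(res) + 1L]] <- data.frame(
        pirna_id = pirnas$pirna_id[pi], mrna_id = names(mrnas)[mi],
        site_start = starts[cand], site_seq = site_seq,
        duplex_alignment = align, n_mismatches = mm_cnt[cand],
        n_gu_wobbles = wob_cnt[cand], penalty_score = pen[cand],
        delta_g = dg, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else data.frame(
    pirna_id = character(), mrna_id = character(), site_start = integer(),
    site_seq = character(), duplex_alignment = character(),
    n_mismatches = integer(), n_gu_wobbles = integer(),
    penalty_score = numeric(), delta_g = numeric(), stringsAsFactors = FALSE)
  out <- out[order(out$penalty_score, out$delta_g, out$pirna_id,
                   out$mrna_id, out$site_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("target_sites", "data.frame")
  out
}

#' Nearest-neighbor free energy of an ungapped piRNA:mRNA duplex
#'
#' Computes the duplex free energy as the initiation penalty plus the sum of
#' nearest-neighbor stacking energies over consecutive paired positions
#' (Watson-Crick or G:U wobble), plus a terminal penalty for each duplex end
#' whose outermost position forms an AU or GU pair. Mismatched positions
#' break stacks: no stacking energy is counted across them, and they add no
#' stabilisation of their own.
#'
#' @param pirna_seq piRNA sequence, 5'->3' (DNA or RNA letters).
#' @param site_seq the mRNA site it pairs with, 5'->3', same length;
#'   position `i` of the piRNA pairs position `L - i + 1` of the site.
#' @param params table from [nn_params()].
#' @return free energy in kcal/mol (negative = stable).
#' @export
#' @examples
#' p <- nn_params()
#' duplex_free_energy("GGGGG", "CCCCC", p)  # 4 GC-helix stacks + initiation
duplex_free_energy <- function(pirna_seq, site_seq, params = nn_params()) {
  p <- seq_chars(dna_to_rna(toupper(pirna_seq)))
  s <- seq_chars(dna_to_rna(toupper(site_seq)))
  L <- length(p)
  stopifnot(L == length(s), L >= 1)
  q <- rev(s)  # q[i] is the mRNA base opposite piRNA position i
  paired <- !is.na(pair_label(p, q))
  dg <- params$init_penalty
  if (L >= 2) {
    for (i in seq_len(L - 1L)) {
      if (paired[i] && paired[i + 1L]) {
        dg <- dg + stack_energy(params, p[i], p[i + 1L], q[i], q[i + 1L])
      }
    }
  }
  for (i in c(1L, if (L > 1) L)) {
    if (paired[i] && pair_label(p[i], q[i]) %in% c("AU", "UA", "GU", "UG")) {
      dg <- dg + params$au_end_penalty
    }
  }
  dg
}

#' Filter target sites by duplex free energy
#'
#' Retains sites strictly more stable than the cutoff (`delta_g <
#' dg_cutoff`); a site at exactly the cutoff is dropped. Input order is
#' preserved.
#'
#' @param sites a `target_sites` table.
#' @param dg_cutoff free-energy threshold in kcal/mol (default -20).
#' @return the filtered `target_sites` table.
#' @export
filter_sites <- function(sites, dg_cutoff = -20) {
  out <- sites[sites$delta_g < dg_cutoff, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("target_sites", "data.frame")
  out
}

#' Deduplicated piRNA-mRNA target pairs
#'
#' Collapses a site table to one row per (piRNA, mRNA) pair -- an mRNA
#' counts once per piRNA no matter how many sites it carries -- keeping the
#' best (lowest penalty, then lowest free energy) site's statistics.
#'
#' @param sites a `target_sites` table (typically after [filter_sites()]).
#' @return `data.frame` with `pirna_id`, `mrna_id`, `n_sites`, and the best
#'   site's `penalty_score` and `delta_g`.
#' @export
target_pairs <- function(sites) {
  if (nrow(sites) == 0L) {
    return(data.frame(pirna_id = character(), mrna_id = character(),
                      n_sites = integer(), penalty_score = numeric(),
                      delta_g = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(sites$pirna_id, sites$mrna_id, sep = "\r")
  ord <- order(key, sites$penalty_score, sites$delta_g)
  s <- sites[ord, , drop = FALSE]
  k <- key[ord]
  first <- !duplicated(k)
  out <- data.frame(pirna_id = s$pirna_id[first], mrna_id = s$mrna_id[first],
                    n_sites = as.integer(table(k)[k[first]]),
                    penalty_score = s$penalty_score[first],
                    delta_g = s$delta_g[first],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$pirna_id, out$mrna_id), , drop = FALSE]
}

#' Empirical per-site significance from shuffled piRNAs
#'
#' For each site, scores `n_shuffle` dinucleotide-preserving shuffles of the
#' piRNA against the same site sequence and reports the percentile of the
#' observed free energy in that null: `p = (1 + #{dG_shuffled <= dG_obs}) /
#' (n_shuffle + 1)`. This is the package's own construction of an edge
#' p-value for network filtering; it is not a standard published test.
#'
#' @param sites a `target_sites` table (needs the `site_seq` column).
#' @param pirnas `pirna_set` or `data.frame` with `pirna_id`, `sequence`.
#' @param n_shuffle shuffles per piRNA (default 100).
#' @param params table from [nn_params()].
#' @return `sites` with an added `empirical_p` column.
#' @export
empirical_edge_p <- function(sites, pirnas, n_shuffle = 100L,
                             params = nn_params()) {
  if (inherits(pirnas, "pirna_set")) pirnas <- pirnas$pirnas
  seq_of <- stats::setNames(toupper(pirnas$sequence), pirnas$pirna_id)
  ## one pool of shuffles per piRNA, reused across its sites
  shuffles <- lapply(seq_of, function(s) {
    replicate(n_shuffle, dinucleotide_shuffle(s))
  })
  sites$empirical_p <- vapply(seq_len(nrow(sites)), function(i) {
    sh <- shuffles[[sites$pirna_id[i]]]
    null_dg <- vapply(sh, duplex_free_energy, numeric(1),
                      site_seq = sites$site_seq[i], params = params)
    (1 + sum(null_dg <= sites$delta_g[i])) / (length(null_dg) + 1)
  }, numeric(1))
  sites
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Randomly permutes a sequence while preserving its exact dinucleotide
#' composition (and hence mononucleotide composition and first/last base),
#' by sampling a random Eulerian walk over the dinucleotide multigraph with
#' rejection. Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param x a single sequence.
#' @param max_tries rejection-sampling attempts before returning `x`
#'   unchanged (default 1000).
#' @return a shuffled sequence with identical dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(x, max_tries = 1000L) {
  ch <- seq_chars(x)
  n <- length(ch)
  if (n <= 3L) return(x)
  from <- ch[-n]
  to <- ch[-1L]
  for (t in seq_len(max_tries)) {
    ## per-vertex shuffled successor queues
    succ <- lapply(split(to, from), sample)
    ptr <- lapply(succ, function(v) 1L)
    out <- character(n)
    out[1L] <- ch[1L]
    cur <- ch[1L]
    ok <- TRUE
    for (i in 2:n) {
      q <- succ[[cur]]
      p <- ptr[[cur]]
      if (is.null(q) || p > length(q)) { ok <- FALSE; break }
      nxt <- q[p]
      ptr[[cur]] <- p + 1L
      out[i] <- nxt
      cur <- nxt
    }
    if (ok) return(paste(out, collapse = ""))
  }
  x
}
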