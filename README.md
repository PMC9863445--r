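# piragut

**piRNA discovery, differential expression and regulatory-network analysis
from small RNA-seq.**

PIWI-interacting RNAs (piRNAs) are 24–33 nt small non-coding RNAs that,
beyond their classical germline role in transposon silencing, are
increasingly found regulating mRNAs in somatic tissues — including the
developing gut of honeybee larvae. Identifying them from bulk small RNA-seq
is a filtering exercise: map the collapsed reads ("clean tags") to the
genome, strip everything that is a known small ncRNA (rRNA, tRNA, snRNA,
snoRNA, scRNA, miRNA), and keep the 24–33 nt tags that map to a single
genomic position. `piragut` implements that cascade and everything a study
built on it needs downstream, for bench scientists and bioinformaticians
analysing insect small-RNA libraries:

* collapsed-FASTA / FASTQ import with read counts (`id_xCOUNT` dialect);
* an exact k-mer genome index with strand-aware queries;
* annotation-cascade contaminant filtering and piRNA calling
  (length window + unique-position rule);
* length-distribution and 5′ first-base-bias statistics;
* TPM normalisation, `TPM = T × 10⁶ / N` with `N` the sample's total clean
  sRNA reads;
* a differential screen at `|log₂FC| ≥ 1` and `p ≤ 0.05` (Welch's t on TPM
  replicates, or Audic–Claverie on pooled counts), plus the `2^−ΔΔCt`
  helper for qPCR cross-validation;
* ungapped antisense target scanning (≤ 3 mismatches, G:U wobbles as half
  penalties, seed-region doubling at piRNA positions 2–7) with
  nearest-neighbor duplex free energies (Turner 2004 parameters) and a
  strict ΔG < −20 kcal/mol site filter;
* Fisher-exact term enrichment with rich factors (`k/K`);
* bipartite piRNA–mRNA networks with hubs, pathway subnetworks and
  GraphML/SIF export;
* a fully seeded synthetic-world generator that plants ground truth for
  every stage.

## Worked example

Everything below runs in under a minute on a laptop. We build a synthetic
world — a 50 kb genome with 300 planted piRNA loci, contaminant ncRNA loci
of every filtered class, three groups (Ac4/Ac5/Ac6) × three replicate
libraries, and transcripts carrying planted target sites — and push it
through the pipeline.

```r
library(piragut)

world <- simulate_world(sim_config(seed = 42))
libs  <- setNames(world$manifest$library_size, world$manifest$sample)
res   <- run_pirna_pipeline(world$libraries, world$genome, world$annotation,
                            library_sizes = libs)
res$classified
#> Classified tags (cascade rRNA > tRNA > snRNA > snoRNA > scRNA > miRNA):
#> candidate_pool          miRNA           rRNA          scRNA         snoRNA
#>            335             23             24             24             24
#>          snRNA           tRNA
#>             24             24
res$pirnas
#> piRNA candidate set: 300 piRNAs, 9 sample(s)
#>   length range: 24 - 33 nt
```

All 144 planted contaminant reads are removed with their planted class, and
the 300 candidates are exactly the planted unique piRNA loci (the short
background reads fail the length window; the twice-planted multimapper
reads fail the unique-position rule). Group membership and structure:

```r
manifest <- setNames(world$manifest$group, world$manifest$sample)
compare_groups(res$pirnas, manifest)
#> piRNA set comparison over 3 groups:
#>   shared by all: 270
#>   unique to Ac4 : 10
#>   unique to Ac5 : 10
#>   unique to Ac6 : 10
first_base_bias(res$pirnas)
#> First-base profile (pooled):
#>      A      C      G      U
#> 0.1900 0.4833 0.1500 0.1767
#> dominant first base: C
```

The 270/10/10/10 split recovers the generator's 10 group-specific loci per
group, and the pooled first-base profile recovers the planted 5′-C bias
(planted probability 0.5). The differential screen between consecutive
stages:

```r
de <- differential_screen(res$expr, manifest, c("Ac4", "Ac5"))
de
#> Differential screen Ac4 vs Ac5 ( welch_t ): 300 piRNAs; 15 up, 18 down
```

(The calls are the planted 4-fold effects for this comparison plus the
group-specific piRNAs, which are genuinely differential.) Target scanning
and the network for the DE piRNAs:

```r
truth  <- world$truth$pirna_loci
de_ids <- world$truth$de$locus_id
pir    <- data.frame(pirna_id = de_ids,
                     sequence = truth$sequence[match(de_ids, truth$locus_id)])
sites  <- filter_sites(scan_targets(pir, world$transcripts))  # dG < -20
net    <- build_network(sites)
net
#> piRNA-mRNA regulatory network: 27 piRNAs, 29 mRNAs, 52 edges
#>   top hub: pirna_locus_034 with 2 targets
enrich(unique(sites$mrna_id), names(world$transcripts), world$term_map)
#> Enrichment: 12 terms tested; 1 significant at raw p
```

Every planted antisense site is recovered (perfect 24–33-mers duplex far
below −20 kcal/mol), the network is the planted bipartite pairing, and the
enrichment table carries Fisher p, BH q and the rich factor `k/K` per term.
`pathway_subnetwork(net, genes)` restricts to, e.g., the Wnt-pathway genes
of the term map, and `write_network(net, "out")` emits GraphML/SIF/TSV.

A thin command-line wrapper over these functions is installed at
`inst/cli/piragut.R` (subcommands `simulate`, `classify`, `call`, `stats`,
`de`, `scan`, `enrich`, `network`).

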