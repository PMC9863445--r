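---
title: "piRNA discovery and regulatory-network analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{piRNA discovery and regulatory-network analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piragut)
```

# Overview

`piragut` implements a complete desk-scale pipeline for PIWI-interacting RNA
(piRNA) analysis in insect small RNA-seq data, of the kind used to
characterise piRNAs in honeybee larval gut tissue across developmental
stages. The stages are:

1. **Import** of collapsed small-RNA reads ("clean tags") with counts.
2. **Genome mapping** of every tag by exact k-mer indexed search.
3. **Annotation-cascade filtering** of known small ncRNA classes
   (rRNA, tRNA, snRNA, snoRNA, scRNA, miRNA).
4. **piRNA calling** by the length window (24–33 nt) and the
   unique-position rule.
5. **Structural statistics**: length distribution and 5′ first-base bias.
6. **TPM normalisation** and **differential-expression screening** between
   consecutive developmental groups.
7. **Antisense target scanning** with a mismatch cap and nearest-neighbor
   duplex free-energy filtering.
8. **Fisher-exact term enrichment** with rich factors.
9. **Bipartite piRNA–mRNA network construction** with pathway subnetworks.

A seeded synthetic-data generator plants ground truth for every stage, so
the whole pipeline is validated end to end without external downloads.

# The discovery model

## Filter cascade

Tags are first mapped to the genome; unmapped tags are reported and
dropped. A mapped tag is removed as a contaminant when **any** of its
genomic loci overlaps an annotated feature of a filtered ncRNA class by at
least one base pair. Overlaps are strand-aware by default (`stranded =
FALSE` relaxes this); the data this pipeline emulates do not state a
strandedness convention, so the switch is exposed.

When a tag overlaps features of several classes, a fixed cascade priority
decides the label: rRNA > tRNA > snRNA > snoRNA > scRNA > miRNA. The
priority order is a package convention — the classes themselves, not their
precedence, are what published filter cascades state. Which class wins only
affects contaminant bookkeeping, never the candidate pool: a tag is in the
pool exactly when it overlaps none of the six classes.

Filtering is done against a genomic annotation rather than by re-aligning
reads to sequence databases (GenBank/Rfam); at desk scale the two have the
same set semantics and the annotation route keeps tests self-contained.

## piRNA calling

From the candidate pool, a tag is called a piRNA when

* its length is between 24 and 33 nt inclusive, and
* it maps to **exactly one** genomic position (the unique-position rule).

Identifiers are assigned deterministically in sequence-sorted order
(`piR-ace-000001`, ...), so calling is invariant to input order. Presence
of a piRNA in a group means a summed raw count of at least
`min_count` (default 1) over the group's replicates; the set comparison
reports shared piRNAs, group-unique piRNAs, and all `2^g − 1` UpSet
membership classes.

## Structural statistics

The length histogram and the first-base profile both default to
**unique-sequence weighting** (each distinct piRNA counts once), which is
what per-length percentages of a piRNA catalogue usually show; a
read-count weighting is available (`weight = "read_counts"`). Both
statistics are computed over the full 24–33 nt calling window. First-base
frequencies are reported in RNA letters; ties in the dominant base are
reported as ties rather than broken arbitrarily.

# Quantification and differential expression

TPM here is *tags per million*:

$$\mathrm{TPM}_{is} = \frac{T_{is} \times 10^6}{N_s}$$

where $T_{is}$ is the read count of piRNA $i$ in sample $s$ and $N_s$ is
the sample's **total clean small-RNA reads** — not the piRNA-only sum and
with no length normalisation. Supplying the true library sizes matters:
with the fallback (per-sample sums of the supplied matrix) the columns of a
piRNA-only matrix would be inflated, so the fallback warns.

The screen between groups A and B uses the standard rule
$|\log_2 \mathrm{FC}| \ge 1$ and $p \le 0.05$, both boundaries inclusive,
with

$$\log_2 \mathrm{FC} = \log_2 \frac{\bar{x}_B + \varepsilon}{\bar{x}_A + \varepsilon}$$

on group-mean TPM. The pseudocount $\varepsilon = 0.01$ TPM keeps fold
changes finite when one group is zero (observed fold changes around
$\pm 12$ in comparable data sets imply some such handling); it is small
enough not to disturb moderately expressed piRNAs.

The p-value comes from **Welch's t test** on the TPM replicates (the
two-group location test a t-test-based analysis implies, robust to unequal
variances), or alternatively from the **Audic–Claverie** test on pooled raw
counts, useful when replicate-level variance cannot be estimated. Two
degenerate cases are closed deliberately: when both groups are exactly
constant, p is 1 if the constants agree and 0 if they differ. No
multiple-testing correction enters the screen — the rule is on raw p — but
a Benjamini–Hochberg column is emitted for information.

The `ddct()` helper implements the $2^{-\Delta\Delta C_t}$ relative
expression computation used when cross-validating screened piRNAs by
RT-qPCR against a reference gene.

# Target scanning and duplex energetics

## Scanner

piRNA targeting is modelled as ungapped antisense complementarity: every
window of every transcript is evaluated against the reverse complement of
each piRNA (so this scan is exhaustive by construction, and tests compare
it to an independent brute-force enumerator). A window is a candidate site
when it has at most `max_mismatches = 3` mismatches. G:U wobble pairs are
scored as half a mismatch in the penalty but, by default, do not count
against the mismatch cap (`gu_counts_as_mismatch` flips this). Penalties
are doubled inside the **seed region**, piRNA positions 2–7, following the
seed definition established for nematode piRNA target recognition. The
penalty scheme (mismatch 1, wobble 0.5, seed doubling) follows the
TargetFinder family of plant/small-RNA target predictors; gapped alignment
is deliberately out of scope — the model is "precise, complementary
matching with a small mismatch budget".

## Free energy

Each site gets a duplex free energy from a nearest-neighbor model at
37 °C:

$$\Delta G = \Delta G_\mathrm{init} + \sum_{\text{stacks}} \Delta G_\mathrm{NN} + \sum_{\text{ends}} \Delta G_\mathrm{AU}$$

The bundled table holds the Turner 2004 RNA/RNA stacking free energies for
all Watson–Crick and G·U nearest-neighbor stacks (the Watson–Crick values
are the Xia et al. 1998 measurements at 0.1 kcal/mol resolution), the
duplex initiation penalty (+4.09 kcal/mol) and the terminal AU/GU penalty
(+0.45 kcal/mol per end). Two modelling simplifications are intentional
and conservative:

* **Mismatches break stacks.** No stacking energy is counted across a
  mismatched position and mismatches contribute no stabilisation; full
  internal-loop models would often assign favourable terms to single
  mismatches, so our $\Delta G$ is an upper (less stable) bound near
  mismatches.
* **No intramolecular structure.** Target accessibility (mRNA folding) is
  not modelled.

Sites are retained when $\Delta G$ is **strictly** below −20 kcal/mol; a
site at exactly −20 is dropped. For network edges an optional empirical
p-value is available: the percentile of the observed $\Delta G$ among
`n_shuffle = 100` dinucleotide-preserving shuffles of the piRNA scored
against the same site. This construction is the package's own (a
free-energy edge threshold accompanied by an unspecified "p < 0.05" occurs
in the literature this pipeline emulates, with no stated test), and it is
documented as such.

# Enrichment and network

Per term, enrichment of a foreground gene set against an annotated
background uses Fisher's exact test on
$[[k, n-k], [K-k, N-n-(K-k)]]$, two-sided by default (matching R's
`fisher.test`, which the relevant literature cites), with a one-sided
over-representation option. The **rich factor** is $k/K$: foreground genes
in the term over background genes in the term. The background defaults to
all annotated genes of the transcript set, not merely all targets.

The regulatory network is the bipartite graph of the filtered
(piRNA, mRNA) pairs, deduplicated so an mRNA counts once per piRNA. Degree
tables and a hub ranking (piRNAs by target count) are computed, and
pathway subnetworks are induced subgraphs on a pathway's genes plus their
piRNA neighbours. Graphs are emitted as GraphML/SIF/TSV for Cytoscape-style
viewers; layout and rendering are out of scope.

# The synthetic-data generator

`simulate_world()` emulates the study design the pipeline targets: three
developmental groups (Ac4/Ac5/Ac6) × three replicate libraries. Its
defaults are fixed once and are the package's study conditions:

| parameter | default | rationale |
|---|---|---|
| genome | 50 kb, 2 scaffolds | large enough for ~300 unique loci, small enough for sub-minute tests |
| piRNA loci | 300 (10/group group-specific) | a few hundred piRNAs is the catalogue size such studies report |
| length distribution | unimodal over 24–33, mode 27–28 | insect piRNA size profiles |
| first-base bias | C with probability 0.5 | the C bias reported for honeybee larval gut piRNAs |
| contaminants | 8 loci × 6 biotypes, 3 reads each | exercises every cascade branch |
| library size | 50,000 reads/sample | keeps Poisson noise realistic at ~100 reads/tag |
| DE fraction | 0.1 at \|log2FC\| = 2 | 4-fold planted effects, split over the two consecutive comparisons |
| replicate noise | lognormal, CV = 0.2 | typical replicate variability for bulk sRNA libraries |
| transcripts | 40 × 0.6–1.5 kb | enough targets for network structure in seconds |
| planted sites | 2 per DE piRNA, 0 mismatches | guarantees recoverable truth below the ΔG cutoff |

Counts are drawn as Poisson around lognormal-noise-scaled group means, with
group-specific piRNAs zeroed outside their group and planted fold changes
applied as a step from the affected group onward (so an effect planted
between Ac4 and Ac5 does not create a spurious opposite effect between Ac5
and Ac6). Reads are exact copies of their planted loci, so exact mapping
recovers them; short (18–23 nt) background reads and twice-planted
multimapper reads exercise the length window and the unique-position rule.
The generator audits its own loci after genome assembly: a planted piRNA
whose sequence happens to occur elsewhere is recorded as non-unique in the
truth table rather than silently assumed unique.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: sequencing errors and adapter artifacts,
quality trimming (inputs are "clean tags" by construction), genomic repeat
structure and piRNA clusters, ping-pong biogenesis signatures, isoform
structure in transcripts, and database-version effects in annotation. The
planted world is deliberately easy in exactly the ways that make the
pipeline's correctness checkable: sensitivities of 1.0 on it validate the
implementation, not the biology of any particular data set.

`simulate_counts()` exposes the count model alone (no genome) for studying
the screen's operating characteristics at scale: with 1000 null piRNAs the
screen's false-positive rate sits well under the nominal 5% (the fold-change
condition makes the compound rule conservative), and 4-fold planted effects
at CV 0.2 with three replicates are recovered at roughly 90% — the residual
misses are low-abundance rows where three-replicate t tests are underpowered,
a behaviour shared with any replicate-based screen at this design size.

# Numerical choices and edge cases

* Genome index: exact hash of all plus-strand k-mers (k = 12 by default,
  half the shortest piRNA); queries verify candidates by direct substring
  comparison, so hits are exact. Mismatched mapping uses pigeonhole
  seeding over `max_mismatches + 1` disjoint chunks and needs query length
  ≥ `(max_mismatches + 1) × k`.
* Coordinates are 1-based inclusive throughout, matching GFF3; minus-strand
  hits are reported at the plus-strand coordinates of the matching slice.
* Sequences are stored as DNA (T); RNA semantics (U, G·U wobbles) apply at
  the scanning boundary.
* Collapsed-FASTA counts use the common `id_xCOUNT` header dialect; a
  missing suffix degrades to count 1 with a warning rather than an error,
  since single-read headers are common in hand-built files.
* Ties in the first-base argmax are reported as ties; the length histogram
  includes empty lengths as zeros so it always spans the window.
* `fisher.test` is the implementation; the test suite checks it against an
  exhaustive hypergeometric summation written with `choose()` directly.
* Problem sizes in the test suite (50 kb world, 1000-row null screens,
  20-instance scanner sweeps) were chosen so the whole suite runs in about
  a minute; they are the package's standard validation sizes.

# Known limitations

* Exact (0-mismatch) genome mapping is the default; the mismatch-tolerant
  mode is Hamming-distance only (no indels).
* The duplex model ignores internal-loop stabilisation and target-site
  accessibility; absolute ΔG values are conservative near mismatches.
* The empirical edge p-value is a package construction, not a published
  test; treat it as a ranking device.
* Headline catalogue counts from any real study (numbers of piRNAs, of
  DE piRNAs, of targets) depend on sequencing depth, genome assembly and
  annotation versions, and are not reproduction targets of the synthetic
  validation.
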