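---
title: "Mapping endoribonuclease cleavage with dual RNA-seq libraries"
author: "cleavemap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping endoribonuclease cleavage with dual RNA-seq libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleavemap)
```

## The measurement problem

Bacterial toxin–antitoxin systems frequently encode endoribonuclease toxins
that arrest growth by cleaving cellular RNA. Characterizing such a nuclease
means answering four questions at once: *where* on the transcriptome it
cuts (at single-nucleotide resolution), *how much* each site is cut, *what
sequence and positional preferences* drive the cutting, and *which genes*
are most affected. cleavemap implements a dual-library strategy for these
questions:

* an **unfragmented 5′-end library** sequences only molecules with a free
  5′ end, mapping the exact first nucleotide of each cleavage product;
* a **fragmented coverage library** fragments the RNA before library
  preparation, so read density reports how much intact RNA spans each
  position.

Each library is sequenced for a toxin-induction sample and an empty-vector
control. Two per-nucleotide, per-strand ratio tracks summarize them:

* the **cleavage ratio** `log2((t + eps) / (v + eps))` of depth-normalized
  fragmented coverage (toxin `t`, vector `v`). Cleavage and subsequent decay
  carve *valleys* (negative values) into a transcript's profile, while
  expression changes move the whole profile up or down;
* the **5′-end ratio** `(t + eps) / (v + eps)` of depth-normalized 5′-end
  counts, on a linear scale. A cleavage event creates a new 5′ end, so a cut
  position shows a sharp peak over the vector control.

## From ratios to called sites

A position `p` on strand `s` is called a cleavage site when three criteria
hold simultaneously (`callSites()`):

1. 5′-end ratio at `p` of at least **32** — strong evidence of a new 5′ end;
2. mean cleavage ratio of at most **−1** (a two-fold density drop) over the
   **10** nucleotides transcript-upstream of `p`, with every window position
   defined — evidence that material upstream of the putative cut was lost;
3. raw vector-control coverage of at least **64** reads at `p` and across
   the window — an expression gate ensuring the ratios are measurable.

"Upstream" is always transcript orientation (`p-10 … p-1` on `+`,
`p+1 … p+10` on `-`), and the reported position is the first nucleotide of
the downstream cleavage product. The upstream criterion uses the window
*mean* by default; `aggregate = "min"` is available, and
`requireLocalMax = TRUE` switches from threshold semantics (every passing
position is a site) to peak semantics (only local maxima of the 5′-end
ratio within ±2 nt). Threshold semantics is the default because site counts
under it match the set of positions with self-contained evidence; the flag
exists because "peak" language is sometimes taken to mean strict local
maxima.

All thresholds are inclusive and exposed as arguments. Raising any of them
can only remove sites (a property the test suite checks on a grid). The
related Fig-S3-style *candidate classification* (`classifyCandidates()`)
uses a relaxed 5′-end-ratio threshold of 10 and the cleavage ratio at the
candidate position itself, and removes expression-failing candidates from
the candidate set instead of labeling them uncleaved.

## Specificity summaries

* **Motif** (`extractFlanks()`, `buildMotif()`): flanking windows of 8 nt on
  each side of the cut are stacked; per-column information content is
  `I_k = 2 + sum_b p_kb log2 p_kb` bits against a uniform background with
  `0·log 0 = 0`, and columns with `I_k >= 0.05` bits form the trimmed motif.
  No pseudocount and no small-sample correction are applied: the trimming
  floor is tiny and a correction would itself shift which columns survive,
  so the plain plug-in estimator is used and documented. Motifs are kept in
  the DNA alphabet internally; `motifConsensus(x, rna = TRUE)` renders U.
* **Subcodon preference** (`subcodonDistribution()`): each CDS site is
  classified by the codon position of the nucleotide immediately downstream
  of the cut — class c means "cleavage before codon position c", computed
  from the annotated frame anchor, strand-aware. Sites outside any CDS, or
  in overlapping CDS with disagreeing frames, are excluded and counted
  rather than guessed.
* **Positional density** (`positionalDensity()`): CDS sites are mapped to
  relative coordinate `x = offset / length` and binned over [0, 1] into a
  density integrating to 1. Ribosome-dependent nucleases show density
  decreasing 5′→3′. Choose the bin count so bins average ≥ ~10 sites; the
  package default is 20 for large site sets and the acceptance analyses use
  10.

## Normalization

Size factors are *total mapped counts / 1e6* (counts per million), not
median-of-ratios: cleavage suppresses a large fraction of all genes, so a
median-of-ratios scheme would absorb the effect being measured. Totals can
exclude annotated rRNA loci (`excludeRrna = TRUE`) for rRNA-depleted
samples; for non-depleted samples the rRNA mass stays in the total, where it
acts as a stable anchor — mature rRNA is not cleaved by these toxins, so its
mass calibrates the scale against which mRNA loss is measured. Replicates
are combined at the *ratio* level by the geometric mean (arithmetic mean of
log2 values for the cleavage ratio), never by pooling counts, so a
deep replicate cannot dominate. The ratio pseudocount defaults to 0.25
normalized counts: small enough not to perturb positions with real signal,
large enough to keep ratios finite at vector-zero positions; cleavage
ratios are additionally masked where the vector sample has fewer than 1
normalized count, because a ratio against nothing is noise.

## The simulator: what it emulates and what it does not

`simulateExperiment()` provides ground-truthed inputs in the exact on-disk
formats the pipeline consumes. The generative model:

1. **Reference** (`makeReference()`): a random genome (GC 0.5 by default)
   with 200 non-overlapping genes on alternating strands — 92% CDS (300 to
   1500 nt, codon multiples), 5% tRNA (76 nt), 3% rRNA (1500 nt). Transcript
   abundances are log-normal (sigma 1.5 log2 units, spanning roughly three
   decades as bacterial transcriptomes do), with rRNA boosted 20-fold so
   that stable RNA carries roughly half the sampled mass, as in
   non-depleted libraries. Abundance is drawn **once per reference**: it is
   a property of the strain, so toxin and vector samples share it and
   ratios carry no gene-level expression offsets.
2. **Cleavable sites** (`toxinActiveSites()`): all motif occurrences on
   mRNA-like transcripts (CDS and `other`; mature tRNA/rRNA are spared, as
   observed for these toxins). For ribosome-dependent nucleases only CDS
   transcripts are attacked and each occurrence is *active* with probability
   `w_class * exp(-x / lambda)`, where `w_class` is 1 for the favored
   subcodon class and `((1-beta)/2)/beta` otherwise and x is the relative
   CDS coordinate. Activity is a property of toxin × transcript (ribosome
   statistics at that codon), so the active set is drawn once per
   experiment and shared across conditions and replicates. With this
   site-level formulation the realized cuts hit the favored class with
   expected fraction beta and decay 5′→3′ at scale lambda, while every
   active site is cut at full efficiency — so the planted beta and lambda
   remain recoverable after threshold-based site calling. (Folding the
   biases into the per-molecule cut probability instead would make
   disfavored sites weakly cut and systematically uncallable, biasing the
   recovered fractions.)
3. **Molecules** (`simulateMolecules()`): per gene a Poisson number of
   full-length transcripts; each active site in each molecule is cut
   independently with probability `efficiency` (default 0.9); each cut
   splits the molecule, and the 5′-side product of every cut is degraded
   with probability `upstreamDecay` (default 0.9), emulating the observed
   instability of upstream cleavage products. An optional
   motif-independent `backgroundRate` adds housekeeping-RNase cuts (default
   0; their 5′ products decay with probability 0.5).
4. **Libraries** (`sampleLibrary()`): the unfragmented library samples
   surviving molecules uniformly, reading `min(readLen, length)` nt from
   each free 5′ end; the fragmented library breaks every molecule by a
   Poisson process with mean spacing 100 nt (identical to exponential
   spacings), drops pieces under 15 nt as unmappable, and samples pieces
   uniformly. Fragment counts are Poisson at the target depth (default
   5e5 per library).

The simulator reproduces the features the analyses rely on — motif-directed
cleavage, 5′-product decay, abundance variation, ribosome-dependent biases,
the two sampling processes — and deliberately omits sequencing error,
alignment ambiguity, operonic co-transcription, GC/positional sampling
bias, and secondary-structure protection of specific sites. Tests that pass
on simulated data therefore validate the *inference machinery*, not the
upstream alignment or any claim that real libraries are bias-free.

## Recovery performance under the default study conditions

At the default conditions (200 genes, two replicates, 5e5 fragments per
library, efficiency 0.9, decay 0.9, motif ACA), the test suite and
`scripts/acceptance.R` recompute: site recall ≥ 0.9 and precision ≥ 0.95
against the expression-gated planted truth; exact recovery of the trimmed
ACA motif; the planted subcodon fraction within ±0.05 (measured in a run
with positional thinning disabled, which isolates the subcodon parameter
and yields ~650 classified sites instead of ~150); and a monotone-decreasing
metagene for lambda = 0.2. Positional estimates need many sites and the 5′
thinning leaves only about one active site per gene, so the metagene run
uses a four-fold larger experiment (800 genes, 2e6 fragments per library).
A vector-vs-vector run calls zero sites. The numbers printed in the README
were produced by these scripts.

## Permutation overlap test

For two toxins sharing candidate motif positions, `permutationOverlap()`
tests whether the number of candidates cleaved by *both* exceeds chance by
permuting the cleaved/uncleaved labels (permuting one vector is equivalent
to permuting both independently and is how it is implemented). The p-value
uses the add-one estimator `(1 + #{perm both >= observed}) / (nPerm + 1)`,
which can never return zero. Because this null is exactly
Hypergeometric(n, a, b), the analytic tail probability is reported
alongside (`p_hyper`); the permutation machinery is retained because it
generalizes to statistics without a closed form, and its distributional
correctness is verified against exact enumeration in the test suite.

## Numerical and degenerate-input conventions

* Coordinates are 1-based closed (the Bioconductor convention) everywhere in
  memory; BED and bedGraph are converted at the I/O boundary, GFF3 is
  native. A fragment's transcript 5′ end is `start` on `+` and `end` on `-`.
* Masked profile positions carry `NA`, propagate through ratios and
  replicate combination (a position masked in any replicate is masked in
  the combination), and are excluded from every statistic.
* Gene-level "cleaved" uses a strict `min_cr < -1`, while the site-calling
  criterion is `<= -1`; the two thresholds are deliberately kept distinct.
* Motif occurrence counts are overlapping (the conservative superset).
* Top-peak ties break by lower coordinate, then `+` strand.
* Genes partially masked in a ratio track are summarized over their
  unmasked positions with the unmasked fraction recorded, rather than
  dropped.
* Single-chromosome genomes only; multi-record FASTA is an error rather
  than a silent concatenation.

## Known limitations

* The expression gate uses one vector replicate's raw coverage (replicate 1
  in `runCleavagePipeline()`), mirroring a per-sample read-count gate; very
  borderline genes can differ between replicates.
* Multi-mapping policy is inherited from the aligned input: the toolkit
  consumes BED intervals and does not re-adjudicate ambiguous alignments.
* Site calling uses fixed evidence thresholds, not an error-rate-controlled
  statistical test; thresholds are exposed and monotone, but no FDR is
  attached.
* The subcodon panel excludes frame-conflicted sites from overlapping CDS
  and reports the excluded count; with heavily overlapping annotations the
  classified fraction can be small.
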