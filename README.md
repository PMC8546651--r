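# cleavemap

Single-nucleotide mapping and quantification of endoribonuclease cleavage
from dual RNA-seq libraries.

## The problem

Many bacterial toxin–antitoxin systems encode endoribonuclease toxins that
arrest growth by cutting cellular RNA. Characterizing one requires knowing
where it cuts, how strongly, and with what sequence, reading-frame, and
positional preferences. cleavemap implements a dual-library strategy for
strand-specific paired-end RNA-seq of a toxin-induction sample against an
empty-vector control:

* an **unfragmented 5′-end library** captures only RNAs with free 5′ ends,
  locating cleavage products at single-nucleotide resolution;
* a **fragmented coverage library** measures how much intact RNA spans each
  position, quantifying the extent of cleavage.

From depth-normalized per-nucleotide tracks the package computes, at every
genome position `i` on each strand,

* the **cleavage ratio** `CR_i = log2((t_i + ε) / (v_i + ε))` from
  fragmented coverage (toxin `t`, vector `v`; `ε = 0.25`), where cleavage
  carves valleys (`CR < 0`);
* the **5′-end ratio** `ER_i = (t_i + ε) / (v_i + ε)` from 5′-end counts,
  where a cut produces a sharp peak.

A position is called a **cleavage site** when `ER ≥ 32`, the mean `CR` over
the 10 transcript-upstream nucleotides is `≤ −1`, and the vector control has
`≥ 64` raw reads at the site and across that window. Called sites feed the
specificity analyses: the sequence motif with per-column information content
`I_k = 2 + Σ_b p_kb log2 p_kb` (bits; columns with `I_k ≥ 0.05` bits form
the trimmed motif), the subcodon preference (codon position of the
nucleotide downstream of each cut), the 5′→3′ positional density along
coding regions, per-gene summaries (minimum cleavage ratio, fraction of
expressed genes cleaved), and a permutation test of site overlap between two
nucleases against its exact hypergeometric null.

A generative simulator (`simulateExperiment()`) produces ground-truthed
inputs — genome, annotation, and both library types for both conditions in
FASTA/GFF3/BED6 — under a motif-directed Bernoulli cleavage model with
5′-product decay and optional ribosome-dependent subcodon/positional bias,
so every inference step can be validated against planted truth.

## Worked example

Simulate a MazF-like ribosome-independent nuclease (motif ACA, cut 5′ of
the first A, per-site cleavage probability 0.9, 5′-product decay 0.9) and
run the full pipeline:

```r
library(cleavemap)

ref <- makeReference(simConfig(seed = 11))
tox <- toxinModel("ACA", cutOffset = 0, efficiency = 0.9, upstreamDecay = 0.9)
sim <- simulateExperiment(ref, tox, nReplicates = 2, depth = 5e5, seed = 11)
res <- runCleavagePipeline(sim$samples, ref$genome, ref$annotation)

nrow(res$sites)
#> [1] 1723

motif <- buildMotif(extractFlanks(res$sites, ref$genome, flank = 8, pad = TRUE))
motif
#> MotifModel: 1723 sequences, width 16, cut 5' of column 9
#>   trimmed consensus (>= 0.05 bits): ACA

fractionBelow(res$geneTable, -1)
#> [1] 89.76378
```

1,723 positions pass all three evidence thresholds; stacking their flanking
sequences recovers the planted ACA motif exactly (the cut falls 5′ of
column 9, i.e. immediately before the motif), and ~90% of expressed genes
have at least one position more than 2-fold down — the hallmark of a
promiscuous mRNA interferase. Checking calls against the simulator's truth
log:

```r
truth <- paste(sim$truth$position, sim$truth$strand)
called <- paste(res$sites$position, res$sites$strand)
mean(called %in% truth)   # precision
#> [1] 1
```

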