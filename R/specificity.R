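#' @include AllClasses.R
NULL

#' Extract transcript-strand flanking windows around cleavage sites
#'
#' Returns, for each site, the `2 * flank` nucleotides centered on the cut in
#' transcript orientation: `flank` upstream and `flank` downstream of the
#' cut, so the cut always falls between window columns `flank` and
#' `flank + 1`. Minus-strand windows are reverse complemented. Sites too
#' close to a genome end are skipped with a warning (or returned as `NA`
#' when `pad = TRUE`).
#'
#' @param sites data.frame with `position` (first nucleotide of the
#'   downstream product) and `strand`.
#' @param genome a [Biostrings::DNAString].
#' @param flank window half-width in nt (default 8).
#' @param pad if `TRUE`, edge sites yield `NA` instead of being dropped,
#'   preserving row alignment with `sites`.
#' @return character vector of windows, all of length `2 * flank`; the
#'   number of edge-skipped sites is attached as `attr(, "skipped_edge")`.
#' @export
extractFlanks <- function(sites, genome, flank = 8L, pad = FALSE) {
  flank <- as.integer(flank)
  L <- length(genome)
  n <- nrow(sites)
  out <- rep(NA_character_, n)
  if (n) {
    p <- sites$position
    s <- sites$strand
    lo <- ifelse(s == "+", p - flank, p - flank + 1L)
    hi <- ifelse(s == "+", p + flank - 1L, p + flank)
    ok <- lo >= 1L & hi <= L
    if (any(ok)) {
      v <- Biostrings::Views(genome, start = lo[ok], end = hi[ok])
      seqs <- as.character(Biostrings::DNAStringSet(v))
      neg <- s[ok] == "-"
      if (any(neg))
        seqs[neg] <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[neg])))
      out[ok] <- seqs
    }
    skipped <- sum(!ok)
  } else skipped <- 0L
  if (!pad) {
    if (skipped) warning(skipped, " site(s) within ", flank,
                         " nt of a genome end skipped")
    out <- out[!is.na(out)]
  }
  attr(out, "skipped_edge") <- skipped
  out
}

#' Build a cleavage motif model from aligned flanking windows
#'
#' Column-wise base frequencies (no pseudocount) and per-column information
#' content `I_k = 2 + sum_b p_kb log2 p_kb` (bits, uniform background,
#' `0 * log 0 = 0`). Columns with at least `bitsThreshold` bits form the
#' trimmed span reported by [motifConsensus()]; the display threshold of
#' 0.05 bits discards flanking noise while keeping weakly informative motif
#' positions.
#'
#' @param seqs character vector of equal-length sequences over A,C,G,T.
#' @param cutIndex column index such that cleavage falls between columns
#'   `cutIndex - 1` and `cutIndex`; defaults to `width/2 + 1`, the
#'   convention of [extractFlanks()].
#' @param bitsThreshold trimming threshold in bits (default 0.05).
#' @return a [MotifModel-class].
#' @examples
#' m <- buildMotif(c("TACAG", "AACAT", "GACAC", "CACAA"), cutIndex = 2)
#' motifConsensus(m)
#' @export
buildMotif <- function(seqs, cutIndex = NULL, bitsThreshold = 0.05) {
  seqs <- as.character(seqs)
  seqs <- seqs[!is.na(seqs)]
  if (length(seqs) == 0L) stop("no sequences to build a motif from")
  W <- unique(nchar(seqs))
  if (length(W) != 1L) stop("sequences must all have the same length")
  if (is.null(cutIndex)) cutIndex <- W %/% 2L + 1L
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
  counts <- matrix(0L, nrow = 4L, ncol = W, dimnames = list(c("A", "C", "G", "T"), NULL))
  present <- intersect(rownames(cm), rownames(counts))
  counts[present, ] <- cm[present, , drop = FALSE]
  freqs <- sweep(counts, 2L, colSums(counts), "/")
  plogp <- ifelse(freqs > 0, freqs * log2(freqs), 0)
  info <- pmin(pmax(2 + colSums(plogp), 0), 2)
  new("MotifModel", counts = counts, frequencies = freqs, info = info,
      cutIndex = as.integer(cutIndex),
      trimmedSpan = which(info >= bitsThreshold),
      bitsThreshold = bitsThreshold, nSeqs = length(seqs))
}

#' Subcodon preference of cleavage sites within coding regions
#'
#' Classifies each site by the codon position (1-3) of the nucleotide
#' immediately downstream of the cut, using the annotated reading frame:
#' class c means "cleavage before codon position c". Sites outside any CDS,
#' or inside overlapping CDS whose frames disagree, are excluded and
#' counted.
#'
#' @param sites data.frame with `position` and `strand` (a `subcodon` column,
#'   e.g. from [callSites()], is reused if present).
#' @param annotation a [GenomeAnnotation-class] (needed unless `sites`
#'   carries `subcodon`).
#' @return list with `fractions` (named f1,f2,f3 summing to 1), `nSites`
#'   (classified sites) and `nExcluded`.
#' @export
subcodonDistribution <- function(sites, annotation = NULL) {
  cls <- if ("subcodon" %in% names(sites)) sites$subcodon
         else {
           if (is.null(annotation)) stop("annotation required to classify sites")
           .subcodon_class(sites, annotation)
         }
  ok <- !is.na(cls)
  counts <- tabulate(cls[ok], nbins = 3L)
  n <- sum(counts)
  fr <- if (n > 0) counts / n else rep(NA_real_, 3L)
  names(fr) <- paste0("f", 1:3)
  list(fractions = fr, nSites = n, nExcluded = sum(!ok))
}

#' 5'-to-3' positional density of cleavage sites across coding regions
#'
#' Maps each CDS site to the relative coordinate
#' `x = (transcript offset from the CDS 5' end) / (CDS length)` and returns
#' a histogram density over [0, 1] (integrating to 1). A 5' cleavage bias,
#' the signature of ribosome-dependent nucleases, shows as density
#' decreasing with x.
#'
#' @param sites data.frame with `position` and `strand`.
#' @param annotation a [GenomeAnnotation-class].
#' @param nBins number of equal-width bins over [0, 1] (default 20, >= 2).
#' @return list with `breaks` (length `nBins + 1`), `density` (per-bin,
#'   integrates to 1), `mids`, `x` (per-site relative coordinates), `nSites`
#'   and `nExcluded` (sites outside a unique CDS).
#' @export
positionalDensity <- function(sites, annotation, nBins = 20L) {
  nBins <- as.integer(nBins)
  if (nBins < 2L) stop("nBins must be at least 2")
  genes <- geneRecords(annotation)
  cds <- genes[mcols(genes)$biotype == "CDS"]
  n <- nrow(sites)
  x <- rep(NA_real_, n)
  if (n && length(cds)) {
    gr <- GenomicRanges::GRanges("genome",
                                 IRanges::IRanges(sites$position, width = 1L),
                                 strand = sites$strand)
    hits <- GenomicRanges::findOverlaps(gr, cds)
    qh <- S4Vectors::queryHits(hits)
    uniqueHit <- qh %in% names(which(table(qh) == 1L))
    qh1 <- qh[uniqueHit]; sh1 <- S4Vectors::subjectHits(hits)[uniqueHit]
    st <- GenomicRanges::start(cds)[sh1]; en <- GenomicRanges::end(cds)[sh1]
    strnd <- as.character(GenomicRanges::strand(cds))[sh1]
    p <- sites$position[qh1]
    off <- ifelse(strnd == "+", p - st, en - p)
    x[qh1] <- off / (en - st + 1L)
  }
  xs <- x[!is.na(x)]
  if (length(xs) == 0L) {
    warning("no CDS sites; empty positional density")
    return(list(breaks = seq(0, 1, length.out = nBins + 1L),
                density = rep(NA_real_, nBins),
                mids = NULL, x = xs, nSites = 0L, nExcluded = n))
  }
  h <- graphics::hist(xs, breaks = seq(0, 1, length.out = nBins + 1L),
                      plot = FALSE, right = FALSE, include.lowest = TRUE)
  list(breaks = h$breaks, density = h$density, mids = h$mids,
       x = xs, nSites = length(xs), nExcluded = sum(is.na(x)))
}
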