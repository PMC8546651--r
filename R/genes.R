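#' @include AllClasses.R
NULL

.gene_positions <- function(gene_gr, i) {
  GenomicRanges::start(gene_gr)[i]:GenomicRanges::end(gene_gr)[i]
}

#' Flag highly expressed genes from vector-control coverage
#'
#' A gene is expressed iff every position within it, on its strand, carries
#' at least `minReads` raw reads in the empty-vector control. The default 64
#' is the expression gate used throughout the site-level analyses; 256 is
#' the stricter gate used for cross-library comparisons of per-gene minima.
#'
#' @param vectorRawCoverage raw `coverage` [NucProfile-class] from the
#'   vector condition.
#' @param annotation a [GenomeAnnotation-class].
#' @param minReads expression threshold (inclusive; default 64).
#' @param biotype optional biotype filter (e.g. `"CDS"`, `"tRNA"`).
#' @return named logical vector over gene ids.
#' @export
expressedGenes <- function(vectorRawCoverage, annotation, minReads = 64,
                           biotype = NULL) {
  genes <- geneRecords(annotation)
  if (!is.null(biotype)) genes <- genes[mcols(genes)$biotype %in% biotype]
  plus <- profileValues(vectorRawCoverage, "+")
  minus <- profileValues(vectorRawCoverage, "-")
  strnd <- as.character(GenomicRanges::strand(genes))
  out <- vapply(seq_along(genes), function(i) {
    v <- if (strnd[i] == "+") plus else minus
    vv <- v[.gene_positions(genes, i)]
    !any(is.na(vv)) && all(vv >= minReads)
  }, logical(1))
  names(out) <- mcols(genes)$gene_id
  out
}

#' Per-gene minimum cleavage ratio
#'
#' The most negative cleavage-ratio value within each expressed gene, the
#' gene-level cleavage summary. Genes with masked in-gene positions are
#' summarized over the unmasked positions, with the unmasked fraction
#' recorded rather than the gene dropped.
#'
#' @param cr log2 cleavage-ratio [NucProfile-class].
#' @param annotation a [GenomeAnnotation-class].
#' @param expressed named logical from [expressedGenes()]; only `TRUE` genes
#'   get a minimum.
#' @return data.frame (one row per gene in `expressed`) with `gene_id`,
#'   `expressed`, `min_cr` (`NA` unless expressed and at least one unmasked
#'   position), `unmasked_fraction`, `n_positions`, `biotype`.
#' @export
minCleavageRatio <- function(cr, annotation, expressed) {
  genes <- geneRecords(annotation)
  idx <- match(names(expressed), mcols(genes)$gene_id)
  if (any(is.na(idx))) stop("expressed gene ids absent from the annotation")
  genes <- genes[idx]
  plus <- profileValues(cr, "+"); minus <- profileValues(cr, "-")
  strnd <- as.character(GenomicRanges::strand(genes))
  n <- length(genes)
  min_cr <- rep(NA_real_, n); unmasked <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!expressed[i]) next
    v <- (if (strnd[i] == "+") plus else minus)[.gene_positions(genes, i)]
    ok <- !is.na(v)
    unmasked[i] <- mean(ok)
    if (any(ok)) min_cr[i] <- min(v[ok])
  }
  data.frame(gene_id = names(expressed),
             expressed = unname(expressed),
             min_cr = min_cr,
             unmasked_fraction = unmasked,
             n_positions = GenomicRanges::width(genes),
             biotype = mcols(genes)$biotype,
             row.names = NULL)
}

#' Percentage of expressed genes cleaved below a threshold
#'
#' `100 * #(expressed genes with min_cr strictly below threshold) /
#' #(expressed genes)`. The default threshold of -1 corresponds to a
#' relative 2-fold drop in RNA abundance at the most cleaved position.
#'
#' @param geneTable data.frame from [minCleavageRatio()].
#' @param threshold log2 threshold (strict `<`; default -1).
#' @return percentage in [0, 100].
#' @export
fractionBelow <- function(geneTable, threshold = -1) {
  ex <- geneTable[geneTable$expressed & !is.na(geneTable$min_cr), , drop = FALSE]
  if (nrow(ex) == 0L) stop("no expressed genes with a defined minimum")
  100 * sum(ex$min_cr < threshold) / nrow(ex)
}

#' Count motif occurrences per gene on the transcript strand
#'
#' Overlapping occurrences are counted. Minus-strand genes are scanned on
#' the reverse complement of their genomic interval.
#'
#' @param genome a [Biostrings::DNAString].
#' @param annotation a [GenomeAnnotation-class].
#' @param motif string over A,C,G,T (length >= 1).
#' @param biotype optional biotype filter.
#' @return named integer vector of counts per gene id.
#' @export
motifHits <- function(genome, annotation, motif, biotype = NULL) {
  if (nchar(motif) < 1L || grepl("[^ACGT]", toupper(motif)))
    stop("motif must be a non-empty string over A,C,G,T")
  motif <- toupper(motif)
  genes <- geneRecords(annotation)
  if (!is.null(biotype)) genes <- genes[mcols(genes)$biotype %in% biotype]
  occ <- motifOccurrences(genome, annotation, motif, biotype = biotype)
  counts <- integer(length(genes))
  names(counts) <- mcols(genes)$gene_id
  if (nrow(occ)) {
    tab <- table(occ$gene_id)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Genomic positions of motif occurrences within genes
#'
#' Scans each gene's transcript-strand sequence for (overlapping) motif
#' matches and reports, per occurrence, the genomic coordinate of the motif
#' base at `cutOffset` — the first nucleotide of the downstream product if
#' the nuclease cuts 5' of that base.
#'
#' @inheritParams motifHits
#' @param cutOffset 0-based offset of the cut base within the motif.
#' @return data.frame with `gene_id`, `strand`, `transcript_offset` (1-based
#'   offset of the motif start within the transcript), `position` (genomic
#'   cut position) and `rel_pos` (relative transcript coordinate in [0, 1)).
#' @export
motifOccurrences <- function(genome, annotation, motif, cutOffset = 0L,
                             biotype = NULL) {
  motif <- toupper(motif)
  genes <- geneRecords(annotation)
  if (!is.null(biotype)) genes <- genes[mcols(genes)$biotype %in% biotype]
  strnd <- as.character(GenomicRanges::strand(genes))
  res <- vector("list", length(genes))
  pat <- Biostrings::DNAString(motif)
  for (i in seq_along(genes)) {
    st <- GenomicRanges::start(genes)[i]; en <- GenomicRanges::end(genes)[i]
    seq <- Biostrings::subseq(genome, st, en)
    if (strnd[i] == "-") seq <- Biostrings::reverseComplement(seq)
    m <- Biostrings::matchPattern(pat, seq)
    if (length(m) == 0L) next
    off <- BiocGenerics::start(m)            # transcript offset of motif start
    gl <- en - st + 1L
    pos <- if (strnd[i] == "+") st + off - 1L + cutOffset
           else en - off + 1L - cutOffset
    res[[i]] <- data.frame(gene_id = mcols(genes)$gene_id[i],
                           strand = strnd[i],
                           transcript_offset = off,
                           position = pos,
                           rel_pos = (off + cutOffset - 1L) / gl)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L)
    return(data.frame(gene_id = character(), strand = character(),
                      transcript_offset = integer(), position = integer(),
                      rel_pos = numeric()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Squared Pearson correlation of per-gene minima between two tables
#'
#' Compares gene-level minimum cleavage ratios from two library types (or
#' samples) over the genes expressed, with a defined minimum, in both.
#'
#' @param tableA,tableB data.frames from [minCleavageRatio()].
#' @return list with `r_squared`, `n_genes` and `gene_id` (the intersection
#'   used).
#' @export
compareMinima <- function(tableA, tableB) {
  a <- tableA[tableA$expressed & !is.na(tableA$min_cr), c("gene_id", "min_cr")]
  b <- tableB[tableB$expressed & !is.na(tableB$min_cr), c("gene_id", "min_cr")]
  shared <- intersect(a$gene_id, b$gene_id)
  if (length(shared) < 3L)
    stop("need at least 3 genes expressed in both tables; got ", length(shared))
  x <- a$min_cr[match(shared, a$gene_id)]
  y <- b$min_cr[match(shared, b$gene_id)]
  list(r_squared = stats::cor(x, y)^2, n_genes = length(shared),
       gene_id = shared)
}

#' Extract a profile slice in transcript orientation
#'
#' Values over a region reported 5' to 3' on the region's strand (reversed
#' for minus-strand regions), with the mask propagated as `NA`.
#'
#' @param profile a [NucProfile-class].
#' @param start,end 1-based closed genomic interval.
#' @param strand `"+"` or `"-"`.
#' @return numeric vector of length `end - start + 1`.
#' @export
regionProfile <- function(profile, start, end, strand = "+") {
  L <- genomeLength(profile)
  if (start < 1L || end > L || start > end)
    stop("region [", start, ", ", end, "] outside genome [1, ", L, "]")
  v <- profileValues(profile, strand)[start:end]
  if (strand == "-") v <- rev(v)
  v
}
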