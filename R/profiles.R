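#' @include AllClasses.R
NULL

.strand_split <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  list(plus = gr[s == "+"], minus = gr[s == "-"])
}

.coverage_vec <- function(gr, genomeLength) {
  if (length(gr) == 0L) return(numeric(genomeLength))
  cov <- IRanges::coverage(IRanges::IRanges(GenomicRanges::start(gr),
                                            GenomicRanges::end(gr)),
                           width = genomeLength)
  as.numeric(cov)
}

#' Per-nucleotide fragment coverage
#'
#' Adds one count at every position covered by each paired-end fragment
#' (both read extents and the gap between them), per strand. The column sum
#' equals the total fragment length.
#'
#' @param frags a [FragmentSet-class].
#' @param genomeLength genome length in nucleotides.
#' @return a raw-count [NucProfile-class] of kind `"coverage"`.
#' @export
fragmentCoverage <- function(frags, genomeLength) {
  gr <- fragments(frags)
  if (length(gr) && (any(GenomicRanges::start(gr) < 1L) ||
                     any(GenomicRanges::end(gr) > genomeLength)))
    stop("fragments extend outside [1, ", genomeLength, "]")
  ss <- .strand_split(gr)
  NucProfile(.coverage_vec(ss$plus, genomeLength),
             .coverage_vec(ss$minus, genomeLength),
             kind = "coverage")
}

#' Transcript 5'-end position of each fragment
#'
#' @param frags a [FragmentSet-class].
#' @return integer vector: `start` for `+` fragments, `end` for `-` fragments.
#' @export
fragment5pEnds <- function(frags) {
  gr <- fragments(frags)
  s <- as.character(GenomicRanges::strand(gr))
  ifelse(s == "+", GenomicRanges::start(gr), GenomicRanges::end(gr))
}

#' Per-nucleotide fragment 5'-end counts
#'
#' Adds one count at each fragment's transcript 5' end only (the position
#' read out by the unfragmented 5'-end library). The column sum equals the
#' number of fragments.
#'
#' @param frags a [FragmentSet-class]; a warning is raised if it is not from
#'   an unfragmented library.
#' @param genomeLength genome length in nucleotides.
#' @return a raw-count [NucProfile-class] of kind `"end5"`.
#' @export
end5Counts <- function(frags, genomeLength) {
  if (frags@library != "unfragmented")
    warning("5'-end counting is intended for the unfragmented library; got '",
            frags@library, "'")
  gr <- fragments(frags)
  if (length(gr) && (any(GenomicRanges::start(gr) < 1L) ||
                     any(GenomicRanges::end(gr) > genomeLength)))
    stop("fragments extend outside [1, ", genomeLength, "]")
  p5 <- fragment5pEnds(frags)
  s <- as.character(GenomicRanges::strand(gr))
  NucProfile(tabulate(p5[s == "+"], nbins = genomeLength),
             tabulate(p5[s == "-"], nbins = genomeLength),
             kind = "end5")
}

#' Depth-normalization size factor from total mapped counts
#'
#' The size factor is the total raw count over included positions (both
#' strands) divided by `scale` (counts per million by default). For samples
#' that were not rRNA-depleted, rRNA loci dominate the totals and are
#' excluded via the annotation's rRNA mask.
#'
#' @param raw a raw-count [NucProfile-class] (`coverage` or `end5`).
#' @param annotation a [GenomeAnnotation-class] (required when
#'   `excludeRrna = TRUE`).
#' @param excludeRrna exclude rRNA loci from the total.
#' @param scale target total (default 1e6).
#' @return positive scalar size factor.
#' @export
sizeFactor <- function(raw, annotation = NULL, excludeRrna = FALSE, scale = 1e6) {
  if (raw@normalized) stop("size factors are computed from raw counts")
  incl <- rep(TRUE, genomeLength(raw))
  if (excludeRrna) {
    if (is.null(annotation)) stop("annotation required to exclude rRNA regions")
    incl <- !rrnaMask(annotation)
  }
  total <- sum(raw@plus[incl & raw@plusMask], na.rm = TRUE) +
    sum(raw@minus[incl & raw@minusMask], na.rm = TRUE)
  if (total <= 0) stop("zero included counts; cannot compute a size factor")
  total / scale
}

#' Divide a raw-count profile by its size factor
#'
#' @param raw a raw-count [NucProfile-class].
#' @param factor positive scalar from [sizeFactor()].
#' @return the normalized profile (same kind, `normalized = TRUE`).
#' @export
normalizeProfile <- function(raw, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("size factor must be a positive scalar")
  NucProfile(raw@plus / factor, raw@minus / factor, kind = raw@kind,
             plusMask = raw@plusMask, minusMask = raw@minusMask,
             normalized = TRUE)
}

#' Combine replicate ratio profiles by geometric mean
#'
#' Linear-scale ratios (`end_ratio`) are combined by the geometric mean;
#' log2-scale ratios (`cleavage_ratio`) by the arithmetic mean of the log
#' values, which is the same quantity on the log scale. A position is masked
#' if it is masked in any replicate.
#'
#' @param profiles list of ratio-kind [NucProfile-class] objects of equal
#'   length and identical kind.
#' @return the combined [NucProfile-class].
#' @export
combineReplicates <- function(profiles) {
  if (length(profiles) == 0L) stop("no profiles to combine")
  kinds <- vapply(profiles, profileKind, character(1))
  if (length(unique(kinds)) != 1L) stop("profiles of mixed kinds: ",
                                        paste(unique(kinds), collapse = ", "))
  kind <- kinds[1L]
  if (!kind %in% c("cleavage_ratio", "end_ratio"))
    stop("replicates are combined at the ratio level; got kind '", kind, "'")
  Ls <- vapply(profiles, genomeLength, integer(1))
  if (length(unique(Ls)) != 1L) stop("profiles of unequal length")
  comb <- function(mat, masks, logScale) {
    mask <- Reduce(`&`, masks)
    if (logScale) {
      v <- rowMeans(mat)
    } else {
      # geometric mean; exact zeros stay zero
      v <- exp(rowMeans(log(mat)))
      anyZero <- apply(mat == 0, 1L, any)
      v[which(anyZero)] <- 0
    }
    v[!mask] <- NA_real_
    list(v = v, mask = mask)
  }
  logScale <- kind == "cleavage_ratio"
  p <- comb(do.call(cbind, lapply(profiles, slot, "plus")),
            lapply(profiles, slot, "plusMask"), logScale)
  m <- comb(do.call(cbind, lapply(profiles, slot, "minus")),
            lapply(profiles, slot, "minusMask"), logScale)
  NucProfile(p$v, m$v, kind = kind, plusMask = p$mask, minusMask = m$mask,
             normalized = TRUE)
}

.ratio_strand <- function(t, v, tm, vm, pseudocount, log2scale, minDefined) {
  mask <- tm & vm
  if (log2scale) mask <- mask & !is.na(v) & v >= minDefined
  num <- t + pseudocount
  den <- v + pseudocount
  mask <- mask & !is.na(den) & den > 0
  r <- num / den
  if (log2scale) r <- log2(r)
  r[!mask] <- NA_real_
  list(v = r, mask = mask)
}

#' Per-nucleotide log2 cleavage ratio
#'
#' `log2((toxin + pseudocount) / (vector + pseudocount))` from normalized
#' coverage profiles. Negative values mark positions cleaved or destabilized
#' after toxin induction. Positions where the vector-control normalized
#' coverage falls below `minDefined` are masked rather than reported.
#'
#' @param toxin,vector normalized `coverage` [NucProfile-class] objects.
#' @param pseudocount epsilon added to both numerator and denominator
#'   (normalized-count units; default 0.25).
#' @param minDefined minimum vector normalized coverage for the ratio to be
#'   defined (default 1).
#' @return a [NucProfile-class] of kind `"cleavage_ratio"` (log2 scale).
#' @export
cleavageRatio <- function(toxin, vector, pseudocount = 0.25, minDefined = 1) {
  .check_ratio_inputs(toxin, vector, "coverage")
  p <- .ratio_strand(toxin@plus, vector@plus, toxin@plusMask, vector@plusMask,
                     pseudocount, TRUE, minDefined)
  m <- .ratio_strand(toxin@minus, vector@minus, toxin@minusMask, vector@minusMask,
                     pseudocount, TRUE, minDefined)
  NucProfile(p$v, m$v, kind = "cleavage_ratio", plusMask = p$mask,
             minusMask = m$mask, normalized = TRUE)
}

#' Per-nucleotide linear 5'-end ratio
#'
#' `(toxin + pseudocount) / (vector + pseudocount)` from normalized 5'-end
#' count profiles, on a linear scale (the peak-calling thresholds 32 and
#' 1,000 are linear). Large values mark new RNA 5' ends created by cleavage.
#'
#' @param toxin,vector normalized `end5` [NucProfile-class] objects.
#' @param pseudocount epsilon (default 0.25); positions where
#'   `vector + pseudocount == 0` are masked.
#' @return a [NucProfile-class] of kind `"end_ratio"` (linear scale).
#' @export
endRatio <- function(toxin, vector, pseudocount = 0.25) {
  .check_ratio_inputs(toxin, vector, "end5")
  p <- .ratio_strand(toxin@plus, vector@plus, toxin@plusMask, vector@plusMask,
                     pseudocount, FALSE, 0)
  m <- .ratio_strand(toxin@minus, vector@minus, toxin@minusMask, vector@minusMask,
                     pseudocount, FALSE, 0)
  NucProfile(p$v, m$v, kind = "end_ratio", plusMask = p$mask,
             minusMask = m$mask, normalized = TRUE)
}

.check_ratio_inputs <- function(toxin, vector, kind) {
  if (profileKind(toxin) != kind || profileKind(vector) != kind)
    stop("both profiles must be of kind '", kind, "'")
  if (genomeLength(toxin) != genomeLength(vector))
    stop("profiles cover genomes of different length")
  if (!identical(toxin@normalized, vector@normalized))
    stop("mixing normalized and raw profiles in a ratio")
}
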