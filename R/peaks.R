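#' @include AllClasses.R
NULL

.upstream_window <- function(p, strand, w) {
  if (strand == "+") (p - w):(p - 1L) else (p + 1L):(p + w)
}

#' Call single-nucleotide cleavage sites
#'
#' A position p on strand s is called a cleavage site iff
#' (a) the 5'-end ratio at p is at least `minEndRatio` (default 32-fold),
#' (b) the mean log2 cleavage ratio over the `upstreamWindow` nucleotides
#' transcript-upstream of p is at most `maxUpstreamCr` (default -1, a 2-fold
#' drop in fragmented-library density), with every window position unmasked,
#' and (c) the raw vector-control coverage is at least `minExpression`
#' (default 64 reads) at p and at every window position. Sites whose window
#' would extend past a genome end are skipped and counted in the
#' `skipped_edge` attribute.
#'
#' "Upstream" always means transcript orientation: positions p-w..p-1 on the
#' plus strand, p+1..p+w on the minus strand. The emitted position is the
#' first nucleotide of the downstream cleavage product.
#'
#' @param endRatio linear 5'-end-ratio [NucProfile-class].
#' @param cleavageRatio log2 cleavage-ratio [NucProfile-class].
#' @param vectorRawCoverage raw vector-control coverage [NucProfile-class].
#' @param minEndRatio,maxUpstreamCr,minExpression,upstreamWindow thresholds
#'   (defaults 32, -1, 64, 10).
#' @param aggregate how to summarize the upstream cleavage ratio: `"mean"`
#'   (default) or `"min"`.
#' @param requireLocalMax if `TRUE`, only positions whose 5'-end ratio is a
#'   strict local maximum within `localMaxRadius` are kept (peak rather than
#'   threshold semantics; default `FALSE`: every passing position is a site).
#' @param localMaxRadius radius (nt) for `requireLocalMax` (default 2).
#' @param genome optional [Biostrings::DNAString]; adds `flank_seq`.
#' @param annotation optional [GenomeAnnotation-class]; adds `gene_id` and
#'   `subcodon`.
#' @param flank flank width for `flank_seq` (default 8).
#' @return data.frame with columns `position`, `strand`, `end_ratio`,
#'   `upstream_cr`, and (when genome/annotation given) `gene_id`, `subcodon`,
#'   `flank_seq`; sorted by (strand, position). The number of edge-skipped
#'   candidates is attached as `attr(, "skipped_edge")`.
#' @export
callSites <- function(endRatio, cleavageRatio, vectorRawCoverage,
                      minEndRatio = 32, maxUpstreamCr = -1,
                      minExpression = 64, upstreamWindow = 10L,
                      aggregate = c("mean", "min"),
                      requireLocalMax = FALSE, localMaxRadius = 2L,
                      genome = NULL, annotation = NULL, flank = 8L) {
  aggregate <- match.arg(aggregate)
  L <- genomeLength(endRatio)
  if (genomeLength(cleavageRatio) != L || genomeLength(vectorRawCoverage) != L)
    stop("profiles cover genomes of different length")
  if (profileKind(endRatio) != "end_ratio" ||
      profileKind(cleavageRatio) != "cleavage_ratio" ||
      profileKind(vectorRawCoverage) != "coverage")
    stop("expected end_ratio, cleavage_ratio and coverage profiles, in that order")
  w <- as.integer(upstreamWindow)
  skipped <- 0L
  res <- list()
  for (s in c("+", "-")) {
    er <- profileValues(endRatio, s)
    cr <- profileValues(cleavageRatio, s)
    vc <- profileValues(vectorRawCoverage, s)
    cand <- which(!is.na(er) & er >= minEndRatio)
    if (requireLocalMax && length(cand)) {
      keep <- vapply(cand, function(p) {
        lo <- max(1L, p - localMaxRadius); hi <- min(L, p + localMaxRadius)
        nb <- er[lo:hi]; nb[p - lo + 1L] <- -Inf
        er[p] > max(nb, na.rm = TRUE)
      }, logical(1))
      cand <- cand[keep]
    }
    if (length(cand) == 0L) next
    edge <- if (s == "+") cand - w < 1L else cand + w > L
    skipped <- skipped + sum(edge)
    cand <- cand[!edge]
    keep <- vapply(cand, function(p) {
      win <- .upstream_window(p, s, w)
      crw <- cr[win]
      if (any(is.na(crw))) return(FALSE)
      stat <- if (aggregate == "mean") mean(crw) else min(crw)
      if (stat > maxUpstreamCr) return(FALSE)
      vcw <- vc[c(win, p)]
      !any(is.na(vcw)) && all(vcw >= minExpression)
    }, logical(1))
    cand <- cand[keep]
    if (length(cand)) {
      ucr <- vapply(cand, function(p) {
        crw <- cr[.upstream_window(p, s, w)]
        if (aggregate == "mean") mean(crw) else min(crw)
      }, numeric(1))
      res[[s]] <- data.frame(position = cand, strand = s,
                             end_ratio = er[cand], upstream_cr = ucr)
    }
  }
  sites <- if (length(res)) do.call(rbind, res) else
    data.frame(position = integer(), strand = character(),
               end_ratio = numeric(), upstream_cr = numeric())
  sites <- sites[order(match(sites$strand, c("+", "-")), sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  if (!is.null(annotation)) sites <- annotateSites(sites, annotation)
  if (!is.null(genome)) {
    fl <- extractFlanks(sites, genome, flank = flank, pad = TRUE)
    sites$flank_seq <- fl
  }
  attr(sites, "skipped_edge") <- skipped
  sites
}

#' Attach gene context and subcodon class to sites
#'
#' Each site is assigned the strand-matched gene containing its position
#' (`NA` if none; the first by coordinate if several overlap). The subcodon
#' class is the codon position of the nucleotide immediately downstream of
#' the cut, from the annotated reading frame; it is `NA` for sites outside a
#' CDS or in overlapping CDS with conflicting frames.
#'
#' @param sites data.frame with `position` and `strand`.
#' @param annotation a [GenomeAnnotation-class].
#' @return `sites` with `gene_id` and `subcodon` columns added.
#' @export
annotateSites <- function(sites, annotation) {
  genes <- geneRecords(annotation)
  n <- nrow(sites)
  gene_id <- rep(NA_character_, n)
  subcodon <- rep(NA_integer_, n)
  if (n) {
    gr <- GenomicRanges::GRanges("genome",
                                 IRanges::IRanges(sites$position, width = 1L),
                                 strand = sites$strand)
    hits <- GenomicRanges::findOverlaps(gr, genes)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    first <- !duplicated(qh)
    gene_id[qh[first]] <- mcols(genes)$gene_id[sh[first]]
    subcodon <- .subcodon_class(sites, annotation)
  }
  sites$gene_id <- gene_id
  sites$subcodon <- subcodon
  sites
}

.subcodon_class <- function(sites, annotation) {
  genes <- geneRecords(annotation)
  cds <- genes[mcols(genes)$biotype == "CDS"]
  n <- nrow(sites)
  cls <- rep(NA_integer_, n)
  if (n == 0L || length(cds) == 0L) return(cls)
  gr <- GenomicRanges::GRanges("genome",
                               IRanges::IRanges(sites$position, width = 1L),
                               strand = sites$strand)
  hits <- GenomicRanges::findOverlaps(gr, cds)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  anchors <- mcols(cds)$frame_anchor[sh]
  strands <- as.character(GenomicRanges::strand(cds))[sh]
  p <- sites$position[qh]
  c_raw <- ifelse(strands == "+",
                  ((p - anchors) %% 3) + 1L,
                  ((anchors - p) %% 3) + 1L)
  # a site in several CDS keeps its class only if all frames agree
  agg <- tapply(c_raw, qh, function(v) if (length(unique(v)) == 1L) v[1L] else NA_integer_)
  cls[as.integer(names(agg))] <- as.integer(agg)
  cls
}

#' Select top 5'-end-ratio peaks by threshold or rank
#'
#' Threshold mode returns every unmasked position with a value of at least
#' `threshold` (e.g. the >= 1,000 peak set); top-n mode returns the `n`
#' highest-value positions, ties broken by lower coordinate then plus strand
#' (e.g. the top 30 peaks within rRNA regions).
#'
#' @param endRatio a [NucProfile-class] (any kind; typically `end_ratio`).
#' @param threshold linear threshold (threshold mode).
#' @param n number of peaks (top-n mode). Exactly one of `threshold`/`n`
#'   must be given.
#' @param regionMask optional logical vector of genome length restricting the
#'   search (e.g. the annotation's [rrnaMask()]).
#' @return data.frame with `position`, `strand`, `value`, ordered by
#'   decreasing value (ties: coordinate, then `+` strand).
#' @export
topPeaks <- function(endRatio, threshold = NULL, n = NULL, regionMask = NULL) {
  if (is.null(threshold) == is.null(n))
    stop("give exactly one of 'threshold' or 'n'")
  L <- genomeLength(endRatio)
  if (!is.null(regionMask) && length(regionMask) != L)
    stop("regionMask must have genome length")
  rows <- list()
  for (s in c("+", "-")) {
    v <- profileValues(endRatio, s)
    ok <- !is.na(v)
    if (!is.null(regionMask)) ok <- ok & regionMask
    idx <- which(ok)
    if (length(idx))
      rows[[s]] <- data.frame(position = idx, strand = s, value = v[idx])
  }
  if (length(rows) == 0L)
    return(data.frame(position = integer(), strand = character(), value = numeric()))
  df <- do.call(rbind, rows)
  df <- df[order(-df$value, df$position, match(df$strand, c("+", "-"))), , drop = FALSE]
  if (!is.null(threshold)) {
    df <- df[df$value >= threshold, , drop = FALSE]
  } else {
    if (n > nrow(df)) {
      warning("requested ", n, " peaks but only ", nrow(df),
              " defined positions; returning all")
      n <- nrow(df)
    }
    df <- df[seq_len(n), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}
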