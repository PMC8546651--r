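#' @include AllClasses.R
NULL

#' Run the dual-library cleavage-mapping pipeline
#'
#' From per-sample fragment sets to called cleavage sites: raw per-nucleotide
#' coverage (fragmented libraries) and 5'-end counts (unfragmented
#' libraries), size-factor depth normalization, per-replicate log2 cleavage
#' ratios and linear 5'-end ratios (toxin vs matched vector replicate),
#' replicate combination by geometric mean, threshold-based site calling,
#' and the per-gene minimum cleavage-ratio table.
#'
#' @param samples nested list `samples[[condition]][[library]][[replicate]]`
#'   of [FragmentSet-class] objects, as returned in
#'   [simulateExperiment()]`$samples`; conditions `vector` and `toxin`,
#'   libraries `fragmented` and `unfragmented`, equal replicate counts.
#' @param genome a [Biostrings::DNAString].
#' @param annotation a [GenomeAnnotation-class].
#' @param excludeRrna exclude rRNA loci from size-factor totals (use for
#'   samples that were not rRNA-depleted).
#' @param pseudocount,minDefined ratio parameters (see [cleavageRatio()]).
#' @param minEndRatio,maxUpstreamCr,minExpression,upstreamWindow site-calling
#'   thresholds (see [callSites()]).
#' @param expressionThreshold gate for the per-gene summary (default 64).
#' @param flank flank width for site sequence windows.
#' @return list with `cleavageRatio`, `endRatio` (replicate-combined
#'   [NucProfile-class] tracks), `vectorRawCoverage` (replicate 1, the
#'   expression gate), `sizeFactors`, `sites` (from [callSites()]),
#'   `expressed`, and `geneTable` (from [minCleavageRatio()]).
#' @export
runCleavagePipeline <- function(samples, genome, annotation,
                                excludeRrna = FALSE,
                                pseudocount = 0.25, minDefined = 1,
                                minEndRatio = 32, maxUpstreamCr = -1,
                                minExpression = 64, upstreamWindow = 10L,
                                expressionThreshold = 64, flank = 8L) {
  L <- length(genome)
  nRep <- length(samples$vector$fragmented)
  stopifnot(nRep >= 1L,
            length(samples$toxin$fragmented) == nRep,
            length(samples$vector$unfragmented) == nRep,
            length(samples$toxin$unfragmented) == nRep)
  sizeFactors <- list()
  rawCov <- list(); normCov <- list(); normEnd5 <- list()
  for (cond in c("vector", "toxin")) {
    for (r in seq_len(nRep)) {
      cov <- fragmentCoverage(samples[[cond]]$fragmented[[r]], L)
      e5 <- end5Counts(samples[[cond]]$unfragmented[[r]], L)
      sfC <- sizeFactor(cov, annotation, excludeRrna = excludeRrna)
      sfE <- sizeFactor(e5, annotation, excludeRrna = excludeRrna)
      key <- paste(cond, r, sep = "_")
      sizeFactors[[paste0(key, "_coverage")]] <- sfC
      sizeFactors[[paste0(key, "_end5")]] <- sfE
      rawCov[[key]] <- cov
      normCov[[key]] <- normalizeProfile(cov, sfC)
      normEnd5[[key]] <- normalizeProfile(e5, sfE)
    }
  }
  crReps <- lapply(seq_len(nRep), function(r)
    cleavageRatio(normCov[[paste0("toxin_", r)]], normCov[[paste0("vector_", r)]],
                  pseudocount = pseudocount, minDefined = minDefined))
  erReps <- lapply(seq_len(nRep), function(r)
    endRatio(normEnd5[[paste0("toxin_", r)]], normEnd5[[paste0("vector_", r)]],
             pseudocount = pseudocount))
  cr <- combineReplicates(crReps)
  er <- combineReplicates(erReps)
  vecCov <- rawCov[["vector_1"]]
  sites <- callSites(er, cr, vecCov,
                     minEndRatio = minEndRatio, maxUpstreamCr = maxUpstreamCr,
                     minExpression = minExpression,
                     upstreamWindow = upstreamWindow,
                     genome = genome, annotation = annotation, flank = flank)
  expressed <- expressedGenes(vecCov, annotation, minReads = expressionThreshold)
  geneTable <- minCleavageRatio(cr, annotation, expressed)
  list(cleavageRatio = cr, endRatio = er, vectorRawCoverage = vecCov,
       sizeFactors = unlist(sizeFactors), sites = sites,
       expressed = expressed, geneTable = geneTable)
}
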