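#' @include AllClasses.R
NULL

#' Genome length of an object
#' @param x a cleavemap object.
#' @return integer(1), genome length in nucleotides.
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' Per-strand values of a profile
#' @param x a [NucProfile-class].
#' @param strand `"+"` or `"-"`.
#' @return numeric vector of genome length; masked positions are `NA`.
#' @export
setGeneric("profileValues", function(x, strand = "+") standardGeneric("profileValues"))

#' Per-strand validity mask of a profile
#' @inheritParams profileValues
#' @return logical vector; `TRUE` where the value is defined.
#' @export
setGeneric("profileMask", function(x, strand = "+") standardGeneric("profileMask"))

#' Track kind of a profile
#' @param x a [NucProfile-class].
#' @return one of `"coverage"`, `"end5"`, `"cleavage_ratio"`, `"end_ratio"`.
#' @export
setGeneric("profileKind", function(x) standardGeneric("profileKind"))

#' Gene records of an annotation
#' @param x a [GenomeAnnotation-class].
#' @return `GRanges` with mcols `gene_id`, `biotype`, `frame_anchor`.
#' @export
setGeneric("geneRecords", function(x) standardGeneric("geneRecords"))

#' Per-position rRNA mask of an annotation
#' @param x a [GenomeAnnotation-class].
#' @return logical vector of genome length.
#' @export
setGeneric("rrnaMask", function(x) standardGeneric("rrnaMask"))

#' Fragment intervals of a sample
#' @param x a [FragmentSet-class].
#' @return stranded `GRanges`.
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' Trimmed consensus of a motif model
#'
#' Majority base per column, restricted to the trimmed span (columns with at
#' least the model's bits threshold of information).
#'
#' @param x a [MotifModel-class].
#' @param rna report in the RNA alphabet (U for T).
#' @return character(1); empty string if no column passes the threshold.
#' @export
setGeneric("motifConsensus", function(x, rna = FALSE) standardGeneric("motifConsensus"))

#' @rdname genomeLength
#' @export
setMethod("genomeLength", "NucProfile", function(x) length(x@plus))
#' @rdname genomeLength
#' @export
setMethod("genomeLength", "GenomeAnnotation", function(x) x@genomeLength)

#' @rdname profileValues
#' @export
setMethod("profileValues", "NucProfile", function(x, strand = "+") {
  if (strand == "+") x@plus else x@minus
})

#' @rdname profileMask
#' @export
setMethod("profileMask", "NucProfile", function(x, strand = "+") {
  if (strand == "+") x@plusMask else x@minusMask
})

#' @rdname profileKind
#' @export
setMethod("profileKind", "NucProfile", function(x) x@kind)

#' @rdname geneRecords
#' @export
setMethod("geneRecords", "GenomeAnnotation", function(x) x@genes)

#' @rdname rrnaMask
#' @export
setMethod("rrnaMask", "GenomeAnnotation", function(x) x@rrnaMask)

#' @rdname fragments
#' @export
setMethod("fragments", "FragmentSet", function(x) x@fragments)

#' @rdname motifConsensus
#' @export
setMethod("motifConsensus", "MotifModel", function(x, rna = FALSE) {
  if (length(x@trimmedSpan) == 0L) return("")
  span <- min(x@trimmedSpan):max(x@trimmedSpan)
  bases <- rownames(x@counts)[apply(x@frequencies[, span, drop = FALSE], 2L, which.max)]
  out <- paste(bases, collapse = "")
  if (rna) out <- gsub("T", "U", out, fixed = TRUE)
  out
})

setMethod("show", "NucProfile", function(object) {
  n <- genomeLength(object)
  cat(sprintf("NucProfile [%s%s] over %d nt\n", object@kind,
              if (object@normalized) ", normalized" else "", n))
  cat(sprintf("  defined: + %d / %d, - %d / %d positions\n",
              sum(object@plusMask), n, sum(object@minusMask), n))
})

setMethod("show", "GenomeAnnotation", function(object) {
  bt <- table(factor(mcols(object@genes)$biotype,
                     levels = c("CDS", "tRNA", "rRNA", "other")))
  cat(sprintf("GenomeAnnotation: %d genes on %d nt (%s)\n",
              length(object@genes), object@genomeLength,
              paste(sprintf("%s=%d", names(bt), bt), collapse = ", ")))
})

setMethod("show", "FragmentSet", function(object) {
  cat(sprintf("FragmentSet '%s': %d fragments (%s, %s library, rep %d)\n",
              object@sampleId, length(object@fragments), object@condition,
              object@library, object@replicate))
})

setMethod("show", "MotifModel", function(object) {
  cat(sprintf("MotifModel: %d sequences, width %d, cut 5' of column %d\n",
              object@nSeqs, ncol(object@counts), object@cutIndex))
  cat(sprintf("  trimmed consensus (>= %.2f bits): %s\n",
              object@bitsThreshold, motifConsensus(object)))
})
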