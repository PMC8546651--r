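#' @import methods
#' @importFrom S4Vectors mcols mcols<-
NULL

.PROFILE_KINDS <- c("coverage", "end5", "cleavage_ratio", "end_ratio")

#' Per-nucleotide strand-specific track
#'
#' A `NucProfile` holds one numeric value per genome position on each strand,
#' together with a validity mask (`TRUE` = defined). Masked positions carry
#' `NA` and are excluded from every downstream statistic. The `kind` records
#' the stage of the track: raw or normalized `coverage` counts, raw or
#' normalized `end5` counts (fragment 5' ends), the log2 `cleavage_ratio`
#' (toxin over vector coverage), or the linear `end_ratio` (toxin over vector
#' 5'-end counts).
#'
#' @slot plus,minus numeric vectors of genome length (values per position).
#' @slot plusMask,minusMask logical vectors; `TRUE` where the value is defined.
#' @slot kind one of `"coverage"`, `"end5"`, `"cleavage_ratio"`, `"end_ratio"`.
#' @slot normalized logical; `TRUE` once depth-normalized (count kinds only).
#'
#' @export
setClass("NucProfile",
  representation(
    plus = "numeric", minus = "numeric",
    plusMask = "logical", minusMask = "logical",
    kind = "character", normalized = "logical"
  )
)

setValidity("NucProfile", function(object) {
  msg <- character()
  L <- length(object@plus)
  if (length(object@minus) != L) msg <- c(msg, "plus and minus strands differ in length")
  if (length(object@plusMask) != L || length(object@minusMask) != L)
    msg <- c(msg, "masks must have genome length")
  if (length(object@kind) != 1L || !object@kind %in% .PROFILE_KINDS)
    msg <- c(msg, sprintf("kind must be one of %s", paste(.PROFILE_KINDS, collapse = ", ")))
  if (length(object@normalized) != 1L) msg <- c(msg, "normalized must be a single logical")
  if (any(is.na(object@plus[object@plusMask])) || any(is.na(object@minus[object@minusMask])))
    msg <- c(msg, "unmasked positions must carry finite values, not NA")
  if (length(msg) == 0 && object@kind %in% c("coverage", "end5")) {
    if (any(object@plus[object@plusMask] < 0) || any(object@minus[object@minusMask] < 0))
      msg <- c(msg, "count profiles must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a NucProfile
#'
#' @param plus,minus numeric vectors of genome length. `NA` entries are masked.
#' @param kind track kind (see [NucProfile-class]).
#' @param plusMask,minusMask optional logical masks; default: non-`NA` entries.
#' @param normalized whether counts have been depth-normalized.
#' @return a [NucProfile-class] object.
#' @export
NucProfile <- function(plus, minus, kind,
                       plusMask = NULL, minusMask = NULL,
                       normalized = FALSE) {
  plus <- as.numeric(plus); minus <- as.numeric(minus)
  if (is.null(plusMask)) plusMask <- !is.na(plus)
  if (is.null(minusMask)) minusMask <- !is.na(minus)
  plus[!plusMask] <- NA_real_
  minus[!minusMask] <- NA_real_
  new("NucProfile", plus = plus, minus = minus,
      plusMask = plusMask, minusMask = minusMask,
      kind = kind, normalized = normalized)
}

#' Genome annotation: genes, biotypes, reading frames, rRNA mask
#'
#' Wraps a `GRanges` of gene records (metadata columns `gene_id`, `biotype`
#' in `{CDS, tRNA, rRNA, other}`, and for CDS `frame_anchor`: the genomic
#' 1-based coordinate of the first nucleotide of the first codon) plus a
#' per-position logical marking rRNA loci on either strand, used to exclude
#' rRNA from size-factor totals.
#'
#' @slot genes a `GRanges` with mcols `gene_id`, `biotype`, `frame_anchor`.
#' @slot rrnaMask logical vector of genome length.
#' @slot genomeLength integer(1).
#' @export
setClass("GenomeAnnotation",
  representation(genes = "GRanges", rrnaMask = "logical", genomeLength = "integer")
)

setValidity("GenomeAnnotation", function(object) {
  msg <- character()
  g <- object@genes
  L <- object@genomeLength
  need <- c("gene_id", "biotype", "frame_anchor")
  if (!all(need %in% colnames(mcols(g))))
    msg <- c(msg, "genes must carry mcols gene_id, biotype, frame_anchor")
  if (length(object@rrnaMask) != L) msg <- c(msg, "rrnaMask must have genome length")
  if (length(g)) {
    if (any(GenomicRanges::start(g) < 1L) || any(GenomicRanges::end(g) > L))
      msg <- c(msg, "gene coordinates outside genome")
    if (!all(as.character(GenomicRanges::strand(g)) %in% c("+", "-")))
      msg <- c(msg, "gene strand must be + or -")
    if (!all(mcols(g)$biotype %in% c("CDS", "tRNA", "rRNA", "other")))
      msg <- c(msg, "biotype must be CDS, tRNA, rRNA or other")
    cds <- mcols(g)$biotype == "CDS"
    fa <- mcols(g)$frame_anchor[cds]
    if (any(is.na(fa)))
      msg <- c(msg, "CDS genes must carry a frame_anchor")
    else if (any(fa < GenomicRanges::start(g)[cds] | fa > GenomicRanges::end(g)[cds]))
      msg <- c(msg, "frame_anchor must lie within its CDS")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeAnnotation
#'
#' @param genes `GRanges` with mcols `gene_id`, `biotype`, and `frame_anchor`
#'   (NA for non-CDS).
#' @param genomeLength genome length in nucleotides.
#' @return a [GenomeAnnotation-class]; the rRNA mask is derived from the
#'   `biotype == "rRNA"` genes (union over both strands).
#' @export
GenomeAnnotation <- function(genes, genomeLength) {
  genomeLength <- as.integer(genomeLength)
  mask <- logical(genomeLength)
  rr <- genes[mcols(genes)$biotype == "rRNA"]
  if (length(rr)) {
    for (i in seq_along(rr)) {
      mask[GenomicRanges::start(rr)[i]:GenomicRanges::end(rr)[i]] <- TRUE
    }
  }
  new("GenomeAnnotation", genes = genes, rrnaMask = mask,
      genomeLength = genomeLength)
}

#' One sample's aligned fragments plus library metadata
#'
#' @slot fragments `GRanges` of strand-aware fragment intervals (1-based
#'   closed, the Bioconductor convention; BED input is converted on read).
#' @slot sampleId text identifier.
#' @slot condition `"toxin"` or `"vector"`.
#' @slot library `"fragmented"` (coverage library) or `"unfragmented"`
#'   (5'-end library).
#' @slot replicate positive integer.
#' @export
setClass("FragmentSet",
  representation(fragments = "GRanges", sampleId = "character",
                 condition = "character", library = "character",
                 replicate = "integer")
)

setValidity("FragmentSet", function(object) {
  msg <- character()
  if (!object@condition %in% c("toxin", "vector"))
    msg <- c(msg, "condition must be 'toxin' or 'vector'")
  if (!object@library %in% c("fragmented", "unfragmented"))
    msg <- c(msg, "library must be 'fragmented' or 'unfragmented'")
  if (length(object@replicate) != 1L || is.na(object@replicate) || object@replicate < 1L)
    msg <- c(msg, "replicate must be a positive integer")
  s <- as.character(GenomicRanges::strand(object@fragments))
  if (length(s) && !all(s %in% c("+", "-")))
    msg <- c(msg, "fragments must be stranded (+ or -); library is strand-specific")
  if (length(msg)) msg else TRUE
})

#' Construct a FragmentSet
#'
#' @param fragments stranded `GRanges` (or a data.frame with `start`, `end`,
#'   `strand`, 1-based closed coordinates).
#' @param sampleId,condition,library,replicate sample metadata.
#' @return a [FragmentSet-class].
#' @export
FragmentSet <- function(fragments, sampleId = "sample",
                        condition = c("vector", "toxin"),
                        library = c("fragmented", "unfragmented"),
                        replicate = 1L) {
  condition <- match.arg(condition)
  library <- match.arg(library)
  if (is.data.frame(fragments)) {
    fragments <- GenomicRanges::GRanges(
      seqnames = "genome",
      ranges = IRanges::IRanges(start = fragments$start, end = fragments$end),
      strand = fragments$strand
    )
  }
  new("FragmentSet", fragments = fragments, sampleId = sampleId,
      condition = condition, library = library,
      replicate = as.integer(replicate))
}

#' Cleavage-site sequence motif with per-column information content
#'
#' Column-wise base counts and frequencies over aligned flanking windows, the
#' per-position information content I_k = 2 + sum_b p_kb log2 p_kb (bits,
#' uniform background, 0*log0 = 0), the cut index (cleavage falls 5' of
#' window column `cutIndex`), and the span of columns retaining at least
#' `bitsThreshold` bits.
#'
#' @slot counts 4 x W integer matrix (rows A,C,G,T).
#' @slot frequencies 4 x W numeric matrix; columns sum to 1.
#' @slot info numeric W; bits per column, in [0, 2].
#' @slot cutIndex integer(1); cleavage is between columns cutIndex-1 and cutIndex.
#' @slot trimmedSpan integer; indices of columns with info >= bitsThreshold.
#' @slot bitsThreshold numeric(1).
#' @slot nSeqs integer(1).
#' @export
setClass("MotifModel",
  representation(counts = "matrix", frequencies = "matrix", info = "numeric",
                 cutIndex = "integer", trimmedSpan = "integer",
                 bitsThreshold = "numeric", nSeqs = "integer")
)

setValidity("MotifModel", function(object) {
  msg <- character()
  if (!identical(rownames(object@counts), c("A", "C", "G", "T")))
    msg <- c(msg, "counts rows must be A,C,G,T")
  cs <- colSums(object@frequencies)
  if (any(abs(cs - 1) > 1e-9)) msg <- c(msg, "frequency columns must sum to 1")
  if (any(object@info < -1e-12 | object@info > 2 + 1e-12))
    msg <- c(msg, "information content must lie in [0, 2] bits")
  if (length(msg)) msg else TRUE
})

#' Generative description of an endoribonuclease toxin
#'
#' Parameters of the simulator's cleavage model: the recognition motif and
#' the cut position within it, the per-molecule per-site cleavage
#' probability, the decay probability of the 5'-side cleavage product, and
#' (for ribosome-dependent nucleases) the subcodon preference and the
#' 5'-to-3' positional decay scale.
#'
#' @slot motif DNA string over A,C,G,T.
#' @slot cutOffset 0-based index within the motif; cleavage falls 5' of that
#'   base (so `cutOffset = 0` cuts immediately before the motif).
#' @slot efficiency per-molecule, per-site Bernoulli cleavage probability q.
#' @slot upstreamDecay probability d that the 5'-side product of a cut is
#'   degraded before library sampling.
#' @slot ribosomeDependent logical; gates the two bias parameters below and
#'   restricts cleavage to CDS transcripts.
#' @slot subcodonBias beta in [1/3, 1]: expected fraction of realized cuts at
#'   the favored subcodon class.
#' @slot favoredSubcodon the favored class in {1, 2, 3}.
#' @slot positionalLambda decay scale of the 5' bias, in relative CDS
#'   coordinate units (site weight exp(-x/lambda)).
#' @slot backgroundRate per-nucleotide, per-molecule probability of a
#'   motif-independent background cut (housekeeping RNase stand-in); applies
#'   in both conditions.
#' @export
setClass("ToxinModel",
  representation(motif = "character", cutOffset = "integer",
                 efficiency = "numeric", upstreamDecay = "numeric",
                 ribosomeDependent = "logical", subcodonBias = "numeric",
                 favoredSubcodon = "integer", positionalLambda = "numeric",
                 backgroundRate = "numeric")
)

setValidity("ToxinModel", function(object) {
  msg <- character()
  if (nchar(object@motif) < 1L || grepl("[^ACGT]", object@motif))
    msg <- c(msg, "motif must be a non-empty string over A,C,G,T")
  if (object@cutOffset < 0L || object@cutOffset >= nchar(object@motif))
    msg <- c(msg, "cutOffset must index a motif base")
  for (p in c("efficiency", "upstreamDecay")) {
    v <- slot(object, p)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must be in [0, 1]", p))
  }
  if (object@subcodonBias < 1 / 3 - 1e-12 || object@subcodonBias > 1)
    msg <- c(msg, "subcodonBias must be in [1/3, 1]")
  if (!object@favoredSubcodon %in% 1:3)
    msg <- c(msg, "favoredSubcodon must be 1, 2 or 3")
  if (object@positionalLambda <= 0) msg <- c(msg, "positionalLambda must be positive")
  if (object@backgroundRate < 0 || object@backgroundRate > 1)
    msg <- c(msg, "backgroundRate must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a ToxinModel
#'
#' @param motif,cutOffset,efficiency,upstreamDecay,ribosomeDependent
#'   see [ToxinModel-class].
#' @param subcodonBias,favoredSubcodon,positionalLambda ribosome-dependence
#'   parameters (ignored when `ribosomeDependent = FALSE`).
#' @param backgroundRate motif-independent background cut rate.
#' @return a [ToxinModel-class].
#' @examples
#' mazf <- toxinModel("ACA", cutOffset = 0, efficiency = 0.9)
#' @export
toxinModel <- function(motif, cutOffset = 0L, efficiency = 0.9,
                       upstreamDecay = 0.9, ribosomeDependent = FALSE,
                       subcodonBias = 1 / 3, favoredSubcodon = 1L,
                       positionalLambda = 0.2, backgroundRate = 0) {
  new("ToxinModel", motif = toupper(motif), cutOffset = as.integer(cutOffset),
      efficiency = efficiency, upstreamDecay = upstreamDecay,
      ribosomeDependent = ribosomeDependent, subcodonBias = subcodonBias,
      favoredSubcodon = as.integer(favoredSubcodon),
      positionalLambda = positionalLambda, backgroundRate = backgroundRate)
}
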