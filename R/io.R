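#' @include AllClasses.R
NULL

#' Read a single-chromosome genome from FASTA
#'
#' The toolkit targets single-chromosome bacterial genomes; multi-record
#' FASTA files are rejected rather than concatenated. The sequence is
#' upper-cased and must contain only A, C, G, T (ambiguity codes such as N
#' are rejected with the offending position named).
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAString] with the record name attached as
#'   `names()`-style metadata (`attr(x, "genomeName")`).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g", "acgt"), fa)
#' as.character(readGenome(fa))
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequence records in ", path)
  if (length(seqs) > 1L)
    stop("multi-record FASTA not supported (", length(seqs),
         " records); single-chromosome genomes only")
  s <- toupper(as.character(seqs[[1L]]))
  if (nchar(s) == 0L) stop("empty genome sequence in ", path)
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0L)
    stop(sprintf("genome alphabet restricted to A/C/G/T: found '%s' at position %d",
                 substr(s, bad, bad), as.integer(bad)))
  g <- Biostrings::DNAString(s)
  attr(g, "genomeName") <- names(seqs)[1L]
  g
}

#' Write a genome to FASTA
#'
#' @param genome a [Biostrings::DNAString].
#' @param path output path.
#' @param name FASTA record name (defaults to the name stored at read time,
#'   or `"genome"`).
#' @return `path`, invisibly.
#' @export
writeGenome <- function(genome, path, name = NULL) {
  if (is.null(name)) name <- attr(genome, "genomeName")
  if (is.null(name)) name <- "genome"
  set <- Biostrings::DNAStringSet(genome)
  names(set) <- name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a GenomeAnnotation to GFF3
#'
#' Inverse of [readAnnotation()]: one feature per gene, typed by biotype,
#' with `ID` and `biotype` attributes; CDS features carry the phase implied
#' by their frame anchor.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param path output path.
#' @param chrom sequence name to write.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(annotation, path, chrom = "genome") {
  g <- geneRecords(annotation)
  md <- mcols(g)
  strnd <- as.character(GenomicRanges::strand(g))
  phase <- rep(NA_integer_, length(g))
  cds <- md$biotype == "CDS"
  phase[cds & strnd == "+"] <-
    md$frame_anchor[cds & strnd == "+"] - GenomicRanges::start(g)[cds & strnd == "+"]
  phase[cds & strnd == "-"] <-
    GenomicRanges::end(g)[cds & strnd == "-"] - md$frame_anchor[cds & strnd == "-"]
  out <- GenomicRanges::GRanges(chrom, IRanges::ranges(g), strand = strnd)
  mcols(out)$source <- "cleavemap"
  mcols(out)$type <- md$biotype
  mcols(out)$phase <- as.integer(phase)
  mcols(out)$ID <- md$gene_id
  mcols(out)$biotype <- md$biotype
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

.BIOTYPES <- c("CDS", "tRNA", "rRNA")

#' Read gene annotation from GFF3
#'
#' Coordinates stay in the GFF3/Bioconductor convention (1-based closed).
#' Each feature becomes one gene record; the biotype is taken from a
#' `biotype=` attribute when present, otherwise from the feature type if it
#' is one of CDS/tRNA/rRNA, otherwise `"other"` (with a warning). For CDS
#' records the frame anchor (genomic coordinate of the first nucleotide of
#' the first codon) is computed strand-aware from the feature's phase:
#' `start + phase` on `+`, `end - phase` on `-`. A CDS without a resolvable
#' phase is an error.
#'
#' @param path path to a GFF3 file.
#' @param genome the [Biostrings::DNAString] returned by [readGenome()]
#'   (used for bounds checking).
#' @return a [GenomeAnnotation-class].
#' @export
readAnnotation <- function(path, genome) {
  if (!file.exists(path)) stop("annotation GFF3 not found: ", path)
  gff <- rtracklayer::import(path, format = "gff3")
  L <- length(genome)
  if (length(gff) == 0L) stop("no features in ", path)
  if (any(GenomicRanges::start(gff) < 1L) || any(GenomicRanges::end(gff) > L))
    stop("annotation coordinates fall outside the genome [1, ", L, "]")
  md <- mcols(gff)
  type <- as.character(md$type)
  biotype <- if ("biotype" %in% colnames(md)) as.character(md$biotype) else rep(NA_character_, length(gff))
  miss <- is.na(biotype)
  biotype[miss] <- ifelse(type[miss] %in% .BIOTYPES, type[miss], NA_character_)
  unknown <- is.na(biotype) | !(biotype %in% c(.BIOTYPES, "other"))
  if (any(unknown)) {
    warning(sum(unknown), " feature(s) with unrecognized biotype mapped to 'other'")
    biotype[unknown] <- "other"
  }
  ids <- if ("ID" %in% colnames(md)) as.character(md$ID) else rep(NA_character_, length(gff))
  ids[is.na(ids)] <- paste0("gene", which(is.na(ids)))
  phase <- if ("phase" %in% colnames(md)) suppressWarnings(as.integer(md$phase)) else rep(NA_integer_, length(gff))
  strnd <- as.character(GenomicRanges::strand(gff))
  if (!all(strnd %in% c("+", "-")))
    stop("all annotated genes must be stranded (+ or -)")
  anchor <- rep(NA_real_, length(gff))
  is_cds <- biotype == "CDS"
  if (any(is_cds & is.na(phase)))
    stop("CDS feature(s) without resolvable phase: ",
         paste(ids[is_cds & is.na(phase)], collapse = ", "))
  plus <- is_cds & strnd == "+"
  minus <- is_cds & strnd == "-"
  anchor[plus] <- GenomicRanges::start(gff)[plus] + phase[plus]
  anchor[minus] <- GenomicRanges::end(gff)[minus] - phase[minus]
  genes <- GenomicRanges::GRanges(
    seqnames = "genome",
    ranges = IRanges::IRanges(GenomicRanges::start(gff), GenomicRanges::end(gff)),
    strand = strnd,
    gene_id = ids, biotype = biotype, frame_anchor = anchor
  )
  GenomeAnnotation(genes, genomeLength = L)
}

#' Read one sample's aligned fragments from BED6
#'
#' BED's 0-based half-open intervals are converted to the internal 1-based
#' closed convention on import (via rtracklayer). Every fragment must be
#' stranded: the libraries are strand-specific, so a `.` strand is an error,
#' reported with the offending record index.
#'
#' @param path path to a BED6 file.
#' @param sampleId,condition,library,replicate sample metadata (see
#'   [FragmentSet-class]).
#' @param genomeLength optional; when supplied, fragments outside
#'   `[1, genomeLength]` are an error.
#' @return a [FragmentSet-class]; fragment order is preserved.
#' @export
readFragments <- function(path, sampleId = basename(path),
                          condition = c("vector", "toxin"),
                          library = c("fragmented", "unfragmented"),
                          replicate = 1L, genomeLength = NULL) {
  condition <- match.arg(condition)
  library <- match.arg(library)
  if (!file.exists(path)) stop("fragment BED not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("malformed BED6 in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  s <- as.character(GenomicRanges::strand(gr))
  bad <- which(!s %in% c("+", "-"))
  if (length(bad))
    stop("unstranded fragment(s) at record ", paste(utils::head(bad, 5L), collapse = ", "),
         " in ", path, "; the library is strand-specific")
  zw <- which(GenomicRanges::width(gr) < 1L)
  if (length(zw))
    stop("fragment with end <= start at record ", zw[1L], " in ", path)
  if (!is.null(genomeLength)) {
    oob <- which(GenomicRanges::start(gr) < 1L | GenomicRanges::end(gr) > genomeLength)
    if (length(oob))
      stop("fragment outside genome at record ", oob[1L], " in ", path)
  }
  FragmentSet(GenomicRanges::granges(gr), sampleId = sampleId,
              condition = condition, library = library, replicate = replicate)
}

#' Write a FragmentSet as BED6
#'
#' @param frags a [FragmentSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFragments <- function(frags, path) {
  gr <- fragments(frags)
  mcols(gr)$name <- paste0("f", seq_along(gr))
  mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write a profile as a pair of strand-suffixed bedGraph files
#'
#' Runs of equal value are collapsed into single intervals; masked positions
#' are always omitted, zeros are omitted by default. Output coordinates are
#' bedGraph-native (0-based half-open).
#'
#' @param profile a [NucProfile-class].
#' @param prefix output prefix; files `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph` are written.
#' @param omitZeros drop zero-valued runs (default `TRUE`).
#' @param chrom chromosome name to write.
#' @return named character vector of the two paths, invisibly.
#' @export
writeProfile <- function(profile, prefix, omitZeros = TRUE, chrom = "genome") {
  paths <- c(plus = paste0(prefix, ".plus.bedgraph"),
             minus = paste0(prefix, ".minus.bedgraph"))
  for (s in c("plus", "minus")) {
    v <- profileValues(profile, if (s == "plus") "+" else "-")
    r <- rle(ifelse(is.na(v), NA_real_, v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- !is.na(r$values)
    if (omitZeros) keep <- keep & r$values != 0
    df <- data.frame(chrom = rep(chrom, sum(keep)),
                     start = starts[keep] - 1L,  # bedGraph is 0-based half-open
                     end = ends[keep],
                     value = r$values[keep])
    con <- file(paths[[s]], "w")
    writeLines(sprintf("track type=bedGraph name=\"%s.%s\"", basename(prefix), s), con)
    if (nrow(df))
      utils::write.table(format(df, scientific = FALSE, trim = TRUE), con,
                         sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    close(con)
  }
  invisible(paths)
}

#' Read a strand-suffixed bedGraph pair back into a profile
#'
#' @param prefix prefix used in [writeProfile()].
#' @param genomeLength genome length in nucleotides.
#' @param kind track kind of the profile being read.
#' @param missing how to treat positions absent from the file: `"zero"`
#'   (count tracks written with zeros omitted) or `"mask"` (ratio tracks,
#'   where absent means undefined).
#' @return a [NucProfile-class].
#' @export
readProfile <- function(prefix, genomeLength, kind = "coverage",
                        missing = c("zero", "mask")) {
  missing <- match.arg(missing)
  fill <- if (missing == "zero") 0 else NA_real_
  out <- list()
  for (s in c("plus", "minus")) {
    path <- paste0(prefix, ".", s, ".bedgraph")
    if (!file.exists(path)) stop("bedGraph not found: ", path)
    gr <- rtracklayer::import(path, format = "bedGraph")
    v <- rep(fill, genomeLength)
    if (length(gr)) {
      st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
      sc <- mcols(gr)$score
      for (i in seq_along(gr)) v[st[i]:en[i]] <- sc[i]
    }
    out[[s]] <- v
  }
  NucProfile(out$plus, out$minus, kind = kind)
}
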