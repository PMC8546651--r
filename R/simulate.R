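#' @include AllClasses.R
NULL

#' Simulator configuration
#'
#' Study conditions for the synthetic reference: a single-chromosome genome
#' with non-overlapping genes placed on alternating strands (>= 10 nt
#' spacers), CDS lengths a multiple of 3 drawn uniformly from
#' `geneLengthRange`, fixed canonical lengths for tRNA (76 nt) and rRNA
#' (1500 nt), and a log-normal transcript abundance model (sigma in log2
#' units) with an abundance boost for rRNA loci emulating non-depleted
#' samples.
#'
#' @param genomeLength genome length (nt).
#' @param nGenes number of genes.
#' @param geneLengthRange CDS length range (nt); rounded to multiples of 3.
#' @param gc G+C fraction of the random genome.
#' @param biotypeMix named fractions for CDS/tRNA/rRNA (must sum to 1).
#' @param abundanceSdLog2 sigma of the log-normal abundance model (log2 units).
#' @param rrnaBoost abundance multiplier for rRNA genes.
#' @param seed integer seed.
#' @return a list of class `SimConfig`.
#' @export
simConfig <- function(genomeLength = 260000L, nGenes = 200L,
                      geneLengthRange = c(300L, 1500L), gc = 0.5,
                      biotypeMix = c(CDS = 0.92, tRNA = 0.05, rRNA = 0.03),
                      abundanceSdLog2 = 1.5, rrnaBoost = 20, seed = 1L) {
  stopifnot(abs(sum(biotypeMix) - 1) < 1e-9, gc > 0, gc < 1)
  structure(list(genomeLength = as.integer(genomeLength),
                 nGenes = as.integer(nGenes),
                 geneLengthRange = as.integer(geneLengthRange), gc = gc,
                 biotypeMix = biotypeMix, abundanceSdLog2 = abundanceSdLog2,
                 rrnaBoost = rrnaBoost, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Generate a synthetic genome and annotation
#'
#' Random sequence at the configured GC content; genes packed left to right
#' with random 10-50 nt spacers, strands alternating. CDS frame anchors sit
#' at the transcript 5' terminus (`start` on `+`, `end` on `-`).
#'
#' Per-gene transcript abundances are drawn here, once per reference
#' (log-normal with the configured sigma, rRNA boosted by `rrnaBoost`):
#' abundance is a property of the strain, shared by every condition and
#' replicate simulated from the reference, so toxin-vs-vector ratios carry
#' no gene-level expression offsets.
#'
#' @param config a [simConfig()] list.
#' @return list with `genome` ([Biostrings::DNAString]), `annotation`
#'   ([GenomeAnnotation-class]), `abundance` (named positive weights, one
#'   per gene) and `config`.
#' @export
makeReference <- function(config = simConfig()) {
  set.seed(config$seed)
  nG <- config$nGenes
  nBio <- round(nG * config$biotypeMix)
  nBio["CDS"] <- nG - sum(nBio[c("tRNA", "rRNA")])
  biotype <- sample(rep(names(nBio), nBio))
  lens <- integer(nG)
  cds <- biotype == "CDS"
  lens[cds] <- 3L * sample(seq(config$geneLengthRange[1L] %/% 3L,
                               config$geneLengthRange[2L] %/% 3L),
                           sum(cds), replace = TRUE)
  lens[biotype == "tRNA"] <- 76L
  lens[biotype == "rRNA"] <- 1500L
  spacers <- sample(10:50, nG, replace = TRUE)
  if (sum(lens) + sum(spacers) > config$genomeLength)
    stop("infeasible packing: genes + spacers exceed the genome length")
  starts <- cumsum(c(spacers[1L], lens[-nG] + spacers[-1L])) + 1L
  ends <- starts + lens - 1L
  strnd <- rep(c("+", "-"), length.out = nG)
  base_p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
              G = config$gc / 2, T = (1 - config$gc) / 2)
  genome <- Biostrings::DNAString(paste(
    sample(names(base_p), config$genomeLength, replace = TRUE, prob = base_p),
    collapse = ""))
  anchor <- ifelse(biotype == "CDS",
                   ifelse(strnd == "+", starts, ends), NA_real_)
  genes <- GenomicRanges::GRanges(
    "genome", IRanges::IRanges(starts, ends), strand = strnd,
    gene_id = sprintf("g%03d", seq_len(nG)), biotype = biotype,
    frame_anchor = anchor)
  abundance <- 2^stats::rnorm(nG, 0, config$abundanceSdLog2)
  abundance[biotype == "rRNA"] <- abundance[biotype == "rRNA"] * config$rrnaBoost
  names(abundance) <- mcols(genes)$gene_id
  list(genome = genome,
       annotation = GenomeAnnotation(genes, config$genomeLength),
       abundance = abundance,
       config = config)
}

.sim_class_weight <- function(toxin, cls) {
  beta <- toxin@subcodonBias
  w <- rep((1 - beta) / 2 / beta, length(cls))
  w[cls == toxin@favoredSubcodon] <- 1
  w[is.na(cls)] <- 0     # ribosome-dependent cleavage needs a reading frame
  w
}

#' Realized cleavable sites of a toxin on a reference
#'
#' Enumerates the toxin's motif occurrences on cleavable transcripts
#' (biotypes CDS and other; CDS only for ribosome-dependent toxins) and, for
#' ribosome-dependent toxins, thins them site-by-site: an occurrence is
#' active with probability `(class weight) * exp(-x / lambda)`, where the
#' class weight is 1 for the favored subcodon class and `((1-beta)/2)/beta`
#' otherwise and x is the relative CDS coordinate. Which sites a nuclease
#' can attack is a property of the toxin and the transcript (ribosome
#' statistics at that codon), not of an individual RNA molecule, so the
#' active set is drawn once per experiment and shared by every condition and
#' replicate; per-molecule stochasticity enters only through the cut
#' efficiency in [simulateMolecules()].
#'
#' @param genome a [Biostrings::DNAString].
#' @param annotation a [GenomeAnnotation-class].
#' @param toxin a [ToxinModel-class].
#' @param seed integer seed for the activation draw.
#' @return data.frame of active sites: `gene_id`, `strand`,
#'   `transcript_offset`, `position` (genomic cut position), `rel_pos`, `t`
#'   (transcript coordinate of the downstream nucleotide) and `subcodon`.
#' @export
toxinActiveSites <- function(genome, annotation, toxin, seed = 1L) {
  set.seed(seed)
  genes <- geneRecords(annotation)
  bt <- mcols(genes)$biotype
  occ <- motifOccurrences(genome, annotation, toxin@motif,
                          cutOffset = toxin@cutOffset)
  if (nrow(occ) == 0L) return(occ)
  occ$t <- occ$transcript_offset + toxin@cutOffset
  occ <- occ[occ$t >= 2L, , drop = FALSE]   # a cut before nt 1 is a no-op
  gi <- match(occ$gene_id, mcols(genes)$gene_id)
  cleavable <- if (toxin@ribosomeDependent) "CDS" else c("CDS", "other")
  keepBio <- bt[gi] %in% cleavable
  occ <- occ[keepBio, , drop = FALSE]
  if (toxin@ribosomeDependent && nrow(occ)) {
    cls <- .subcodon_class(occ, annotation)
    pAct <- .sim_class_weight(toxin, cls) * exp(-occ$rel_pos / toxin@positionalLambda)
    occ <- occ[stats::runif(nrow(occ)) < pAct, , drop = FALSE]
  }
  occ$subcodon <- if (nrow(occ)) .subcodon_class(occ, annotation) else integer()
  rownames(occ) <- NULL
  occ
}

#' Simulate a population of (possibly cleaved) transcript molecules
#'
#' Per gene, a Poisson number of full-length transcript molecules is drawn
#' with mean proportional to its abundance. When a toxin is given,
#' each active motif occurrence in each molecule is cut independently with
#' probability `efficiency`; each cut splits the molecule and the 5'-side
#' product of every cut is discarded with probability `upstreamDecay`
#' (background cuts use `backgroundDecay`). Which occurrences are active
#' encodes the ribosome-dependence biases: ribosome-independent toxins
#' activate every occurrence in every transcribed gene; ribosome-dependent
#' toxins act only on CDS transcripts and activate an occurrence with
#' probability `(class weight) * exp(-x / lambda)`, where x is the relative
#' CDS coordinate and the class weight is 1 for the favored subcodon class
#' and `((1-beta)/2)/beta` otherwise, so realized cuts hit the favored class
#' with expected fraction beta and decay 5' to 3' at scale lambda.
#'
#' Only mRNA-like transcripts (biotypes `CDS` and `other`) are cleaved:
#' mature tRNA and rRNA are protected by structure and the ribosome, which
#' is also what anchors total-count size factors in the real assay.
#' Ribosome-dependent toxins additionally require a reading frame and act on
#' CDS transcripts only.
#'
#' @param genome a [Biostrings::DNAString].
#' @param annotation a [GenomeAnnotation-class].
#' @param toxin a [ToxinModel-class], or `NULL` for the empty-vector
#'   condition.
#' @param abundance positive per-gene weights in annotation order (or named
#'   by gene id), typically [makeReference()]`$abundance`; drawn log-normal
#'   (sigma `abundanceSdLog2`, rRNA times `rrnaBoost`) when `NULL`.
#' @param totalMolecules expected total molecule count across genes.
#' @param abundanceSdLog2 log-normal abundance sigma (log2 units; only used
#'   when `abundance` is `NULL`).
#' @param rrnaBoost abundance multiplier for rRNA genes (only used when
#'   `abundance` is `NULL`).
#' @param sites active-site table from [toxinActiveSites()]; computed here
#'   (with this function's `seed`) when `NULL`. Pass a shared table when
#'   simulating replicates so that site activity is consistent across
#'   populations.
#' @param backgroundRate motif-independent per-nucleotide per-molecule cut
#'   probability (defaults to the toxin's `backgroundRate`, 0 for vector).
#' @param backgroundDecay decay probability of 5'-side products of
#'   background cuts.
#' @param seed integer seed; the molecule population is bit-reproducible
#'   given (arguments, seed).
#' @return list with `molecules` (data.frame `start`, `end`, `strand`,
#'   `count` of surviving RNA products, genomic 1-based closed coordinates),
#'   `truth` (data.frame of realized toxin cuts: `position`, `strand`,
#'   `gene_id`, `n_cut` molecules cut, `subcodon`, `rel_pos`) and
#'   `activeSites` (the thinned site table the cuts were drawn from).
#' @export
simulateMolecules <- function(genome, annotation, toxin = NULL,
                              abundance = NULL, sites = NULL,
                              totalMolecules = 35000, abundanceSdLog2 = 1.5,
                              rrnaBoost = 20,
                              backgroundRate = NULL, backgroundDecay = 0.5,
                              seed = 1L) {
  if (!is.null(toxin) && is.null(sites))
    sites <- toxinActiveSites(genome, annotation, toxin, seed = seed)
  set.seed(seed)
  if (is.null(backgroundRate))
    backgroundRate <- if (is.null(toxin)) 0 else toxin@backgroundRate
  genes <- geneRecords(annotation)
  nG <- length(genes)
  bt <- mcols(genes)$biotype
  if (is.null(abundance)) {
    w <- 2^stats::rnorm(nG, 0, abundanceSdLog2)
    w[bt == "rRNA"] <- w[bt == "rRNA"] * rrnaBoost
  } else {
    w <- if (!is.null(names(abundance)))
      abundance[mcols(genes)$gene_id] else abundance
    if (length(w) != nG || any(is.na(w)) || any(w <= 0))
      stop("abundance must give a positive weight for every gene")
  }
  nMol <- stats::rpois(nG, totalMolecules * w / sum(w))
  gstart <- GenomicRanges::start(genes); gend <- GenomicRanges::end(genes)
  strnd <- as.character(GenomicRanges::strand(genes))
  glen <- gend - gstart + 1L

  # active cut sites per gene, in transcript coordinates of the downstream nt
  siteList <- rep(list(integer()), nG)
  if (!is.null(toxin) && !is.null(sites) && nrow(sites)) {
    gi <- match(sites$gene_id, mcols(genes)$gene_id)
    for (g in unique(gi)) siteList[[g]] <- sort(sites$t[gi == g])
    truthTab <- sites
    truthTab$n_cut <- 0L
    truthKey <- paste(gi, truthTab$t)
  }

  q <- if (is.null(toxin)) 0 else toxin@efficiency
  d <- if (is.null(toxin)) 0 else toxin@upstreamDecay
  molRows <- vector("list", nG)
  for (g in seq_len(nG)) {
    n <- nMol[g]
    if (n == 0L) next
    len <- glen[g]
    tk <- siteList[[g]]
    K <- length(tk)
    expBg <- len * backgroundRate
    if (K == 0L && expBg == 0) {
      molRows[[g]] <- data.frame(t_start = 1L, t_end = len, gene = g, count = n)
      next
    }
    cutMat <- if (K) matrix(stats::runif(n * K) < q, n, K) else NULL
    nBg <- if (expBg > 0) stats::rpois(n, expBg) else integer(n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      tc <- if (K) tk[cutMat[i, ]] else integer()
      isTox <- rep(TRUE, length(tc))
      if (nBg[i] > 0L) {
        bg <- sample.int(len - 1L, min(nBg[i], len - 1L)) + 1L
        bg <- setdiff(bg, tc)
        tc <- c(tc, bg); isTox <- c(isTox, rep(FALSE, length(bg)))
      }
      if (length(tc) == 0L) {
        rows[[i]] <- c(1L, len)
        next
      }
      o <- order(tc); tc <- tc[o]; isTox <- isTox[o]
      ps <- c(1L, tc); pe <- c(tc - 1L, len)
      # product j (j <= #cuts) is the 5'-side product of cut j
      decayP <- ifelse(isTox, d, backgroundDecay)
      keep <- c(stats::runif(length(tc)) >= decayP, TRUE)
      rows[[i]] <- rbind(ps[keep], pe[keep])
    }
    m <- do.call(cbind, rows)
    molRows[[g]] <- data.frame(t_start = m[1L, ], t_end = m[2L, ],
                               gene = g, count = 1L)
    if (K) {
      truthTab$n_cut[match(paste(g, tk), truthKey)] <- colSums(cutMat)
    }
  }
  mol <- do.call(rbind, molRows[!vapply(molRows, is.null, logical(1))])
  if (is.null(mol) || nrow(mol) == 0L) stop("empty molecule population")
  gidx <- mol$gene
  plusG <- strnd[gidx] == "+"
  molecules <- data.frame(
    start = ifelse(plusG, gstart[gidx] + mol$t_start - 1L,
                   gend[gidx] - mol$t_end + 1L),
    end = ifelse(plusG, gstart[gidx] + mol$t_end - 1L,
                 gend[gidx] - mol$t_start + 1L),
    strand = strnd[gidx],
    count = mol$count)
  truthOut <- NULL
  if (!is.null(toxin) && exists("truthTab") && nrow(truthTab)) {
    truthOut <- data.frame(position = truthTab$position,
                           strand = truthTab$strand,
                           gene_id = truthTab$gene_id,
                           n_cut = truthTab$n_cut,
                           subcodon = truthTab$subcodon,
                           rel_pos = truthTab$rel_pos)
    truthOut <- truthOut[order(match(truthOut$strand, c("+", "-")),
                               truthOut$position), , drop = FALSE]
    rownames(truthOut) <- NULL
  }
  list(molecules = molecules, truth = truthOut,
       activeSites = if (!is.null(toxin) && exists("truthTab")) truthTab else NULL)
}

#' Sample a sequencing library from a molecule population
#'
#' The unfragmented (5'-end) library samples molecules uniformly; each
#' sampled molecule contributes one fragment whose 5' end is the molecule's
#' 5' end, of length `min(readLen, molecule length)`, so only free 5' ends
#' are observed. The fragmented (coverage) library first breaks every
#' molecule at exponential(`fragMeanLen`) spacings (realized as a Poisson
#' breakpoint process, which is the same thing) and then samples the pieces
#' uniformly. The fragment count is Poisson with mean `depth`.
#'
#' @param molecules the `molecules` data.frame from [simulateMolecules()].
#' @param library `"unfragmented"` or `"fragmented"`.
#' @param depth expected number of fragments.
#' @param fragMeanLen mean fragmentation spacing (nt; fragmented only).
#' @param readLen read length (nt; caps unfragmented fragment extent).
#' @param minFragLen fragmented pieces shorter than this are unmappable and
#'   dropped (default 15 nt).
#' @param condition,sampleId,replicate metadata for the returned
#'   [FragmentSet-class].
#' @param seed integer seed.
#' @return a [FragmentSet-class].
#' @export
sampleLibrary <- function(molecules,
                          library = c("unfragmented", "fragmented"),
                          depth = 5e5, fragMeanLen = 100, readLen = 50,
                          minFragLen = 15L,
                          condition = c("vector", "toxin"),
                          sampleId = "sim", replicate = 1L, seed = 1L) {
  library <- match.arg(library)
  condition <- match.arg(condition)
  set.seed(seed)
  if (nrow(molecules) == 0L) stop("empty molecule population")
  nFrag <- stats::rpois(1L, depth)
  if (library == "unfragmented") {
    idx <- sample.int(nrow(molecules), nFrag, replace = TRUE,
                      prob = molecules$count)
    len <- pmin(readLen, molecules$end[idx] - molecules$start[idx] + 1L)
    plus <- molecules$strand[idx] == "+"
    fs <- ifelse(plus, molecules$start[idx], molecules$end[idx] - len + 1L)
    fe <- ifelse(plus, molecules$start[idx] + len - 1L, molecules$end[idx])
    frag <- data.frame(start = fs, end = fe, strand = molecules$strand[idx])
  } else {
    midx <- rep(seq_len(nrow(molecules)), molecules$count)
    len <- (molecules$end - molecules$start + 1L)[midx]
    nb <- stats::rpois(length(midx), len / fragMeanLen)
    bMol <- rep(seq_along(midx), nb)
    bt <- floor(stats::runif(sum(nb)) * len[bMol]) + 1L   # cut before nt bt+1
    ok <- bt >= 1L & bt < len[bMol]
    bMol <- bMol[ok]; bt <- bt[ok] + 1L
    # assemble pieces: every molecule contributes a piece starting at 1,
    # plus one piece per breakpoint
    pMol <- c(seq_along(midx), bMol)
    pStart <- c(rep(1L, length(midx)), bt)
    o <- order(pMol, pStart)
    pMol <- pMol[o]; pStart <- pStart[o]
    dup <- c(FALSE, pMol[-1L] == pMol[-length(pMol)] &
               pStart[-1L] == pStart[-length(pStart)])
    pMol <- pMol[!dup]; pStart <- pStart[!dup]
    isLast <- c(pMol[-1L] != pMol[-length(pMol)], TRUE)
    pEnd <- ifelse(isLast, len[pMol], c(pStart[-1L] - 1L, 0L))
    keep <- (pEnd - pStart + 1L) >= minFragLen
    pMol <- pMol[keep]; pStart <- pStart[keep]; pEnd <- pEnd[keep]
    if (length(pMol) == 0L) stop("fragmentation left no mappable pieces")
    pick <- sample.int(length(pMol), nFrag, replace = TRUE)
    mi <- midx[pMol[pick]]
    plus <- molecules$strand[mi] == "+"
    gs <- molecules$start[mi]; ge <- molecules$end[mi]
    frag <- data.frame(
      start = ifelse(plus, gs + pStart[pick] - 1L, ge - pEnd[pick] + 1L),
      end = ifelse(plus, gs + pEnd[pick] - 1L, ge - pStart[pick] + 1L),
      strand = molecules$strand[mi])
  }
  FragmentSet(frag, sampleId = sampleId, condition = condition,
              library = library, replicate = replicate)
}

#' Simulate a full dual-library toxin-vs-vector experiment
#'
#' Convenience wrapper: one reference, independent molecule populations per
#' condition x replicate, and both library types sampled from each
#' population. Per-sample seeds are derived deterministically from `seed`.
#'
#' @param reference a [makeReference()] list (or `NULL` to build one from
#'   `config`).
#' @param toxin a [ToxinModel-class].
#' @param config a [simConfig()] (used when `reference` is `NULL`).
#' @param nReplicates replicates per condition (default 2).
#' @param depth expected fragments per library.
#' @param totalMolecules expected molecules per population.
#' @param fragMeanLen,readLen library parameters (see [sampleLibrary()]).
#' @param seed master seed.
#' @return list with `reference`, `truth` (realized cuts of toxin replicate
#'   1), and `samples`: a nested list
#'   `samples[[condition]][[library]][[replicate]]` of
#'   [FragmentSet-class] objects.
#' @export
simulateExperiment <- function(reference = NULL, toxin, config = simConfig(),
                               nReplicates = 2L, depth = 5e5,
                               totalMolecules = 35000, fragMeanLen = 100,
                               readLen = 50, seed = 1L) {
  if (is.null(reference)) reference <- makeReference(config)
  genome <- reference$genome; annotation <- reference$annotation
  samples <- list(vector = list(fragmented = list(), unfragmented = list()),
                  toxin = list(fragmented = list(), unfragmented = list()))
  truth <- NULL
  sseed <- function(k) (as.integer(seed) * 97L + k) %% 2147483562L + 1L
  activeSites <- if (!is.null(toxin))
    toxinActiveSites(genome, annotation, toxin, seed = sseed(0L)) else NULL
  k <- 0L
  for (cond in c("vector", "toxin")) {
    for (r in seq_len(nReplicates)) {
      k <- k + 1L
      pop <- simulateMolecules(genome, annotation,
                               toxin = if (cond == "toxin") toxin else NULL,
                               abundance = reference$abundance,
                               sites = if (cond == "toxin") activeSites else NULL,
                               totalMolecules = totalMolecules,
                               seed = sseed(k))
      if (cond == "toxin" && r == 1L) truth <- pop$truth
      for (lib in c("fragmented", "unfragmented")) {
        k <- k + 1L
        samples[[cond]][[lib]][[r]] <- sampleLibrary(
          pop$molecules, library = lib, depth = depth,
          fragMeanLen = fragMeanLen, readLen = readLen,
          condition = cond,
          sampleId = sprintf("%s_%s_rep%d", cond, lib, r),
          replicate = r, seed = sseed(k))
      }
    }
  }
  list(reference = reference, truth = truth, activeSites = activeSites,
       samples = samples)
}
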