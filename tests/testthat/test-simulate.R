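expandMolecules <- function(mol) {
  idx <- rep(seq_len(nrow(mol)), mol$count)
  out <- mol[idx, c("start", "end", "strand")]
  out <- out[order(out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  out
}

test_that("makeReference is deterministic and packs non-overlapping alternating genes", {
  cfg <- simConfig(nGenes = 50, genomeLength = 60000, seed = 31)
  r1 <- makeReference(cfg)
  r2 <- makeReference(cfg)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(r1$abundance, r2$abundance)
  g <- geneRecords(r1$annotation)
  expect_equal(length(g), 50L)
  expect_equal(as.character(GenomicRanges::strand(g)),
               rep(c("+", "-"), 25))
  # >= 10 nt spacers between consecutive genes, no overlap
  gaps <- GenomicRanges::start(g)[-1] - GenomicRanges::end(g)[-50]
  expect_true(all(gaps >= 11))
  # CDS lengths are codon multiples and anchors sit at the 5' terminus
  cds <- g[S4Vectors::mcols(g)$biotype == "CDS"]
  expect_true(all(GenomicRanges::width(cds) %% 3 == 0))
  plus <- as.character(GenomicRanges::strand(cds)) == "+"
  expect_equal(S4Vectors::mcols(cds)$frame_anchor[plus],
               GenomicRanges::start(cds)[plus])
  expect_equal(S4Vectors::mcols(cds)$frame_anchor[!plus],
               GenomicRanges::end(cds)[!plus])
})

test_that("the random genome hits the configured GC within 3 binomial SDs", {
  r <- makeReference(simConfig(nGenes = 10, genomeLength = 1e5, gc = 0.5,
                               seed = 33))
  gcCount <- sum(Biostrings::alphabetFrequency(r$genome)[c("C", "G")])
  expect_lt(abs(gcCount - 5e4), 3 * sqrt(1e5 * 0.25))
  expect_error(makeReference(simConfig(nGenes = 100, genomeLength = 5000)),
               "infeasible")
})

test_that("a zero-efficiency toxin leaves the molecule population identical to the vector condition", {
  ref <- makeReference(simConfig(nGenes = 30, genomeLength = 40000, seed = 35))
  tox0 <- toxinModel("ACA", efficiency = 0)
  vec <- simulateMolecules(ref$genome, ref$annotation, NULL,
                           abundance = ref$abundance,
                           totalMolecules = 3000, seed = 9)
  tox <- simulateMolecules(ref$genome, ref$annotation, tox0,
                           abundance = ref$abundance,
                           totalMolecules = 3000, seed = 9)
  expect_identical(expandMolecules(vec$molecules), expandMolecules(tox$molecules))
  expect_true(all(tox$truth$n_cut == 0))
})

test_that("at full efficiency and decay every cleaved molecule starts at a planted cut", {
  # one gene carrying exactly one ACA
  genome <- Biostrings::DNAString(paste0(strrep("G", 30), "T", "ACA",
                                         strrep("G", 30), strrep("T", 20)))
  genes <- GenomicRanges::GRanges("genome", IRanges::IRanges(11, 70),
                                  strand = "+", gene_id = "g1",
                                  biotype = "CDS", frame_anchor = 11)
  ann <- GenomeAnnotation(genes, length(genome))
  tox <- toxinModel("ACA", cutOffset = 0L, efficiency = 1, upstreamDecay = 1)
  pop <- simulateMolecules(genome, ann, tox, abundance = c(g1 = 1),
                           totalMolecules = 500, seed = 3)
  expect_equal(nrow(pop$truth), 1L)
  expect_equal(pop$truth$position, 32L)   # cut 5' of the A at genomic 32
  mol <- expandMolecules(pop$molecules)
  expect_true(all(mol$start == 32))
  expect_true(all(mol$end == 70))
})

test_that("per-site cut counts are binomial in the efficiency", {
  genome <- Biostrings::DNAString(paste0(strrep("G", 50), "ACA", strrep("G", 50)))
  genes <- GenomicRanges::GRanges("genome", IRanges::IRanges(31, 80),
                                  strand = "+", gene_id = "g1",
                                  biotype = "CDS", frame_anchor = 31)
  ann <- GenomeAnnotation(genes, length(genome))
  tox <- toxinModel("ACA", efficiency = 0.5, upstreamDecay = 0.5)
  pop <- simulateMolecules(genome, ann, tox, abundance = c(g1 = 1),
                           totalMolecules = 10000, seed = 5)
  frac <- pop$truth$n_cut / 10000
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000) + 0.02)
})

test_that("ribosome-dependent site activation favors the planted class and 5' end", {
  ref <- refSim()
  sim <- simSubcodon()
  cls <- sim$activeSites$subcodon
  f1 <- mean(cls == 1)
  expect_lt(abs(f1 - 0.9), 3 * sqrt(0.9 * 0.1 / length(cls)) + 0.01)
  # ribosome-dependent toxins only attack CDS transcripts
  bt <- S4Vectors::mcols(geneRecords(ref$annotation))$biotype
  ids <- S4Vectors::mcols(geneRecords(ref$annotation))$gene_id
  expect_true(all(sim$activeSites$gene_id %in% ids[bt == "CDS"]))
})

test_that("background cuts create motif-independent 5' ends without entering the truth log", {
  ref <- makeReference(simConfig(nGenes = 30, genomeLength = 40000, seed = 35))
  tox <- toxinModel("ACA", efficiency = 0.9, upstreamDecay = 0.9,
                    backgroundRate = 5e-4)
  pop <- simulateMolecules(ref$genome, ref$annotation, tox,
                           abundance = ref$abundance,
                           totalMolecules = 3000, seed = 9)
  occ <- motifOccurrences(ref$genome, ref$annotation, "ACA", cutOffset = 0L)
  gstarts <- ifelse(as.character(GenomicRanges::strand(geneRecords(ref$annotation))) == "+",
                    GenomicRanges::start(geneRecords(ref$annotation)),
                    GenomicRanges::end(geneRecords(ref$annotation)))
  p5 <- ifelse(pop$molecules$strand == "+", pop$molecules$start,
               pop$molecules$end)
  offMotif <- !(paste(p5, pop$molecules$strand) %in%
                  paste(occ$position, occ$strand)) & !(p5 %in% gstarts)
  expect_gt(sum(pop$molecules$count[offMotif]), 0)
  # the truth log still records only motif-directed cuts
  expect_true(all(paste(pop$truth$position, pop$truth$strand) %in%
                    paste(occ$position, occ$strand)))
})

test_that("library sampling is reproducible and Poisson in depth", {
  ref <- makeReference(simConfig(nGenes = 30, genomeLength = 40000, seed = 35))
  pop <- simulateMolecules(ref$genome, ref$annotation, NULL,
                           abundance = ref$abundance,
                           totalMolecules = 3000, seed = 9)
  f1 <- sampleLibrary(pop$molecules, "fragmented", depth = 20000, seed = 21)
  f2 <- sampleLibrary(pop$molecules, "fragmented", depth = 20000, seed = 21)
  expect_identical(fragments(f1), fragments(f2))
  expect_lt(abs(length(fragments(f1)) - 20000), 3 * sqrt(20000))

  u <- sampleLibrary(pop$molecules, "unfragmented", depth = 20000, seed = 22)
  expect_lt(abs(length(fragments(u)) - 20000), 3 * sqrt(20000))
})

test_that("unfragmented sampling reads molecule 5' ends only", {
  mol <- data.frame(start = c(500, 500), end = c(700, 640),
                    strand = c("+", "-"), count = c(30, 30))
  u <- sampleLibrary(mol, "unfragmented", depth = 500, readLen = 50, seed = 2)
  gr <- fragments(u)
  s <- as.character(GenomicRanges::strand(gr))
  expect_true(all(GenomicRanges::start(gr)[s == "+"] == 500))
  expect_true(all(GenomicRanges::end(gr)[s == "-"] == 640))
  expect_true(all(GenomicRanges::width(gr) == 50))
})

test_that("fragmented coverage of intact transcripts is flat in the interior", {
  mol <- data.frame(start = 1001, end = 3000, strand = "+", count = 2000)
  fr <- sampleLibrary(mol, "fragmented", depth = 50000, fragMeanLen = 100,
                      seed = 8)
  cov <- fragmentCoverage(fr, 4000)@plus
  # compare 10 interior bins (staying clear of the edge-effect zones);
  # adjacent positions share fragments, so judge bins on a relative scale
  interior <- cov[1201:2800]
  bins <- colMeans(matrix(interior, nrow = 160))
  expect_true(all(abs(bins / mean(interior) - 1) < 0.1))
})

test_that("simulateExperiment shares active sites and truth across replicates", {
  ref <- makeReference(simConfig(nGenes = 40, genomeLength = 50000, seed = 37))
  tox <- toxinModel("ACA", efficiency = 0.9, upstreamDecay = 0.9)
  sim <- simulateExperiment(ref, tox, nReplicates = 2, depth = 30000,
                            totalMolecules = 5000, seed = 41)
  expect_equal(nrow(sim$truth), nrow(sim$activeSites))
  expect_setequal(sim$truth$position, sim$activeSites$position)
  # both library types and conditions present for both replicates
  expect_equal(length(sim$samples$toxin$unfragmented), 2L)
  expect_s4_class(sim$samples$vector$fragmented[[2]], "FragmentSet")
  # deterministic end to end
  sim2 <- simulateExperiment(ref, tox, nReplicates = 2, depth = 30000,
                             totalMolecules = 5000, seed = 41)
  expect_identical(fragments(sim$samples$toxin$fragmented[[1]]),
                   fragments(sim2$samples$toxin$fragmented[[1]]))
})

test_that("a vector-vs-vector experiment calls no sites and few genes below -1", {
  ref <- makeReference(simConfig(nGenes = 60, genomeLength = 80000, seed = 43))
  sim <- simulateExperiment(ref, toxin = NULL, nReplicates = 2, depth = 2e5,
                            totalMolecules = 10000, seed = 43)
  pl <- runCleavagePipeline(sim$samples, ref$genome, ref$annotation)
  expect_equal(nrow(pl$sites), 0L)
  expect_lt(fractionBelow(pl$geneTable, -1), 2)
})
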