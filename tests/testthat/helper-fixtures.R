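# Shared fixtures. The large simulated experiments are built lazily and
# cached for the whole test run: several files exercise the same study
# conditions and re-simulating them per test would dominate the runtime.

.cache <- new.env(parent = emptyenv())

cachedFixture <- function(name, builder) {
  if (!exists(name, envir = .cache)) assign(name, builder(), envir = .cache)
  get(name, envir = .cache)
}

# small deterministic genome + annotation: two CDS (one per strand),
# one rRNA, generous intergenic space
tinyReference <- function() {
  set.seed(7)
  seq <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAString(seq)
  genes <- GenomicRanges::GRanges(
    "genome",
    IRanges::IRanges(start = c(101, 301, 501), end = c(220, 420, 560)),
    strand = c("+", "-", "+"),
    gene_id = c("cdsA", "cdsB", "rrn1"),
    biotype = c("CDS", "CDS", "rRNA"),
    frame_anchor = c(101, 420, NA))
  list(genome = genome, annotation = GenomeAnnotation(genes, 600L))
}

# flat raw profiles over the tiny reference for constructing scenarios
flatProfile <- function(value, L = 600L, kind = "coverage") {
  NucProfile(rep(value, L), rep(value, L), kind = kind)
}

# reference shared by the recovery simulations (the study conditions)
refSim <- function() cachedFixture("refSim", function() {
  makeReference(simConfig(seed = 101))
})

# ribosome-independent MazF-like run: motif, recall, precision
simIndep <- function() cachedFixture("simIndep", function() {
  ref <- refSim()
  tox <- toxinModel("ACA", cutOffset = 0L, efficiency = 0.9, upstreamDecay = 0.9)
  sim <- simulateExperiment(ref, tox, nReplicates = 2L, depth = 5e5, seed = 101)
  sim$pipeline <- runCleavagePipeline(sim$samples, ref$genome, ref$annotation)
  sim
})

# ribosome-dependent run isolating the subcodon preference (no 5' thinning)
simSubcodon <- function() cachedFixture("simSubcodon", function() {
  ref <- refSim()
  tox <- toxinModel("ACA", efficiency = 0.9, upstreamDecay = 0.9,
                    ribosomeDependent = TRUE, subcodonBias = 0.9,
                    favoredSubcodon = 1L, positionalLambda = 1000)
  sim <- simulateExperiment(ref, tox, nReplicates = 2L, depth = 5e5, seed = 103)
  sim$pipeline <- runCleavagePipeline(sim$samples, ref$genome, ref$annotation)
  sim
})

# ribosome-dependent run with the 5' positional bias at lambda = 0.2;
# positional estimates need many sites, and the 5' thinning leaves only
# ~1 active site per gene, so this run uses a 4x larger experiment
simMetagene <- function() cachedFixture("simMetagene", function() {
  ref <- makeReference(simConfig(nGenes = 800, genomeLength = 1040000,
                                 seed = 105))
  tox <- toxinModel("ACA", efficiency = 0.9, upstreamDecay = 0.9,
                    ribosomeDependent = TRUE, subcodonBias = 0.9,
                    favoredSubcodon = 1L, positionalLambda = 0.2)
  sim <- simulateExperiment(ref, tox, nReplicates = 2L, depth = 2e6,
                            totalMolecules = 140000, seed = 105)
  sim$pipeline <- runCleavagePipeline(sim$samples, ref$genome, ref$annotation)
  sim$reference <- ref
  sim
})

# truth sites passing the same expression gate the caller applies
gatedTruthKeys <- function(truth, vectorRawCoverage, L, window = 10L,
                           minExpression = 64) {
  ok <- vapply(seq_len(nrow(truth)), function(i) {
    p <- truth$position[i]; s <- truth$strand[i]
    win <- if (s == "+") (p - window):p else p:(p + window)
    if (min(win) < 1L || max(win) > L) return(FALSE)
    v <- profileValues(vectorRawCoverage, s)[win]
    !any(is.na(v)) && all(v >= minExpression)
  }, logical(1))
  paste(truth$position, truth$strand)[ok]
}

siteKeys <- function(sites) paste(sites$position, sites$strand)
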