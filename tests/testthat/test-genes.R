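test_that("expressedGenes requires the threshold at every in-gene position, inclusive", {
  ref <- tinyReference()
  cov <- flatProfile(64)
  ex <- expressedGenes(cov, ref$annotation, minReads = 64)
  expect_true(all(ex))

  cov2 <- flatProfile(64)
  cov2@plus[150] <- 63       # one position inside cdsA (plus strand)
  cov2 <- NucProfile(cov2@plus, cov2@minus, kind = "coverage")
  ex2 <- expressedGenes(cov2, ref$annotation, minReads = 64)
  expect_false(ex2[["cdsA"]])
  expect_true(ex2[["cdsB"]])  # minus-strand gene unaffected

  # the stricter cross-library gate
  expect_false(any(expressedGenes(cov, ref$annotation, minReads = 256)))
  expect_named(expressedGenes(cov, ref$annotation, biotype = "CDS"),
               c("cdsA", "cdsB"))
})

test_that("per-gene minimum cleavage ratio matches a brute-force scan on random profiles", {
  ref <- tinyReference()
  genes <- geneRecords(ref$annotation)
  set.seed(13)
  for (i in 1:20) {
    vp <- rnorm(600); vm <- rnorm(600)
    vp[sample(600, 30)] <- NA; vm[sample(600, 30)] <- NA
    cr <- NucProfile(vp, vm, kind = "cleavage_ratio", normalized = TRUE)
    expressed <- setNames(rep(TRUE, 3), S4Vectors::mcols(genes)$gene_id)
    tab <- minCleavageRatio(cr, ref$annotation, expressed)
    for (j in 1:3) {
      rng <- GenomicRanges::start(genes)[j]:GenomicRanges::end(genes)[j]
      v <- if (as.character(GenomicRanges::strand(genes))[j] == "+") vp else vm
      expect_identical(tab$min_cr[j], min(v[rng], na.rm = TRUE))
      expect_equal(tab$unmasked_fraction[j], mean(!is.na(v[rng])))
    }
  }
})

test_that("minCleavageRatio handles flat and single-dip profiles and unexpressed genes", {
  ref <- tinyReference()
  cr <- NucProfile(rep(0, 600), rep(0, 600), kind = "cleavage_ratio",
                   normalized = TRUE)
  cr@plus[150] <- -3
  cr <- NucProfile(cr@plus, cr@minus, kind = "cleavage_ratio", normalized = TRUE)
  expressed <- c(cdsA = TRUE, cdsB = TRUE, rrn1 = FALSE)
  tab <- minCleavageRatio(cr, ref$annotation, expressed)
  expect_equal(tab$min_cr[tab$gene_id == "cdsA"], -3)
  expect_equal(tab$min_cr[tab$gene_id == "cdsB"], 0)
  expect_true(is.na(tab$min_cr[tab$gene_id == "rrn1"]))
})

test_that("fractionBelow uses a strict inequality over expressed genes", {
  tab <- data.frame(gene_id = letters[1:5],
                    expressed = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                    min_cr = c(0, -0.5, -1, -3, -9))
  expect_equal(fractionBelow(tab, -1), 25)      # only -3 is strictly below
  expect_equal(fractionBelow(tab, 0), 75)
  expect_equal(fractionBelow(data.frame(gene_id = "a", expressed = TRUE,
                                        min_cr = 0), -1), 0)
  expect_error(fractionBelow(data.frame(gene_id = "a", expressed = FALSE,
                                        min_cr = NA_real_), -1), "no expressed")
})

test_that("motifHits counts overlapping occurrences on the transcript strand", {
  genes <- GenomicRanges::GRanges(
    "genome", IRanges::IRanges(c(1, 10), c(5, 14)), strand = c("+", "-"),
    gene_id = c("gP", "gM"), biotype = "CDS", frame_anchor = c(1, 14))
  #            gP: AACAA          gM: revcomp(TGTGT) = ACACA
  genome <- Biostrings::DNAString("AACAAGGGGTGTGT")
  ann <- GenomeAnnotation(genes, 14L)
  hits <- motifHits(genome, ann, "ACA")
  expect_equal(hits[["gP"]], 1L)
  expect_equal(hits[["gM"]], 2L)      # overlapping occurrences both counted
  expect_error(motifHits(genome, ann, "AXA"), "A,C,G,T")

  # sliding-window oracle on random gene sequences
  set.seed(17)
  for (i in 1:10) {
    L <- 300L
    g <- Biostrings::DNAString(paste(sample(c("A", "C", "G", "T"), L,
                                            replace = TRUE), collapse = ""))
    gr <- GenomicRanges::GRanges("genome", IRanges::IRanges(21, 280),
                                 strand = sample(c("+", "-"), 1),
                                 gene_id = "g1", biotype = "CDS",
                                 frame_anchor = 21)
    ann2 <- GenomeAnnotation(gr, L)
    seq <- substr(as.character(g), 21, 280)
    if (as.character(GenomicRanges::strand(gr)) == "-")
      seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    oracle <- sum(vapply(1:(nchar(seq) - 2),
                         function(k) substr(seq, k, k + 2) == "ACA", logical(1)))
    expect_equal(unname(motifHits(g, ann2, "ACA")), oracle)
  }
})

test_that("motif cut positions land where the planted toxin cuts", {
  sim <- simIndep()
  occ <- motifOccurrences(refSim()$genome, refSim()$annotation, "ACA",
                          cutOffset = 0L)
  expect_true(all(paste(sim$truth$position, sim$truth$strand) %in%
                    paste(occ$position, occ$strand)))
})

test_that("compareMinima reports affine-invariant R-squared over shared expressed genes", {
  tab <- function(ids, v) data.frame(gene_id = ids, expressed = TRUE, min_cr = v)
  set.seed(23)
  a <- tab(letters[1:10], rnorm(10))
  expect_equal(compareMinima(a, a)$r_squared, 1)
  b <- a; b$min_cr <- 2 * a$min_cr + 1
  expect_equal(compareMinima(a, b)$r_squared, 1)

  # independent tables are uncorrelated
  big <- tab(paste0("g", 1:1000), rnorm(1000))
  big2 <- tab(paste0("g", 1:1000), rnorm(1000))
  expect_lt(compareMinima(big, big2)$r_squared, 0.05)

  # only the shared expressed intersection is used
  c1 <- tab(letters[1:5], 1:5); c1$expressed[4:5] <- FALSE
  c2 <- tab(letters[1:5], c(2, 4, 6, 0, 0))
  out <- compareMinima(c1, c2)
  expect_equal(out$n_genes, 3L)
  expect_equal(out$gene_id, letters[1:3])
  expect_error(compareMinima(tab("a", 1), tab("a", 1)), "at least 3")
})

test_that("regionProfile reports values 5' to 3' on the region's strand", {
  p <- NucProfile(1:10, 101:110, kind = "coverage")
  expect_equal(regionProfile(p, 3, 6, "+"), 3:6)
  expect_equal(regionProfile(p, 3, 6, "-"), c(106, 105, 104, 103))
  expect_error(regionProfile(p, 0, 5), "outside")
  expect_error(regionProfile(p, 8, 12), "outside")

  # slices of a written-and-reread profile match exactly
  prefix <- withr::local_tempfile()
  writeProfile(p, prefix, omitZeros = FALSE)
  back <- readProfile(prefix, 10, kind = "coverage")
  expect_equal(regionProfile(back, 2, 9, "-"), regionProfile(p, 2, 9, "-"))
})

test_that("gene-level cleavage fractions hit the simulation endpoints", {
  sim <- simIndep()
  expect_gt(fractionBelow(sim$pipeline$geneTable, -1), 60)
})
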