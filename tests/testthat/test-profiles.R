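bruteCoverage <- function(df, L) {
  out <- list("+" = numeric(L), "-" = numeric(L))
  for (i in seq_len(nrow(df)))
    out[[df$strand[i]]][df$start[i]:df$end[i]] <-
      out[[df$strand[i]]][df$start[i]:df$end[i]] + 1
  out
}

randomFragments <- function(n, L, maxLen = 60) {
  st <- sample.int(L - maxLen, n, replace = TRUE)
  data.frame(start = st, end = st + sample.int(maxLen, n, replace = TRUE) - 1L,
             strand = sample(c("+", "-"), n, replace = TRUE))
}

test_that("fragmentCoverage adds one count across each fragment", {
  fs <- FragmentSet(data.frame(start = 3, end = 5, strand = "+"))
  p <- fragmentCoverage(fs, 8)
  expect_equal(p@plus, c(0, 0, 1, 1, 1, 0, 0, 0))
  expect_equal(p@minus, rep(0, 8))

  fs2 <- FragmentSet(data.frame(start = c(1, 3), end = c(4, 6),
                                strand = c("+", "+")))
  expect_equal(fragmentCoverage(fs2, 8)@plus, c(1, 1, 2, 2, 1, 1, 0, 0))
})

test_that("coverage and 5'-end counts match brute-force oracles and conserve totals", {
  set.seed(11)
  for (i in 1:15) {
    L <- 500L
    df <- randomFragments(200, L)
    fs <- FragmentSet(df, library = "unfragmented")
    cov <- fragmentCoverage(fs, L)
    oracle <- bruteCoverage(df, L)
    expect_identical(cov@plus, oracle[["+"]])
    expect_identical(cov@minus, oracle[["-"]])
    expect_identical(sum(cov@plus) + sum(cov@minus),
                     sum(df$end - df$start + 1))

    e5 <- end5Counts(fs, L)
    o5 <- list("+" = numeric(L), "-" = numeric(L))
    for (j in seq_len(nrow(df))) {
      p <- if (df$strand[j] == "+") df$start[j] else df$end[j]
      o5[[df$strand[j]]][p] <- o5[[df$strand[j]]][p] + 1
    }
    expect_identical(e5@plus, o5[["+"]])
    expect_identical(e5@minus, o5[["-"]])
    expect_identical(sum(e5@plus) + sum(e5@minus), as.numeric(nrow(df)))
  }
})

test_that("the transcript 5' end is start on plus and end on minus", {
  fs <- FragmentSet(data.frame(start = c(3, 3), end = c(5, 5),
                               strand = c("+", "-")), library = "unfragmented")
  e5 <- end5Counts(fs, 8)
  expect_equal(which(e5@plus == 1), 3L)
  expect_equal(which(e5@minus == 1), 5L)
})

test_that("end5Counts warns on fragmented input", {
  fs <- FragmentSet(data.frame(start = 1, end = 5, strand = "+"),
                    library = "fragmented")
  expect_warning(end5Counts(fs, 8), "unfragmented")
})

test_that("sizeFactor is total included counts per million, with optional rRNA exclusion", {
  ref <- tinyReference()
  p <- flatProfile(0, 600)
  p@plus[1:500] <- 4000   # 2e6 counts total
  p <- NucProfile(p@plus, p@minus, kind = "coverage")
  expect_equal(sizeFactor(p), 2)

  # half the signal inside the rRNA locus [501, 560]
  v <- numeric(600); v[481:500] <- 25000; v[501:540] <- 12500
  q <- NucProfile(v, numeric(600), kind = "coverage")
  expect_equal(sizeFactor(q), 1)
  expect_equal(sizeFactor(q, ref$annotation, excludeRrna = TRUE), 0.5)

  expect_error(sizeFactor(flatProfile(0), NULL), "zero included")
})

test_that("normalization conserves the included total at the scale", {
  set.seed(3)
  for (i in 1:5) {
    v <- rpois(300, 20) * 50
    p <- NucProfile(v, rev(v), kind = "coverage")
    sf <- sizeFactor(p)
    n <- normalizeProfile(p, sf)
    expect_equal(sum(n@plus) + sum(n@minus), 1e6)
    expect_true(n@normalized)
  }
  expect_error(normalizeProfile(flatProfile(1), 0), "positive")
})

test_that("two samples with totals in ratio r have equal normalized totals", {
  v <- rpois(200, 30)
  a <- NucProfile(v, v, kind = "coverage")
  b <- NucProfile(3 * v, 3 * v, kind = "coverage")
  na <- normalizeProfile(a, sizeFactor(a))
  nb <- normalizeProfile(b, sizeFactor(b))
  expect_equal(sum(na@plus), sum(nb@plus))
})

test_that("combineReplicates takes the geometric mean and unions masks", {
  er <- function(v) NucProfile(v, rep(1, length(v)), kind = "end_ratio",
                               normalized = TRUE)
  comb <- combineReplicates(list(er(c(16, 4, NA)), er(c(64, 4, 2))))
  expect_equal(comb@plus, c(32, 4, NA))
  expect_false(comb@plusMask[3])

  # single replicate is the identity
  one <- combineReplicates(list(er(c(2, 3, 4))))
  expect_equal(one@plus, c(2, 3, 4))

  # log2 tracks: arithmetic mean of logs == log of geometric mean
  cr <- function(v) NucProfile(v, v, kind = "cleavage_ratio", normalized = TRUE)
  expect_equal(combineReplicates(list(cr(-1), cr(-3)))@plus, -2)

  # permutation invariance
  set.seed(5)
  reps <- lapply(1:3, function(i) er(runif(50, 0.1, 100)))
  expect_equal(combineReplicates(reps)@plus,
               combineReplicates(rev(reps))@plus)

  expect_error(combineReplicates(list(er(1), cr(1))), "mixed")
  expect_error(combineReplicates(list()), "no profiles")
  expect_error(combineReplicates(list(flatProfile(1))), "ratio")
})

normCov <- function(plus, minus = rep(0, length(plus))) {
  NucProfile(plus, minus, kind = "coverage", normalized = TRUE)
}
normEnd <- function(plus, minus = rep(0, length(plus))) {
  NucProfile(plus, minus, kind = "end5", normalized = TRUE)
}

test_that("cleavageRatio is log2((t+eps)/(v+eps)) with a vector-expression mask", {
  t <- normCov(c(2, 8, 4, 0.5))
  v <- normCov(c(8, 8, 8, 0.5))
  cr <- cleavageRatio(t, v, pseudocount = 0, minDefined = 1)
  expect_equal(cr@plus[1:3], c(-2, 0, -1))     # -1 is the 2-fold-down boundary
  expect_true(is.na(cr@plus[4]))               # vector below minDefined: masked
  expect_equal(profileKind(cr), "cleavage_ratio")

  # identical inputs give exactly 0 whatever the pseudocount
  x <- normCov(runif(20, 0, 50))
  expect_equal(cleavageRatio(x, x, pseudocount = 0.25, minDefined = 0)@plus,
               rep(0, 20))

  # swapping toxin and vector negates the ratio (eps = 0)
  a <- normCov(2:21); b <- normCov(rev(2:21))
  expect_equal(cleavageRatio(a, b, 0, 1)@plus, -cleavageRatio(b, a, 0, 1)@plus)
})

test_that("endRatio is linear with pseudocount handling of zero-count positions", {
  t <- normEnd(c(64, 5, 8))
  v <- normEnd(c(2, 5, 0))
  er <- endRatio(t, v, pseudocount = 0)
  expect_equal(er@plus[1:2], c(32, 1))
  expect_true(is.na(er@plus[3]))               # 0/0 undefined without pseudocount

  er2 <- endRatio(t, v, pseudocount = 0.25)
  expect_equal(er2@plus[3], 33)                # (8 + .25) / .25

  # swap inverts (eps = 0, nonzero counts)
  a <- normEnd(1:10); b <- normEnd(10:1)
  expect_equal(endRatio(a, b, 0)@plus, 1 / endRatio(b, a, 0)@plus)

  expect_error(endRatio(t, normCov(1:3)), "end5")
  expect_error(cleavageRatio(normCov(1:3), normCov(1:4)), "length")
  expect_error(cleavageRatio(normCov(1:3),
                             NucProfile(1:3, 1:3, kind = "coverage")),
               "normalized")
})
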