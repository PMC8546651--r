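#' @include AllClasses.R
NULL

#' Classify candidate motif positions as cleaved or uncleaved for one toxin
#'
#' A candidate is cleaved iff its 5'-end ratio is at least `minEndRatio`
#' (default 10) and its cleavage ratio is at most `maxCr` (default -1), both
#' thresholds inclusive. Candidates failing the expression gate (raw vector
#' coverage below `minExpression` at the candidate position, or masked
#' ratios) are removed from the candidate set entirely, not labeled
#' uncleaved.
#'
#' @param candidates data.frame with `position` and `strand` (typically the
#'   shared-motif positions from [motifOccurrences()]).
#' @param endRatio,cleavageRatio,vectorRawCoverage profiles for the toxin
#'   (see [callSites()]).
#' @param minEndRatio,maxCr,minExpression classification thresholds
#'   (defaults 10, -1, 64).
#' @return `candidates` restricted to gated rows, with a logical `cleaved`
#'   column added; the number of gated-out candidates is attached as
#'   `attr(, "n_gated_out")`.
#' @export
classifyCandidates <- function(candidates, endRatio, cleavageRatio,
                               vectorRawCoverage, minEndRatio = 10,
                               maxCr = -1, minExpression = 64) {
  n <- nrow(candidates)
  if (n == 0L) stop("empty candidate set")
  getv <- function(prof) {
    v <- ifelse(candidates$strand == "+",
                profileValues(prof, "+")[candidates$position],
                profileValues(prof, "-")[candidates$position])
    v
  }
  er <- getv(endRatio); cr <- getv(cleavageRatio); vc <- getv(vectorRawCoverage)
  keep <- !is.na(vc) & vc >= minExpression & !is.na(er) & !is.na(cr)
  if (!any(keep)) stop("no candidates pass the expression gate")
  out <- candidates[keep, , drop = FALSE]
  out$cleaved <- er[keep] >= minEndRatio & cr[keep] <= maxCr
  rownames(out) <- NULL
  attr(out, "n_gated_out") <- sum(!keep)
  out
}

#' Permutation test of cleavage-site overlap between two toxins
#'
#' Tests whether the number of candidates cleaved by both toxins exceeds
#' chance, by permuting the cleaved/uncleaved labels across candidates.
#' Permuting both label vectors independently is equivalent to permuting one
#' against the other, which is how it is implemented. The p-value uses the
#' add-one estimator `p = (1 + #perm with both >= observed) / (nPerm + 1)`,
#' guaranteeing `p > 0`. Because the permutation null of the both-cleaved
#' count is exactly hypergeometric, the analytic tail probability is
#' reported alongside.
#'
#' @param labelsA,labelsB logical vectors of equal length: per-candidate
#'   cleaved calls for each toxin (the `cleaved` column of
#'   [classifyCandidates()]).
#' @param nPerm number of permutations (the reference analysis used 1e5).
#' @param seed integer seed for reproducibility.
#' @param returnNull also return the permuted both-cleaved counts (`null`),
#'   e.g. for goodness-of-fit diagnostics.
#' @return list with `n`, `a`, `b` (candidate and per-toxin cleaved counts),
#'   `both_obs`, `null_mean`, `null_sd`, `p_value` (permutation, add-one),
#'   `p_hyper` (exact hypergeometric upper tail), `n_perm` and `seed`.
#' @export
permutationOverlap <- function(labelsA, labelsB, nPerm = 1e5, seed = 1L,
                               returnNull = FALSE) {
  if (length(labelsA) != length(labelsB))
    stop("label vectors differ in length")
  n <- length(labelsA)
  if (n < 1L) stop("need at least one candidate")
  nPerm <- as.integer(nPerm)
  if (nPerm < 1L) stop("nPerm must be at least 1")
  a <- sum(labelsA); b <- sum(labelsB)
  both_obs <- sum(labelsA & labelsB)
  set.seed(seed)
  # permuting A's labels and intersecting with B == summing B over a
  # uniformly chosen size-a subset of positions
  bnum <- as.numeric(labelsB)
  null <- vapply(seq_len(nPerm),
                 function(i) sum(bnum[sample.int(n, a)]),
                 numeric(1))
  p_perm <- (1 + sum(null >= both_obs)) / (nPerm + 1)
  p_hyper <- stats::phyper(both_obs - 1L, m = a, n = n - a, k = b,
                           lower.tail = FALSE)
  out <- list(n = n, a = a, b = b, both_obs = both_obs,
              null_mean = mean(null), null_sd = stats::sd(null),
              p_value = p_perm, p_hyper = p_hyper,
              n_perm = nPerm, seed = as.integer(seed))
  if (returnNull) out$null <- null
  out
}
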