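# Independent oracles and small data helpers for the test suite.

# Exhaustive O(d^2) scan of Definition-style cutoffs: for every candidate
# threshold t (nonzero |C_j|) count scores below -t and above t by explicit
# comparison, and return the smallest qualifying t (Inf if none). Written
# independently of the package's sorted-scan implementation.
bruteForceCutoff <- function(C, q, procedure = c("BC", "GZ"), h = 1L) {
  procedure <- match.arg(procedure)
  cand <- sort(unique(abs(C[C != 0])))
  for (t in cand) {
    nNeg <- sum(C <= -t)
    nPos <- sum(C >= t)
    num <- if (procedure == "BC") nNeg + 1 else (1 + nNeg) / h
    if (num / max(nPos, 1) <= q) {
      return(t)
    }
  }
  Inf
}

# All equivalence-class representatives for a design, by enumerating every
# m-subset and (for differential m = n) deduplicating complements.
enumerateClassesOracle <- function(m, n, mode) {
  subsets <- utils::combn(m + n, m, simplify = FALSE)
  if (mode == "differential" && m == n) {
    keys <- vapply(subsets, function(s) {
      comp <- setdiff(seq_len(m + n), s)
      paste(pmin(paste(s, collapse = ","), paste(comp, collapse = ",")))
    }, character(1))
    subsets <- subsets[!duplicated(keys)]
  }
  subsets
}

randomScores <- function(d) {
  s <- stats::rnorm(d, sd = 2)
  # inject zeros and exact ties so candidate-set edge cases are exercised
  s[sample.int(d, max(1, d %/% 10))] <- 0
  dup <- sample.int(d, max(1, d %/% 10))
  s[dup] <- s[sample.int(d, length(dup), replace = TRUE)]
  s
}

randomPair <- function(d = 20, m = 2, n = 2, lambda = 5) {
  MeasurementPair(
    matrix(stats::rpois(d * m, lambda), nrow = d),
    matrix(stats::rpois(d * n, lambda), nrow = d)
  )
}
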