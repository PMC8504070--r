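## Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Restores (or removes) the global \code{.Random.seed} afterwards so that
#' seeded plan sampling and data generation never perturb the caller's RNG
#' stream.
#'
#' @param seed integer seed, or \code{NULL} to use the current stream.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
#' @noRd
.withSeed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) {
    return(force(code))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

## Lexicographic unranking of k-subsets of 1..n: maps rank r (0-based) to the
## r-th subset in lexicographic order. Keeps sampled permutation plans
## reproducible across platforms: only the rank is random, not the subset
## construction.
.unrankSubset <- function(r, n, k) {
  stopifnot(r >= 0, r < choose(n, k))
  out <- integer(k)
  x <- 1L
  for (i in seq_len(k)) {
    repeat {
      block <- choose(n - x, k - i)
      if (r < block) break
      r <- r - block
      x <- x + 1L
    }
    out[i] <- x
    x <- x + 1L
  }
  out
}

.checkNumericVector <- function(v, what, allowEmpty = FALSE) {
  if (!is.numeric(v)) {
    stop(sprintf("'%s' must be numeric", what), call. = FALSE)
  }
  if (!allowEmpty && length(v) == 0L) {
    stop(sprintf("'%s' must contain at least one value", what), call. = FALSE)
  }
  if (anyNA(v)) {
    stop(sprintf("'%s' contains missing values", what), call. = FALSE)
  }
  invisible(v)
}

.checkFdrTarget <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q >= 1) {
    stop("target FDR 'q' must be a single number in (0, 1)", call. = FALSE)
  }
  invisible(q)
}

.matchMode <- function(mode) {
  match.arg(mode, c("enrichment", "differential"))
}
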