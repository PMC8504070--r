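#' Number of permutation equivalence classes for a replicate design
#'
#' Permutations of the m + n pooled replicate columns are grouped into
#' equivalence classes by the set of columns they assign to the
#' pseudo-experimental group. For enrichment analysis there are
#' \eqn{\binom{m+n}{m}} classes. For differential analysis the statistic is
#' a magnitude (sign-free), so when m = n a class and its complementary
#' split are identified, leaving \eqn{\binom{2m}{m}/2} classes; for m != n
#' the count is again \eqn{\binom{m+n}{m}}.
#'
#' @param m,n replicate counts (>= 1).
#' @param mode \code{"enrichment"} or \code{"differential"}.
#' @return the number of equivalence classes (identity included).
#' @examples
#' countEquivalenceClasses(2, 1, "enrichment")   # 3
#' countEquivalenceClasses(3, 3, "differential") # 10
#' @export
countEquivalenceClasses <- function(m, n, mode = c("enrichment", "differential")) {
  mode <- match.arg(mode)
  stopifnot(m >= 1, n >= 1)
  if (mode == "differential" && m == n) {
    choose(2 * m, m) / 2
  } else {
    choose(m + n, m)
  }
}

#' Build a permutation plan for contrast-score construction
#'
#' Assembles the identity column assignment plus \code{h} distinct
#' non-identity equivalence classes, sampled uniformly without replacement.
#' Each class is represented by the set of pooled-matrix columns assigned to
#' the pseudo-experimental group (for differential analysis with m = n the
#' representative containing column 1 is used, so a split and its complement
#' are never both present).
#'
#' By default the plan is exhaustive (all \code{h_max} non-identity classes)
#' whenever \code{h_max <= 100}; otherwise 100 classes are sampled with the
#' given seed. Exhaustive plans are seed-independent. Sampling draws class
#' ranks and converts them to column subsets by lexicographic unranking, so
#' a plan is reproducible from \code{(m, n, mode, h, seed)} alone.
#'
#' Differential analysis needs at least two equivalence classes, hence
#' m + n >= 3; a 1vs1 differential design is rejected.
#'
#' @param m,n replicate counts.
#' @param mode \code{"enrichment"} or \code{"differential"}.
#' @param h number of non-identity classes, \code{"max"} for all of them, or
#'   \code{"default"} for the rule above.
#' @param seed integer seed used only when classes are sampled.
#' @return a \linkS4class{PermutationPlan}.
#' @examples
#' plan <- buildPermutationPlan(2, 1, "enrichment", h = "max")
#' plan
#' @export
buildPermutationPlan <- function(m, n, mode = c("enrichment", "differential"),
                                 h = "default", seed = 1L) {
  mode <- match.arg(mode)
  m <- as.integer(m)
  n <- as.integer(n)
  stopifnot(m >= 1L, n >= 1L)
  if (mode == "differential" && m + n < 3L) {
    stop("differential analysis needs at least 3 replicates in total ",
         "(m + n >= 3); a 1vs1 differential design has a single ",
         "equivalence class and cannot be analysed", call. = FALSE)
  }
  total <- countEquivalenceClasses(m, n, mode)
  hMax <- total - 1
  if (identical(h, "default")) {
    h <- min(100, hMax)
  } else if (identical(h, "max")) {
    h <- hMax
  }
  h <- as.integer(h)
  if (is.na(h) || h < 1L || h > hMax) {
    stop(sprintf("'h' must be an integer in [1, %d] (h_max) for this design",
                 hMax), call. = FALSE)
  }
  exhaustive <- (h == hMax)
  ## rank 0 is the identity subset 1:m in lexicographic order, for every
  ## mode; non-identity classes have ranks 1 .. h_max
  ranks <- if (exhaustive) {
    seq_len(hMax)
  } else {
    .withSeed(seed, sample.int(hMax, h, replace = FALSE))
  }
  half <- mode == "differential" && m == n
  classes <- c(
    list(seq_len(m)),
    lapply(ranks, function(r) {
      if (half) {
        ## classes are the m-subsets of 1..2m containing column 1
        c(1L, .unrankSubset(r, 2L * m - 1L, m - 1L) + 1L)
      } else {
        .unrankSubset(r, m + n, m)
      }
    })
  )
  methods::new("PermutationPlan",
    mode = mode, m = m, n = n, classes = classes, h = h,
    seed = if (exhaustive) NA_real_ else as.numeric(seed),
    exhaustive = exhaustive
  )
}

setMethod("show", "PermutationPlan", function(object) {
  cat(sprintf(
    "PermutationPlan (%s, %dvs%d): identity + %d class%s%s\n",
    object@mode, object@m, object@n, object@h,
    if (object@h == 1L) "" else "es",
    if (object@exhaustive) " (exhaustive)"
    else sprintf(" sampled with seed %g", object@seed)
  ))
})

#' Per-class interestingness statistics over all features
#'
#' For every feature j and every equivalence class in the plan, pools the
#' feature's m + n measurements, assigns the class's columns to the
#' pseudo-experimental group, and computes the minus statistic
#' (difference of group means). For differential analysis the absolute value
#' is taken, since departures in either direction are interesting. Column 1
#' of the result corresponds to the identity assignment, i.e., the observed
#' data.
#'
#' @param data a \linkS4class{MeasurementPair}.
#' @param plan a \linkS4class{PermutationPlan} built for the same (m, n).
#' @return a d x (h + 1) numeric matrix of statistics, rownames = feature
#'   IDs, first column named \code{"identity"}.
#' @seealso \code{\link{contrastFromPermutations}}
#' @export
permutedStatistics <- function(data, plan) {
  stopifnot(methods::is(data, "MeasurementPair"),
            methods::is(plan, "PermutationPlan"))
  rc <- replicateCounts(data)
  if (rc[["m"]] != plan@m || rc[["n"]] != plan@n) {
    stop(sprintf(
      "plan was built for a %dvs%d design but data are %dvs%d",
      plan@m, plan@n, rc[["m"]], rc[["n"]]), call. = FALSE)
  }
  w <- cbind(experimentalMatrix(data), backgroundMatrix(data))
  m <- plan@m
  n <- plan@n
  totals <- rowSums(w)
  stats <- vapply(plan@classes, function(cols) {
    sx <- rowSums(w[, cols, drop = FALSE])
    sx / m - (totals - sx) / n
  }, numeric(nrow(w)))
  if (!is.matrix(stats)) stats <- matrix(stats, nrow = 1L)
  if (plan@mode == "differential") stats <- abs(stats)
  dimnames(stats) <- list(
    featureIds(data),
    c("identity", paste0("perm_", seq_len(plan@h)))
  )
  stats
}

#' Contrast scores from permuted statistics
#'
#' Converts each feature's h + 1 per-class statistics (identity first) into
#' a single signed contrast score. Writing \eqn{T^{(0)} \ge \dots \ge
#' T^{(h)}} for the sorted statistics:
#' \describe{
#'   \item{minus score}{\eqn{T^{(0)} - T^{(1)}} when the identity statistic
#'     attains the maximum, else \eqn{T^{(1)} - T^{(0)}}. Ties at the top
#'     give 0.}
#'   \item{maximum score}{\eqn{|T^{(0)}|} when the identity statistic is the
#'     strict, unique maximum; 0 when the top two sorted values tie;
#'     \eqn{-|T^{(0)}|} otherwise.}
#' }
#' A negative score means some random permutation looked more interesting
#' than the observed data, evidence that the feature is null; the
#' symmetric-null behaviour of these scores is what the GZ procedure
#' thresholds.
#'
#' @param stats d x (h + 1) matrix from \code{\link{permutedStatistics}}
#'   (identity statistics in column 1).
#' @param kind \code{"max"} (default, the recommended choice for
#'   permutation-based analyses) or \code{"minus"}.
#' @return numeric vector of d contrast scores.
#' @export
contrastFromPermutations <- function(stats, kind = c("max", "minus")) {
  kind <- match.arg(kind)
  if (!is.matrix(stats) || ncol(stats) < 2L) {
    stop("'stats' must be a matrix with the identity column plus at least ",
         "one permutation column", call. = FALSE)
  }
  s0 <- stats[, 1L]
  top2 <- apply(stats, 1L, function(r) {
    i <- which.max(r)
    c(r[i], max(r[-i]))
  })
  t0 <- top2[1L, ]
  t1 <- top2[2L, ]
  idAtMax <- s0 >= t0 # s0 <= t0 always; equality = identity attains the max
  scores <- if (kind == "minus") {
    ifelse(idAtMax, t0 - t1, t1 - t0)
  } else {
    ifelse(t0 == t1, 0, ifelse(idAtMax, abs(t0), -abs(t0)))
  }
  names(scores) <- rownames(stats)
  scores
}
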