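# Rank-based two-sample statistics and the joint label-permutation null.
#
# All statistics are affine functions of the group-1 rank sum, so the whole
# permutation null is a single (m x n) %*% (n x B) matrix product against a
# matrix of permuted label weights. Statistics are rational with spacing no
# finer than 1/(2*n1*n0); rounding to 8 decimals at construction makes every
# subsequent >= comparison exact despite the BLAS summation order.

.snap <- function(x) round(x, 8L)

STATISTICS <- c("meanrank", "mannwhitney")

#' Row-wise midrank transform
#'
#' Replaces each row of an abundance matrix by the ranks of its values across
#' samples, ties receiving midranks (the mean of the tied rank positions).
#' Zeros, which dominate sparse microbiome tables, therefore tie symmetrically.
#' Every row's ranks sum to n(n+1)/2.
#'
#' @param x abundance matrix (features x samples).
#' @return numeric matrix of the same shape holding midranks.
#' @export
rank_transform <- function(x) {
  validate_abundance(x)
  r <- t(apply(x, 1L, rank, ties.method = "average"))
  if (nrow(x) == 1L) r <- matrix(r, nrow = 1L)
  dimnames(r) <- dimnames(x)
  r
}

# Statistics for each column of a 0/1 label matrix L (n x B), given midranks.
# meanrank:    T = mean rank in group 1 - mean rank in group 0
# mannwhitney: T = U1 - n1*n0/2 = R1 - n1*(n+1)/2  (centered at the null mean)
.stats_from_ranks <- function(ranks, L, statistic, n1, n0) {
  n <- ncol(ranks)
  out <- switch(statistic,
    meanrank    = ranks %*% (L / n1 - (1 - L) / n0),
    mannwhitney = ranks %*% L - n1 * (n + 1) / 2,
    stop("unknown statistic: ", statistic, call. = FALSE)
  )
  .snap(out)
}

#' Two-sample rank statistics per feature
#'
#' Computes, for every feature, either the difference in mean midrank between
#' the two groups (`"meanrank"`) or the Mann-Whitney U statistic centered at
#' its null mean n1*n0/2 (`"mannwhitney"`). Both are affine in the group-1
#' rank sum and therefore order features identically by |T|.
#'
#' @param x abundance matrix.
#' @param groups two-group labelling (see [group_assignment()]); anything
#'   accepted by that constructor.
#' @param statistic `"meanrank"` (default) or `"mannwhitney"`.
#' @return named numeric vector of length `nrow(x)`.
#' @export
compute_statistics <- function(x, groups, statistic = c("meanrank", "mannwhitney")) {
  statistic <- match.arg(statistic)
  labels <- group_assignment(groups)
  check_alignment(x, labels)
  ranks <- rank_transform(x)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  drop(.stats_from_ranks(ranks, cbind(as.numeric(labels)), statistic, n1, n0))
}

new_statistic_profile <- function(observed, permuted, statistic, labels, ranks,
                                  seed = NULL) {
  stopifnot(length(observed) == nrow(permuted), all(is.finite(observed)),
            all(is.finite(permuted)))
  structure(list(
    observed = observed,
    permuted = permuted,
    B = ncol(permuted),
    statistic_name = statistic,
    labels = labels,
    n1 = sum(labels == 1L),
    n0 = sum(labels == 0L),
    ranks = ranks,
    seed = seed
  ), class = "statistic_profile")
}

#' @export
print.statistic_profile <- function(x, ...) {
  cat("Permutation statistic profile\n")
  cat(sprintf("  statistic: %s\n  features:  %d\n  samples:   %d (%d vs %d)\n  permutations: %d\n",
              x$statistic_name, length(x$observed), length(x$labels),
              x$n0, x$n1, x$B))
  invisible(x)
}

#' Build the joint permutation null of the test statistics
#'
#' Computes the observed statistic for every feature, then draws `B` uniform
#' random permutations of the label vector and recomputes all statistics under
#' each. One shared label shuffle per permutation is applied to every feature
#' simultaneously, so the dependence between features is preserved in the
#' null. Permutations are sampled with replacement from the n! arrangements
#' (the identity may recur). The result is deterministic given `seed`
#' (R's default Mersenne-Twister stream).
#'
#' @param x abundance matrix.
#' @param groups two-group labelling.
#' @param statistic `"meanrank"` or `"mannwhitney"`.
#' @param B number of permutations (default 1000).
#' @param seed optional integer seed for the permutation stream.
#' @return a `statistic_profile`: list with `observed` (length m), `permuted`
#'   (m x B), `B`, `statistic_name`, the labels, the midrank matrix and the
#'   seed.
#' @export
build_null <- function(x, groups, statistic = c("meanrank", "mannwhitney"),
                       B = 1000L, seed = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(is.numeric(B), length(B) == 1L, B >= 1)
  B <- as.integer(B)
  labels <- group_assignment(groups)
  check_alignment(x, labels)
  if (!is.null(seed)) set.seed(seed)
  ranks <- rank_transform(x)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  L <- matrix(0, nrow = length(labels), ncol = B)
  for (b in seq_len(B)) L[, b] <- sample(as.numeric(labels))
  observed <- drop(.stats_from_ranks(ranks, cbind(as.numeric(labels)),
                                     statistic, n1, n0))
  permuted <- .stats_from_ranks(ranks, L, statistic, n1, n0)
  new_statistic_profile(observed, permuted, statistic, labels, ranks, seed)
}

#' Exhaustive permutation null for small designs
#'
#' Enumerates every distinct assignment of n1 samples to group 1 (the
#' statistic depends on labels only through that set), giving the exact
#' permutation distribution. Intended for tests, oracles and exact minimal
#' achievable p-values; the number of arrangements choose(n, n1) must be
#' modest.
#'
#' @inheritParams build_null
#' @return a `statistic_profile` whose `permuted` columns enumerate all
#'   choose(n, n1) arrangements (the observed one included).
#' @export
exhaustive_null <- function(x, groups, statistic = c("meanrank", "mannwhitney")) {
  statistic <- match.arg(statistic)
  labels <- group_assignment(groups)
  check_alignment(x, labels)
  n <- length(labels)
  n1 <- sum(labels == 1L)
  K <- choose(n, n1)
  if (K > 1e6) stop("too many arrangements to enumerate: ", K, call. = FALSE)
  sets <- utils::combn(n, n1)
  L <- matrix(0, nrow = n, ncol = ncol(sets))
  L[cbind(as.vector(sets), rep(seq_len(ncol(sets)), each = n1))] <- 1
  ranks <- rank_transform(x)
  n0 <- n - n1
  observed <- drop(.stats_from_ranks(ranks, cbind(as.numeric(labels)),
                                     statistic, n1, n0))
  permuted <- .stats_from_ranks(ranks, L, statistic, n1, n0)
  new_statistic_profile(observed, permuted, statistic, labels, ranks, NULL)
}

#' Two-sided permutation p-values
#'
#' p_j = (1 + #\{b : |T*_jb| >= |T_j|\}) / (B + 1). The add-one convention
#' (counting the observed labelling as one arrangement) makes these valid
#' permutation p-values; the smallest achievable value is 1/(B+1).
#'
#' @param profile a `statistic_profile` from [build_null()] or
#'   [exhaustive_null()].
#' @return numeric vector of p-values in (0, 1].
#' @export
permutation_pvalues <- function(profile) {
  stopifnot(inherits(profile, "statistic_profile"))
  exceed <- rowSums(abs(profile$permuted) >= abs(profile$observed))
  p <- (1 + exceed) / (profile$B + 1)
  names(p) <- names(profile$observed)
  p
}

# Largest |T| attainable for each feature over all relabelings: place the n1
# largest (or smallest) midranks in group 1. Used by the FBH filter.
max_abs_statistic <- function(profile) {
  ranks <- profile$ranks
  n <- ncol(ranks)
  n1 <- profile$n1
  n0 <- profile$n0
  sorted <- t(apply(ranks, 1L, sort))
  if (nrow(ranks) == 1L) sorted <- matrix(sorted, nrow = 1L)
  r1_hi <- rowSums(sorted[, seq.int(n - n1 + 1L, n), drop = FALSE])
  r1_lo <- rowSums(sorted[, seq_len(n1), drop = FALSE])
  total <- n * (n + 1) / 2
  stat_of <- function(r1) {
    if (profile$statistic_name == "meanrank") r1 / n1 - (total - r1) / n0
    else r1 - n1 * (n + 1) / 2
  }
  .snap(pmax(abs(stat_of(r1_hi)), abs(stat_of(r1_lo))))
}
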