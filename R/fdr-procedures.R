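# The three multiple-testing procedures: BH, filtered BH (FBH), and the
# permutation plug-in DS-FDR, plus the adjusted-p-value formulation that
# unifies them.

.Q_TOL <- 1e-12  # tolerance when comparing p-values / FDR estimates to q

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment: with sorted p-values p_(1) <= ... <= p_(m), the
#' adjusted value is min over i >= j of (m/i) p_(i), capped at 1. Rejecting
#' all hypotheses with adjusted value <= q is the BH procedure at level q.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return numeric vector of adjusted p-values in the input order, with
#'   attribute `method = "bh"`.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(pvalues)
  o <- order(pvalues)
  adj_sorted <- pmin(rev(cummin(rev(pvalues[o] * m / seq_len(m)))), 1)
  adj <- numeric(m)
  adj[o] <- adj_sorted
  names(adj) <- names(pvalues)
  attr(adj, "method") <- "bh"
  adj
}

# Minimal achievable p-values for every row of a profile's rank matrix.
# Exact subset enumeration when choose(n, n1) <= enum_cap, otherwise the
# profile's own B-permutation null with the add-one rule.
min_achievable_from_profile <- function(profile, enum_cap = 20000L) {
  n <- length(profile$labels)
  n1 <- profile$n1
  tmax <- max_abs_statistic(profile)
  if (choose(n, n1) <= enum_cap) {
    ex <- exhaustive_profile_like(profile)
    p <- rowMeans(abs(ex$permuted) >= tmax)
  } else {
    p <- (1 + rowSums(abs(profile$permuted) >= tmax)) / (profile$B + 1)
  }
  names(p) <- names(profile$observed)
  p
}

# Exhaustive arrangement statistics reusing an existing profile's ranks.
exhaustive_profile_like <- function(profile) {
  n <- length(profile$labels)
  n1 <- profile$n1
  sets <- utils::combn(n, n1)
  L <- matrix(0, nrow = n, ncol = ncol(sets))
  L[cbind(as.vector(sets), rep(seq_len(ncol(sets)), each = n1))] <- 1
  list(permuted = .stats_from_ranks(profile$ranks, L, profile$statistic_name,
                                    n1, profile$n0))
}

#' Minimal achievable permutation p-value of one feature
#'
#' The smallest two-sided permutation p-value this feature's observed values
#' can produce, attained in the most extreme relabelling (all large values in
#' one group). Computed exactly by enumerating all choose(n, n1) group
#' assignments when that count is at most `enum_cap`, otherwise estimated from
#' `B` sampled permutations with the add-one rule. Features whose minimal
#' achievable p-value exceeds q can never be rejected at level q and are what
#' the FBH filter removes.
#'
#' @param feature_row numeric vector of one feature's values across samples.
#' @param groups two-group labelling.
#' @param statistic `"meanrank"` or `"mannwhitney"`.
#' @param enum_cap maximum number of arrangements enumerated exactly.
#' @param B permutations used when enumeration is infeasible.
#' @param seed optional seed for the fallback permutations.
#' @return a single p-value in (0, 1\].
#' @export
min_achievable_pvalue <- function(feature_row, groups,
                                  statistic = c("meanrank", "mannwhitney"),
                                  enum_cap = 20000L, B = 1000L, seed = NULL) {
  statistic <- match.arg(statistic)
  labels <- group_assignment(groups)
  x <- matrix(as.numeric(feature_row), nrow = 1L,
              dimnames = list("f", paste0("s", seq_along(feature_row))))
  if (choose(length(labels), sum(labels == 1L)) <= enum_cap) {
    profile <- exhaustive_null(x, labels, statistic)
  } else {
    profile <- build_null(x, labels, statistic, B = B, seed = seed)
  }
  unname(min_achievable_from_profile(profile, enum_cap))
}

#' Estimate V-hat, R-hat and the FDR at a cut-point
#'
#' At cut-point C on the absolute statistic, the estimated number of false
#' discoveries is
#' V-hat = sum_j \[ sum_b I(|T*_jb| >= C) + I(|T_j| >= C) \] / (B + 1),
#' the number of discoveries is R-hat = #\{j : |T_j| >= C\}, and the plug-in
#' FDR estimate is V-hat / R-hat (defined as 0 when R-hat = 0, where nothing
#' is rejected). Ties with C count as exceedances (inclusive >=).
#'
#' @param profile a `statistic_profile`.
#' @param C nonnegative cut-point on |T|.
#' @return list with elements `v_hat`, `r_hat`, `fdr_hat`.
#' @export
estimate_fdr_at_cutpoint <- function(profile, C) {
  stopifnot(inherits(profile, "statistic_profile"), C >= 0)
  obs_ge <- abs(profile$observed) >= C
  v_hat <- sum(rowSums(abs(profile$permuted) >= C) + obs_ge) / (profile$B + 1)
  r_hat <- sum(obs_ge)
  list(v_hat = v_hat, r_hat = r_hat,
       fdr_hat = if (r_hat > 0) v_hat / r_hat else 0)
}

#' DS-FDR: select the rejection cut-point controlling the estimated FDR
#'
#' Evaluates the plug-in FDR estimate of [estimate_fdr_at_cutpoint()] at every
#' candidate cut-point (the sorted distinct observed |T_j|; the estimate only
#' changes there) and picks the smallest candidate C-hat whose estimated FDR
#' is at most q, maximising rejections subject to the constraint. If no
#' cut-point qualifies, C-hat is +Inf and nothing is rejected. All hypotheses
#' with |T_j| >= C-hat are rejected.
#'
#' @param profile a `statistic_profile`.
#' @param q target FDR level in (0, 1).
#' @return a `dsfdr_result`: list with the cut-point table (`cutpoints`,
#'   `v_hat`, `r_hat`, `fdr_hat`), the selected `c_hat`, `q` and the logical
#'   `rejected` vector.
#' @export
dsfdr_threshold <- function(profile, q) {
  stopifnot(inherits(profile, "statistic_profile"),
            is.numeric(q), length(q) == 1L, q > 0, q < 1)
  tab <- dsfdr_cutpoint_table(profile)
  obs <- abs(profile$observed)
  cand <- tab$cutpoints
  r_hat <- tab$r_hat
  v_hat <- tab$v_hat
  fdr_hat <- tab$fdr_hat
  ok <- which(fdr_hat <= q + .Q_TOL)
  c_hat <- if (length(ok)) cand[ok[1L]] else Inf
  rejected <- obs >= c_hat
  names(rejected) <- names(profile$observed)
  structure(list(cutpoints = cand, v_hat = v_hat, r_hat = r_hat,
                 fdr_hat = fdr_hat, c_hat = c_hat, q = q,
                 rejected = rejected),
            class = "dsfdr_result")
}

#' @export
print.dsfdr_result <- function(x, ...) {
  cat("DS-FDR result\n")
  cat(sprintf("  q = %g; C-hat = %s; rejected %d of %d features\n",
              x$q, format(x$c_hat), sum(x$rejected), length(x$rejected)))
  if (is.finite(x$c_hat)) {
    i <- match(x$c_hat, x$cutpoints)
    cat(sprintf("  at C-hat: V-hat = %.3f, R-hat = %d, FDR-hat = %.4f\n",
                x$v_hat[i], x$r_hat[i], x$fdr_hat[i]))
  }
  invisible(x)
}

# Cut-point table shared by dsfdr_threshold() and dsfdr_adjusted_pvalues().
# Candidates are the sorted distinct observed |T_j|; exceedance counts are
# obtained by binning (statistics were snapped at construction, so the
# findInterval comparisons are exact).
dsfdr_cutpoint_table <- function(profile) {
  obs <- abs(profile$observed)
  cand <- sort(unique(obs))
  K <- length(cand)
  tail_count <- function(values) {
    idx <- findInterval(values, cand)          # values < cand[1] -> 0
    tab <- tabulate(idx, nbins = K)
    rev(cumsum(rev(tab)))                      # #{v >= cand[i]}
  }
  r_hat <- tail_count(obs)
  v_hat <- (tail_count(abs(profile$permuted)) + r_hat) / (profile$B + 1)
  list(cutpoints = cand, r_hat = r_hat, v_hat = v_hat,
       fdr_hat = ifelse(r_hat > 0, v_hat / r_hat, 0))
}

#' DS-FDR adjusted p-values
#'
#' The discrete step-up adjustment
#' p_(j)^adj = min over i >= j of \[ sum_l Pr_Hl(p_l <= p_(i)) \] / i,
#' with the null probabilities estimated by permutation. In the permutation
#' world the event \{p_l <= p_(i)\} is the statistic event
#' \{|T_l| >= C_i\} at the common cut-point C_i = |T|_(i), and its estimate --
#' feature l's B permuted statistics augmented with its observed one,
#' denominator B + 1, mirroring the add-one p-value convention -- sums over
#' features to exactly the V-hat of [estimate_fdr_at_cutpoint()], while i is
#' the rejection count R-hat at C_i. The adjusted value of feature j is
#' therefore min over cut-points C <= |T_j| of the estimated FDR, capped at 1,
#' and rejecting adjusted <= q reproduces [dsfdr_threshold()] at level q
#' exactly. When all features share one null distribution the adjustment
#' collapses to BH (up to the finite-B term (m - R-hat)/(B+1) in V-hat, at
#' most m/(B+1)).
#'
#' @param profile a `statistic_profile`.
#' @return numeric vector of adjusted p-values (input order), attribute
#'   `method = "dsfdr"`.
#' @export
dsfdr_adjusted_pvalues <- function(profile) {
  stopifnot(inherits(profile, "statistic_profile"))
  tab <- dsfdr_cutpoint_table(profile)
  running_min <- cummin(tab$fdr_hat)  # min FDR-hat over candidates <= C
  idx <- findInterval(abs(profile$observed), tab$cutpoints)
  adj <- pmin(running_min[idx], 1)
  names(adj) <- names(profile$observed)
  attr(adj, "method") <- "dsfdr"
  adj
}

#' Filtered Benjamini-Hochberg (FBH) procedure
#'
#' Two steps: (1) remove hypotheses whose minimal achievable p-value exceeds
#' q -- they can never be significant at the unadjusted q level, so they only
#' inflate the multiplicity burden; (2) apply BH at level q to the permutation
#' p-values of the kept features, with m in the BH formula equal to the kept
#' count. Filtered-out features are never rejected.
#'
#' @param x abundance matrix.
#' @param groups two-group labelling.
#' @param statistic `"meanrank"` or `"mannwhitney"`.
#' @param B number of permutations.
#' @param q target FDR level in (0, 1).
#' @param seed optional permutation seed.
#' @param enum_cap exact-enumeration cap for the minimal achievable p-values.
#' @return list with logical `kept` and `rejected` vectors, `adjusted`
#'   p-values (NA for filtered-out features), the raw permutation p-values
#'   and the minimal achievable p-values.
#' @export
fbh_procedure <- function(x, groups, statistic = c("meanrank", "mannwhitney"),
                          B = 1000L, q = 0.1, seed = NULL, enum_cap = 20000L) {
  statistic <- match.arg(statistic)
  profile <- build_null(x, groups, statistic, B = B, seed = seed)
  fbh_from_profile(profile, q, enum_cap)
}

fbh_from_profile <- function(profile, q, enum_cap = 20000L) {
  stopifnot(q > 0, q < 1)
  min_p <- min_achievable_from_profile(profile, enum_cap)
  kept <- min_p <= q + .Q_TOL
  p <- permutation_pvalues(profile)
  m <- length(p)
  rejected <- logical(m)
  adjusted <- rep(NA_real_, m)
  if (any(kept)) {
    adj_kept <- bh_adjust(p[kept])
    adjusted[kept] <- adj_kept
    rejected[kept] <- adj_kept <= q + .Q_TOL
  }
  names(rejected) <- names(adjusted) <- names(p)
  list(kept = kept, rejected = rejected, adjusted = adjusted,
       pvalues = p, min_achievable = min_p, q = q)
}

# One rejection vector per method name, sharing a single profile.
apply_procedure <- function(profile, method, q, enum_cap = 20000L) {
  switch(method,
    dsfdr = dsfdr_threshold(profile, q)$rejected,
    bh    = bh_adjust(permutation_pvalues(profile)) <= q + .Q_TOL,
    fbh   = fbh_from_profile(profile, q, enum_cap)$rejected,
    stop("unknown method: ", method, call. = FALSE)
  )
}

#' Differential-abundance test with discrete FDR control
#'
#' The main user-facing entry point: builds the joint permutation null once
#' and applies the chosen multiple-testing procedure. `"dsfdr"` thresholds the
#' absolute statistic directly at the plug-in FDR estimate; `"bh"` applies
#' Benjamini-Hochberg to the permutation p-values; `"fbh"` first drops
#' features that cannot reach significance, then applies BH to the remainder.
#'
#' @param x abundance matrix (features x samples; see [abundance_matrix()]).
#' @param groups two-group labelling aligned to the columns of `x`.
#' @param method `"dsfdr"` (default), `"bh"` or `"fbh"`.
#' @param statistic `"meanrank"` (default) or `"mannwhitney"`.
#' @param q target FDR level (default 0.1).
#' @param B number of label permutations (default 1000).
#' @param seed optional integer seed making the permutation stream
#'   reproducible.
#' @param enum_cap exact-enumeration cap used by the FBH filter.
#' @return a `dsfdr_test` object: list with a per-feature `table`
#'   (feature_id, statistic, raw_p, adjusted_p, rejected), the call
#'   parameters, and method detail (`dsfdr_result` for DS-FDR, filter
#'   information for FBH).
#' @examples
#' set.seed(1)
#' x <- abundance_matrix(matrix(rpois(300, 5), 20, 15,
#'        dimnames = list(paste0("taxon", 1:20), paste0("s", 1:15))))
#' x[1:3, 8:15] <- x[1:3, 8:15] * 4
#' res <- dsfdr_test(x, rep(c("healthy", "sick"), c(7, 8)), seed = 42)
#' res
#' @export
dsfdr_test <- function(x, groups, method = c("dsfdr", "bh", "fbh"),
                       statistic = c("meanrank", "mannwhitney"),
                       q = 0.1, B = 1000L, seed = NULL, enum_cap = 20000L) {
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  stopifnot(q > 0, q < 1)
  profile <- build_null(x, groups, statistic, B = B, seed = seed)
  p <- permutation_pvalues(profile)
  detail <- NULL
  if (method == "dsfdr") {
    detail <- dsfdr_threshold(profile, q)
    rejected <- detail$rejected
    adjusted <- dsfdr_adjusted_pvalues(profile)
  } else if (method == "bh") {
    adjusted <- bh_adjust(p)
    rejected <- adjusted <= q + .Q_TOL
  } else {
    detail <- fbh_from_profile(profile, q, enum_cap)
    rejected <- detail$rejected
    adjusted <- detail$adjusted
  }
  tab <- data.frame(
    feature_id = rownames(x),
    statistic = unname(profile$observed),
    raw_p = unname(p),
    adjusted_p = unname(adjusted),
    rejected = unname(rejected),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, method = method, statistic_name = statistic,
                 q = q, B = as.integer(B), seed = seed, detail = detail,
                 profile = profile),
            class = "dsfdr_test")
}

#' @export
print.dsfdr_test <- function(x, ...) {
  cat(sprintf("Differential abundance test (%s, %s statistic)\n",
              toupper(x$method), x$statistic_name))
  cat(sprintf("  %d features, %d permutations, q = %g\n",
              nrow(x$table), x$B, x$q))
  cat(sprintf("  rejected: %d\n", sum(x$table$rejected)))
  top <- x$table[order(x$table$raw_p), ]
  top <- utils::head(top[top$rejected, ], 5L)
  if (nrow(top)) {
    cat("  top discoveries:\n")
    print(top, row.names = FALSE)
  }
  invisible(x)
}
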