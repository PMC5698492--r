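# Shared fixtures and independent oracles. The oracles deliberately avoid the
# package's matrix-product code path: statistics are computed row by row with
# base rank()/mean(), and permutation distributions by explicit subset
# enumeration.

toy_matrix <- function(m, n, lambda = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  abundance_matrix(matrix(rpois(m * n, lambda), m, n,
                          dimnames = list(sprintf("f%02d", seq_len(m)),
                                          sprintf("s%02d", seq_len(n)))))
}

# mean-rank difference computed directly (group 1 minus group 0)
oracle_meanrank <- function(row, labels) {
  r <- rank(row, ties.method = "average")
  mean(r[labels == 1]) - mean(r[labels == 0])
}

# exact permutation distribution of the mean-rank statistic for one row:
# one value per subset of size n1 assigned to group 1
oracle_enumeration <- function(row, n1) {
  n <- length(row)
  sets <- utils::combn(n, n1)
  apply(sets, 2L, function(g1) {
    labels <- integer(n)
    labels[g1] <- 1L
    oracle_meanrank(row, labels)
  })
}

# the hand-evaluated worked profile: m = 2 features, B = 4 permutations
worked_profile <- function() {
  structure(list(
    observed = c(f1 = 10, f2 = 2),
    permuted = rbind(f1 = c(1, 2, 1, 3), f2 = c(2, 1, 2, 1)),
    B = 4L, statistic_name = "meanrank",
    labels = structure(c(0L, 0L, 1L, 1L), group_names = c("0", "1")),
    n1 = 2L, n0 = 2L, ranks = NULL, seed = NULL
  ), class = "statistic_profile")
}

# small sparse community for procedure-level tests (fast: B a few hundred)
small_community <- function(seed, n_per_group = 15) {
  simulate_community(simulation_spec(
    n_per_group = n_per_group, n_differential = 15L, n_null = 25L,
    n_rare = 110L, seed = seed))
}
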