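test_that("rank_transform assigns midranks and preserves row rank sums", {
  x <- abundance_matrix(rbind(a = c(0, 0, 5, 3), b = c(7, 7, 7, 7),
                              c = c(1, 2, 3, 4)),
                        sample_ids = paste0("s", 1:4))
  r <- rank_transform(x)
  expect_equal(unname(r["a", ]), c(1.5, 1.5, 4, 3))
  expect_equal(unname(r["b", ]), rep(2.5, 4))
  expect_equal(unname(r["c", ]), 1:4 + 0)

  for (seed in 1:5) {
    x <- toy_matrix(12, sample(4:9, 1), seed = seed)
    n <- ncol(x)
    expect_equal(unname(rowSums(rank_transform(x))),
                 rep(n * (n + 1) / 2, nrow(x)))
  }
})

test_that("compute_statistics matches hand evaluation and is label-antisymmetric", {
  x <- abundance_matrix(rbind(a = c(0, 0, 5, 3), b = c(4, 4, 4, 4)),
                        sample_ids = paste0("s", 1:4))
  g <- c(0, 0, 1, 1)
  t_mr <- compute_statistics(x, g, "meanrank")
  expect_equal(unname(t_mr), c(3.5 - 1.5, 0))

  # antisymmetry under label swap
  for (seed in 1:5) {
    x <- toy_matrix(8, 10, seed = seed)
    g <- rep(c(0, 1), each = 5)
    expect_equal(compute_statistics(x, g),
                 -compute_statistics(x, 1 - g))
  }

  expect_error(compute_statistics(x, rep(1, 10)), "nonempty")
  expect_error(compute_statistics(toy_matrix(2, 4, seed = 1), c(0, 0, 1, 1),
                                  "median"), "arg")
})

test_that("meanrank and centered Mann-Whitney order |T| identically", {
  for (seed in 1:8) {
    x <- toy_matrix(5, 6, seed = seed)
    g <- c(0, 0, 0, 1, 1, 1)
    t1 <- abs(compute_statistics(x, g, "meanrank"))
    t2 <- abs(compute_statistics(x, g, "mannwhitney"))
    expect_equal(order(t1), order(t2))
    # both affine in the group-1 rank sum: exact proportionality here
    expect_equal(t1 * 3 * 3 / 6, t2)
  }
})

test_that("exhaustive_null reproduces the enumeration oracle on 3x4 matrices", {
  for (seed in 1:6) {
    x <- toy_matrix(3, 4, seed = seed)
    g <- c(0, 0, 1, 1)
    prof <- exhaustive_null(x, g)
    expect_equal(prof$B, choose(4, 2))
    for (j in 1:3) {
      expect_equal(sort(prof$permuted[j, ]),
                   sort(oracle_enumeration(x[j, ], 2)))
    }
    expect_equal(unname(prof$observed),
                 vapply(1:3, function(j) oracle_meanrank(x[j, ], g), 0))
  }
})

test_that("build_null is deterministic given a seed and null on constant rows", {
  x <- toy_matrix(6, 10, seed = 3)
  x[4, ] <- 5  # constant feature
  g <- rep(c(0, 1), each = 5)
  p1 <- build_null(x, g, B = 50, seed = 99)
  p2 <- build_null(x, g, B = 50, seed = 99)
  expect_identical(p1$permuted, p2$permuted)
  expect_identical(p1$observed, p2$observed)
  expect_true(all(p1$permuted[4, ] == 0))
  expect_equal(unname(p1$observed[4]), 0)
  expect_equal(dim(p1$permuted), c(6L, 50L))
})

test_that("permutation null is invariant to per-feature monotone transforms", {
  x <- toy_matrix(7, 8, seed = 5)
  g <- rep(c(0, 1), each = 4)
  p1 <- build_null(x, g, B = 40, seed = 7)
  y <- abundance_matrix(sqrt(x) * 10 + 1, rownames(x), colnames(x))
  p2 <- build_null(y, g, B = 40, seed = 7)
  expect_identical(p1$permuted, p2$permuted)
  expect_identical(p1$observed, p2$observed)
})

test_that("permutation p-values follow the add-one rule and match enumeration", {
  prof <- worked_profile()
  prof$observed <- c(f1 = 5, f2 = 0)
  prof$permuted <- rbind(f1 = c(1, 2, 3), f2 = c(0, 0, 0))
  prof$B <- 3L
  p <- permutation_pvalues(prof)
  expect_equal(unname(p), c(1 / 4, 1))

  # exhaustive p-values agree with the oracle up to the add-one convention
  for (seed in 1:5) {
    x <- toy_matrix(3, 4, seed = 10 + seed)
    g <- c(0, 0, 1, 1)
    prof <- exhaustive_null(x, g)
    K <- prof$B
    p_pkg <- permutation_pvalues(prof)
    for (j in 1:3) {
      null_t <- oracle_enumeration(x[j, ], 2)
      obs <- oracle_meanrank(x[j, ], g)
      p_exact <- mean(abs(null_t) >= abs(obs) - 1e-12)
      expect_equal(unname(p_pkg[j]), (K * p_exact + 1) / (K + 1))
    }
  }
})

test_that("input validation rejects malformed tables and labellings", {
  expect_error(abundance_matrix(matrix(c(1, -2, 3, 4), 2, 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))), "negative.*b")
  expect_error(abundance_matrix(matrix(c(1, NA, 3, 4), 2, 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))), "missing")
  expect_error(abundance_matrix(matrix(1:4, 2, 2,
               dimnames = list(c("a", "a"), c("s1", "s2")))), "duplicate")
  expect_error(group_assignment(c("x", "y", "z")), "2 distinct")
  expect_error(group_assignment(rep("x", 4)), "2 distinct")
})
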