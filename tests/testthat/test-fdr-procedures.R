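test_that("bh_adjust evaluates the min-over-tail formula and matches p.adjust", {
  expect_equal(as.numeric(bh_adjust(c(0.01, 0.02, 0.03))), rep(0.03, 3))
  expect_equal(as.numeric(bh_adjust(0.05)), 0.05)
  expect_equal(as.numeric(bh_adjust(c(0.5, 0.04))), c(0.5, 0.08))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(1)
  for (i in 1:5) {
    p <- runif(sample(3:40, 1))
    expect_equal(as.numeric(bh_adjust(p)), p.adjust(p, method = "BH"))
  }
})

test_that("minimal achievable p-values are exact on enumerable designs", {
  g <- rep(c(0, 1), each = 5)
  expect_equal(min_achievable_pvalue(rep(0, 10), g), 1)
  expect_equal(min_achievable_pvalue(c(9, rep(0, 9)), g), 1)
  # three tied nonzeros: extreme iff all three in one group
  expect_equal(min_achievable_pvalue(c(4, 4, 4, rep(0, 7)), g),
               2 * choose(5, 3) / choose(10, 3))
  # distinct values, balanced design: unique extreme arrangement per side
  expect_equal(min_achievable_pvalue(c(1, 2, 3, 4), c(0, 0, 1, 1)),
               2 / choose(4, 2))
})

test_that("estimate_fdr_at_cutpoint reproduces the hand-evaluated profile", {
  prof <- worked_profile()
  at10 <- estimate_fdr_at_cutpoint(prof, 10)
  expect_equal(at10, list(v_hat = 0.2, r_hat = 1L, fdr_hat = 0.2))
  at2 <- estimate_fdr_at_cutpoint(prof, 2)
  expect_equal(at2$v_hat, 1.2)
  expect_equal(at2$r_hat, 2L)
  expect_equal(at2$fdr_hat, 0.6)
  beyond <- estimate_fdr_at_cutpoint(prof, 99)
  expect_equal(beyond, list(v_hat = 0, r_hat = 0L, fdr_hat = 0))
})

test_that("estimate_fdr_at_cutpoint agrees with a brute-force double loop", {
  set.seed(20)
  for (i in 1:5) {
    m <- sample(2:6, 1); B <- sample(3:9, 1)
    prof <- worked_profile()
    prof$observed <- round(rnorm(m), 1)
    prof$permuted <- matrix(round(rnorm(m * B), 1), m, B)
    prof$B <- B
    for (C in c(0, 0.5, 1.5)) {
      v <- 0; r <- 0
      for (j in seq_len(m)) {
        cnt <- sum(abs(prof$permuted[j, ]) >= C) + (abs(prof$observed[j]) >= C)
        v <- v + cnt / (B + 1)
        r <- r + (abs(prof$observed[j]) >= C)
      }
      est <- estimate_fdr_at_cutpoint(prof, C)
      expect_equal(est$v_hat, v)
      expect_equal(est$r_hat, r)
      expect_equal(est$fdr_hat, if (r > 0) v / r else 0)
    }
  }
})

test_that("dsfdr_threshold selects the smallest qualifying cut-point", {
  prof <- worked_profile()
  r1 <- dsfdr_threshold(prof, 0.25)
  expect_equal(r1$c_hat, 10)
  expect_equal(unname(r1$rejected), c(TRUE, FALSE))
  expect_equal(r1$cutpoints, c(2, 10))
  expect_equal(r1$fdr_hat, c(0.6, 0.2))

  r2 <- dsfdr_threshold(prof, 0.7)
  expect_equal(r2$c_hat, 2)
  expect_true(all(r2$rejected))

  # no qualifying cut-point: C-hat infinite, nothing rejected
  prof$permuted <- rbind(f1 = rep(11, 4), f2 = rep(11, 4))
  r3 <- dsfdr_threshold(prof, 0.1)
  expect_identical(r3$c_hat, Inf)
  expect_false(any(r3$rejected))

  # structural invariants on a random profile
  prof <- build_null(toy_matrix(25, 12, seed = 2), rep(c(0, 1), each = 6),
                     B = 99, seed = 5)
  res <- dsfdr_threshold(prof, 0.1)
  expect_true(all(diff(res$r_hat) <= 0))
  expect_true(all(diff(res$v_hat) <= 1e-12))
  if (is.finite(res$c_hat)) {
    i <- match(res$c_hat, res$cutpoints)
    expect_lte(res$fdr_hat[i], 0.1 + 1e-12)
    expect_equal(unname(res$rejected),
                 unname(abs(prof$observed) >= res$c_hat))
  }
})

test_that("dsfdr adjusted p-values threshold exactly like the cut-point rule", {
  qgrid <- seq(0.05, 0.95, by = 0.05)
  set.seed(123)
  for (i in 1:40) {
    x <- toy_matrix(3, 4, lambda = 2)
    prof <- exhaustive_null(x, c(0, 0, 1, 1))
    adj <- dsfdr_adjusted_pvalues(prof)
    expect_true(all(adj >= 0 & adj <= 1))
    for (q in qgrid) {
      expect_identical(unname(dsfdr_threshold(prof, q)$rejected),
                       unname(adj <= q + 1e-12))
    }
  }
  # sampled permutations too
  for (seed in 1:5) {
    prof <- build_null(toy_matrix(10, 10, seed = seed),
                       rep(c(0, 1), each = 5), B = 60, seed = seed)
    adj <- dsfdr_adjusted_pvalues(prof)
    for (q in c(0.05, 0.1, 0.3)) {
      expect_identical(unname(dsfdr_threshold(prof, q)$rejected),
                       unname(adj <= q + 1e-12))
    }
  }
})

test_that("single-hypothesis dsfdr adjustment reduces to the raw p-value", {
  x <- abundance_matrix(matrix(c(3, 0, 5, 1, 2, 4), 1, 6,
         dimnames = list("f", paste0("s", 1:6))))
  prof <- build_null(x, rep(c(0, 1), each = 3), B = 30, seed = 4)
  expect_equal(as.numeric(dsfdr_adjusted_pvalues(prof)),
               as.numeric(permutation_pvalues(prof)))
})

test_that("identical per-feature nulls collapse DS-FDR towards BH", {
  # literally identical nulls: rows are monotone transforms of one sample
  base <- c(5, 1, 9, 3, 7, 2, 8, 4)
  x <- abundance_matrix(rbind(a = base, b = base^2, c = 10 * base),
                        sample_ids = paste0("s", 1:8))
  prof <- build_null(x, rep(c(0, 1), each = 4), B = 50, seed = 8)
  p <- permutation_pvalues(prof)
  expect_equal(length(unique(p)), 1L)
  for (q in c(0.05, 0.2, 0.5, 0.9)) {
    expect_identical(unname(dsfdr_threshold(prof, q)$rejected),
                     unname(bh_adjust(p) <= q + 1e-12))
  }

  # identical null *margins* (no ties): DS adjusted <= BH adjusted,
  # agreeing within the finite-B term m/(B+1)
  set.seed(42)
  for (i in 1:10) {
    m <- sample(4:8, 1)
    x <- abundance_matrix(matrix(runif(m * 8), m, 8,
           dimnames = list(paste0("f", 1:m), paste0("s", 1:8))))
    prof <- exhaustive_null(x, rep(c(0, 1), each = 4))
    adj <- dsfdr_adjusted_pvalues(prof)
    bh <- bh_adjust(permutation_pvalues(prof))
    expect_true(all(adj <= bh + 1e-12))
    expect_lt(max(bh - adj), m / (prof$B + 1) + 1e-12)
  }
})

test_that("FBH filters hopeless features and then dominates BH", {
  # all-zero features: min achievable p = 1, kept none, nothing rejected
  x0 <- abundance_matrix(matrix(0, 3, 10,
          dimnames = list(paste0("f", 1:3), paste0("s", 1:10))))
  r0 <- fbh_procedure(x0, rep(c(0, 1), each = 5), B = 50, q = 0.1, seed = 1)
  expect_false(any(r0$kept))
  expect_false(any(r0$rejected))

  # three singleton-presence features (unfilterable signal) plus three
  # strongly separated features: FBH rejects at least as many as BH-on-all
  set.seed(9)
  strong <- t(vapply(1:3, function(i) c(rpois(5, 2), rpois(5, 60) + 20),
                     numeric(10)))
  single <- t(vapply(1:3, function(i) {
    row <- rep(0, 10); row[sample(10, 1)] <- 7; row
  }, numeric(10)))
  x <- abundance_matrix(rbind(strong, single),
                        feature_ids = paste0("f", 1:6),
                        sample_ids = paste0("s", 1:10))
  g <- rep(c(0, 1), each = 5)
  fbh <- fbh_procedure(x, g, B = 400, q = 0.1, seed = 2)
  expect_equal(unname(fbh$kept), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  prof <- build_null(x, g, B = 400, seed = 2)
  bh_rej <- bh_adjust(permutation_pvalues(prof)) <= 0.1 + 1e-12
  expect_true(all(fbh$rejected[bh_rej]))
  expect_gte(sum(fbh$rejected), sum(bh_rej))

  # when no feature is filtered, FBH is exactly BH on the full set
  xf <- toy_matrix(6, 8, lambda = 8, seed = 33)
  gf <- rep(c(0, 1), each = 4)
  rf <- fbh_procedure(xf, gf, B = 200, q = 0.5, seed = 3)
  expect_true(all(rf$kept))
  proff <- build_null(xf, gf, B = 200, seed = 3)
  expect_equal(unname(rf$rejected),
               unname(bh_adjust(permutation_pvalues(proff)) <= 0.5 + 1e-12))
})

test_that("dsfdr_test returns a coherent per-feature table for each method", {
  ds <- small_community(77)
  for (meth in c("dsfdr", "bh", "fbh")) {
    res <- dsfdr_test(ds$matrix, ds$groups, method = meth, B = 200, seed = 11)
    expect_s3_class(res, "dsfdr_test")
    expect_named(res$table,
                 c("feature_id", "statistic", "raw_p", "adjusted_p", "rejected"))
    expect_equal(nrow(res$table), nrow(ds$matrix))
    expect_true(all(res$table$raw_p > 0 & res$table$raw_p <= 1))
    ok <- !is.na(res$table$adjusted_p)
    expect_true(all(res$table$adjusted_p[ok] >= res$table$raw_p[ok] - 1e-12 |
                    meth == "dsfdr"))
  }
  # determinism of the full pipeline
  r1 <- dsfdr_test(ds$matrix, ds$groups, B = 150, seed = 21)
  r2 <- dsfdr_test(ds$matrix, ds$groups, B = 150, seed = 21)
  expect_identical(r1$table, r2$table)
})
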