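# Replicate-based estimation of FDR and power for any procedure, plus the
# abundance-filter sweep and subsample power-curve harnesses.

#' False discovery proportion of one analysis
#'
#' FDP = (false rejections) / max(rejections, 1): the per-dataset realisation
#' whose expectation over replicates is the FDR.
#'
#' @param rejected logical rejection vector.
#' @param truth logical vector marking truly differential features.
#' @return a proportion in \[0, 1\].
#' @export
false_discovery_proportion <- function(rejected, truth) {
  if (length(rejected) != length(truth))
    stop("rejected and truth have different lengths", call. = FALSE)
  sum(rejected & !truth) / max(sum(rejected), 1L)
}

# Per-replicate seeds are derived from the master seed by a fixed counter
# scheme: dataset seed = seed + r, permutation seed = seed + r + 100000.
# Replicates are therefore reproducible and mutually independent streams.
replicate_seeds <- function(seed, r) {
  list(data = seed + r, perm = seed + r + 100000L)
}

#' Estimate FDR and power of the procedures over replicates
#'
#' Repeatedly draws a dataset from `generator`, builds one shared permutation
#' null per replicate, applies every requested procedure to it, and
#' accumulates per-replicate false discovery proportions and true-discovery
#' counts. Replication stops when the Monte-Carlo standard error of every
#' method's FDR estimate falls below `se_target`, or at `max_replicates`.
#'
#' @param generator function taking one integer seed and returning a
#'   `simulated_dataset` (e.g. `function(s) simulate_community(simulation_spec(50, seed = s))`).
#' @param methods character vector among `"dsfdr"`, `"fbh"`, `"bh"`.
#' @param q target FDR level.
#' @param B permutations per replicate.
#' @param statistic test statistic name.
#' @param max_replicates upper bound on replicates (>= 2).
#' @param se_target stop once every method's se(FDR) is below this; an
#'   infinite value disables the stopping rule so that exactly
#'   `max_replicates` replicates run.
#' @param seed master seed; per-replicate seeds are derived from it by a
#'   fixed counter scheme.
#' @param enum_cap exact-enumeration cap for the FBH filter.
#' @return data.frame with one row per method: `method`, `q`, `B`,
#'   `replicates`, `mean_fdr`, `se_fdr`, `mean_true_discoveries`,
#'   `mean_discoveries`, `prop_true_discovered`, `m0`.
#' @export
run_replicates <- function(generator, methods = c("dsfdr", "fbh", "bh"),
                           q = 0.1, B = 1000L,
                           statistic = c("meanrank", "mannwhitney"),
                           max_replicates = 50L, se_target = 0.001,
                           seed = 1L, enum_cap = 20000L) {
  statistic <- match.arg(statistic)
  methods <- match.arg(methods, c("dsfdr", "fbh", "bh"), several.ok = TRUE)
  stopifnot(max_replicates >= 2L)
  fdp <- matrix(NA_real_, nrow = max_replicates, ncol = length(methods),
                dimnames = list(NULL, methods))
  td <- fdp
  disc <- fdp
  m0 <- NA_integer_
  n_truth <- NA_integer_
  done <- 0L
  for (r in seq_len(max_replicates)) {
    s <- replicate_seeds(seed, r)
    ds <- generator(s$data)
    profile <- build_null(ds$matrix, ds$groups, statistic, B = B,
                          seed = s$perm)
    for (meth in methods) {
      rej <- apply_procedure(profile, meth, q, enum_cap)
      fdp[r, meth] <- false_discovery_proportion(rej, ds$truth)
      td[r, meth] <- sum(rej & ds$truth)
      disc[r, meth] <- sum(rej)
    }
    m0 <- sum(!ds$truth)
    n_truth <- sum(ds$truth)
    done <- r
    if (r >= 2L && is.finite(se_target)) {
      se <- apply(fdp[seq_len(r), , drop = FALSE], 2L, stats::sd) / sqrt(r)
      if (all(se < se_target)) break
    }
  }
  idx <- seq_len(done)
  data.frame(
    method = methods,
    q = q,
    B = as.integer(B),
    replicates = done,
    mean_fdr = colMeans(fdp[idx, , drop = FALSE]),
    se_fdr = apply(fdp[idx, , drop = FALSE], 2L, stats::sd) / sqrt(done),
    mean_true_discoveries = colMeans(td[idx, , drop = FALSE]),
    mean_discoveries = colMeans(disc[idx, , drop = FALSE]),
    prop_true_discovered = if (n_truth > 0)
      colMeans(td[idx, , drop = FALSE]) / n_truth else rep(0, length(methods)),
    m0 = m0,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Discovery counts as a function of the abundance-filtering level
#'
#' For each threshold, removes features with total abundance below it
#' ([filter_taxa()]), reruns every procedure on the filtered table and records
#' the rejection count. Mirrors the question of how sensitive each procedure
#' is to the (arbitrary) low-abundance filter.
#'
#' @param x abundance matrix.
#' @param groups two-group labelling.
#' @param filter_levels ascending nonnegative thresholds.
#' @param methods procedures to run.
#' @param q,B,statistic,seed,enum_cap as in [run_replicates()].
#' @return data.frame with columns `filter_level`, `n_taxa`, `method`,
#'   `discoveries`.
#' @export
filter_sweep <- function(x, groups, filter_levels,
                         methods = c("dsfdr", "fbh", "bh"), q = 0.1,
                         B = 1000L, statistic = c("meanrank", "mannwhitney"),
                         seed = 1L, enum_cap = 20000L) {
  statistic <- match.arg(statistic)
  stopifnot(all(filter_levels >= 0), !is.unsorted(filter_levels))
  labels <- group_assignment(groups)
  rows <- list()
  for (i in seq_along(filter_levels)) {
    lev <- filter_levels[i]
    xf <- suppressWarnings(filter_taxa(x, lev))
    for (meth in methods) {
      n_disc <- 0L
      if (nrow(xf) > 0L) {
        profile <- build_null(xf, labels, statistic, B = B, seed = seed + i)
        n_disc <- sum(apply_procedure(profile, meth, q, enum_cap))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        filter_level = lev, n_taxa = nrow(xf), method = meth,
        discoveries = n_disc, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Discovery counts as a function of the per-group sample size
#'
#' For each size, repeatedly subsamples that many samples per group without
#' replacement, runs every procedure and averages the discovery counts --
#' how many samples each procedure needs to find a given number of
#' differentially abundant features.
#'
#' @param x abundance matrix.
#' @param groups two-group labelling.
#' @param sizes per-group subsample sizes, each at most the smaller group.
#' @param methods procedures to run.
#' @param replicates subsample draws per size.
#' @param q,B,statistic,seed,enum_cap as in [run_replicates()].
#' @return data.frame with columns `size`, `method`, `mean_discoveries`.
#' @export
subsample_power_curve <- function(x, groups, sizes,
                                  methods = c("dsfdr", "fbh", "bh"),
                                  q = 0.1, B = 1000L,
                                  statistic = c("meanrank", "mannwhitney"),
                                  replicates = 10L, seed = 1L,
                                  enum_cap = 20000L) {
  statistic <- match.arg(statistic)
  labels <- group_assignment(groups)
  check_alignment(x, labels)
  g0 <- which(labels == 0L)
  g1 <- which(labels == 1L)
  if (any(sizes > min(length(g0), length(g1))))
    stop("subsample size exceeds the smaller group (",
         min(length(g0), length(g1)), ")", call. = FALSE)
  rows <- list()
  for (i in seq_along(sizes)) {
    sz <- sizes[i]
    disc <- matrix(0, nrow = replicates, ncol = length(methods),
                   dimnames = list(NULL, methods))
    for (r in seq_len(replicates)) {
      set.seed(seed + 1000L * i + r)
      cols <- c(sort(sample(g0, sz)), sort(sample(g1, sz)))
      sub_labels <- group_assignment(labels[cols])
      profile <- build_null(x[, cols, drop = FALSE], sub_labels, statistic,
                            B = B, seed = seed + 1000L * i + r + 100000L)
      for (meth in methods)
        disc[r, meth] <- sum(apply_procedure(profile, meth, q, enum_cap))
    }
    for (meth in methods)
      rows[[length(rows) + 1L]] <- data.frame(
        size = sz, method = meth, mean_discoveries = mean(disc[, meth]),
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Shipped simulation presets
#'
#' Returns a generator closure (a function of one seed) for the named preset:
#' * `"sim1"`: the standard community (100 differential, 100 null, 800 rare
#'   taxa) at a given `n_per_group`; the sample-size sweep scenario.
#' * `"sim2"`: 50 samples per group with a configurable rare-taxon count
#'   (`n_rare`); the sparsity sweep scenario.
#' * `"null"`: the same community with no differential block (global null).
#'
#' @param preset one of `"sim1"`, `"sim2"`, `"null"`.
#' @param n_per_group samples per group (default 50 for `"sim2"`, required
#'   for the others).
#' @param n_rare rare-taxon count (default 800; swept in `"sim2"`).
#' @param ... further arguments passed to [simulation_spec()].
#' @return function(seed) returning a `simulated_dataset`.
#' @export
simulation_preset <- function(preset = c("sim1", "sim2", "null"),
                              n_per_group = 50L, n_rare = 800L, ...) {
  preset <- match.arg(preset)
  args <- list(...)
  function(seed) {
    spec_args <- switch(preset,
      sim1 = list(n_per_group = n_per_group, n_rare = n_rare),
      sim2 = list(n_per_group = n_per_group, n_rare = n_rare),
      null = list(n_per_group = n_per_group, n_rare = n_rare,
                  n_differential = 0L))
    spec_args$seed <- seed
    extra <- args[setdiff(names(args), names(spec_args))]
    simulate_community(do.call(simulation_spec, c(spec_args, extra)))
  }
}
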