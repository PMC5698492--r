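# Simulated sparse microbiome communities and the data-driven resample-split
# and signal-spiking protocols. The generators are the package's ground-truth
# test bed: a block of truly differential taxa, a block of null taxa, and a
# large block of rare taxa present in very few samples (the multiplicity
# burden that makes rank statistics discrete).

#' Specify a simulated two-group community
#'
#' Parameters of the multinomial community generator. Each group's samples
#' are multinomial draws of `reads_per_sample` reads from a group-specific
#' frequency vector. Baseline taxon frequencies for the differential and null
#' blocks are drawn log-uniformly over `freq_range` (heavy-tailed, mimicking
#' real taxon-abundance skew); in the sick group the differential taxa's
#' frequencies are multiplied by `effect_size` (alternating direction: up,
#' down, up, ...) and the block is renormalised to its baseline total, so
#' null taxa keep identical relative frequencies in both groups and are not
#' dragged along compositionally. Rare taxa carry
#' frequency zero in the multinomial and are instead injected post hoc: each
#' is made nonzero in at most `rare_presence` randomly chosen samples
#' (irrespective of group, hence truly null) with small uniform counts in
#' 1..`rare_max_count`.
#'
#' Defaults are the package's standard community: 100 differential, 100 null
#' and 800 rare taxa, effect size 1.3, depth 2000 reads, baseline frequencies
#' in \[2e-4, 1e-3\] (0.4--2 expected reads per sample, so counts are sparse
#' and their rank statistics markedly discrete) -- a regime in which all
#' procedures control the FDR at q = 0.1 while differing visibly in power,
#' with the discrete procedure's advantage largest at small sample sizes.
#'
#' @param n_per_group samples per group (N).
#' @param n_differential truly differential taxa.
#' @param n_null null taxa drawn from the shared baseline.
#' @param n_rare rare null taxa present in very few samples.
#' @param effect_size multiplier on differential taxa's frequency in the sick
#'   group; must differ from 1 when `n_differential > 0`.
#' @param effect_heterogeneity spread of per-taxon effects: taxon i receives
#'   the multiplier `effect_size^(1 + h*v_i)` with `v_i ~ Uniform(-1, 1)`, so
#'   at `h = 1` the per-taxon log effect ranges from zero to twice the nominal
#'   one. The default `h = 0` gives every taxon the same effect magnitude.
#' @param rare_presence maximum number of samples in which a rare taxon is
#'   nonzero.
#' @param reads_per_sample multinomial depth per sample.
#' @param freq_range length-2 range of baseline frequencies (log-uniform).
#' @param rare_max_count maximum injected count for a rare taxon occurrence.
#' @param seed integer seed; the whole dataset is deterministic given it.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n_per_group, n_differential = 100L, n_null = 100L,
                            n_rare = 800L, effect_size = 1.3,
                            effect_heterogeneity = 0,
                            rare_presence = 8L, reads_per_sample = 2000L,
                            freq_range = c(2e-4, 1e-3), rare_max_count = 5L,
                            seed = NULL) {
  spec <- list(n_per_group = as.integer(n_per_group),
               n_differential = as.integer(n_differential),
               n_null = as.integer(n_null), n_rare = as.integer(n_rare),
               effect_size = effect_size,
               effect_heterogeneity = effect_heterogeneity,
               rare_presence = as.integer(rare_presence),
               reads_per_sample = as.integer(reads_per_sample),
               freq_range = as.numeric(freq_range),
               rare_max_count = as.integer(rare_max_count),
               seed = seed)
  validate_simulation_spec(spec)
  structure(spec, class = "simulation_spec")
}

validate_simulation_spec <- function(spec) {
  with(spec, {
    stopifnot(n_per_group >= 1L, n_differential >= 0L, n_null >= 0L,
              n_rare >= 0L, rare_presence >= 1L, reads_per_sample >= 1L,
              rare_max_count >= 1L, length(freq_range) == 2L,
              all(freq_range > 0), freq_range[1] <= freq_range[2],
              effect_size > 0, effect_heterogeneity >= 0)
    if (n_differential + n_null + n_rare < 1L)
      stop("spec must contain at least one taxon", call. = FALSE)
    if (n_differential > 0L && effect_size == 1)
      stop("effect_size must differ from 1 when differential taxa are present",
           call. = FALSE)
  })
  invisible(spec)
}

new_simulated_dataset <- function(matrix, labels, truth, spec = NULL) {
  structure(list(matrix = matrix, groups = labels, truth = truth, spec = spec),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("Simulated community: %d taxa x %d samples (%d vs %d), %d truly differential\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$groups == 0L),
              sum(x$groups == 1L), sum(x$truth)))
  invisible(x)
}

#' Simulate a sparse two-group multinomial community
#'
#' Draws one dataset according to a [simulation_spec()]: N healthy and N sick
#' samples, each one multinomial draw of `reads_per_sample` reads from its
#' group's frequency vector, followed by rare-taxon injection. Column sums
#' equal the read depth before the rare-taxon post-processing. The returned
#' truth vector marks the differential block.
#'
#' @param spec a `simulation_spec`.
#' @return a `simulated_dataset`: list with `matrix` (abundance matrix),
#'   `groups` (0 = healthy, 1 = sick), `truth` (logical) and the spec.
#' @export
simulate_community <- function(spec) {
  validate_simulation_spec(spec)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  nd <- spec$n_differential; nn <- spec$n_null; nr <- spec$n_rare
  m <- nd + nn + nr
  N <- spec$n_per_group
  n <- 2L * N
  base <- exp(stats::runif(nd + nn, log(spec$freq_range[1]),
                           log(spec$freq_range[2])))
  freq_healthy <- c(base, rep(0, nr))
  freq_healthy <- freq_healthy / sum(freq_healthy)
  shifted <- base
  if (nd > 0L) {
    # Alternate the effect direction (up, down, up, ...) and renormalise the
    # differential block to its baseline total, so the null block's relative
    # frequencies are identical in both groups (no compositional spill-over).
    idx <- seq_len(nd)
    h <- spec$effect_heterogeneity
    exponents <- 1 + h * stats::runif(nd, -1, 1)
    factors <- spec$effect_size^exponents *
      rep(c(1, -1), length.out = nd)  # sign marks direction
    factors <- ifelse(factors < 0, 1 / abs(factors), factors)
    shifted[idx] <- base[idx] * factors
    shifted[idx] <- shifted[idx] * sum(base[idx]) / sum(shifted[idx])
  }
  freq_sick <- c(shifted, rep(0, nr))
  freq_sick <- freq_sick / sum(freq_sick)
  counts <- cbind(
    stats::rmultinom(N, size = spec$reads_per_sample, prob = freq_healthy),
    stats::rmultinom(N, size = spec$reads_per_sample, prob = freq_sick)
  )
  if (nr > 0L) {
    for (i in seq.int(nd + nn + 1L, m)) {
      k <- sample.int(spec$rare_presence, 1L)
      pos <- sample.int(n, k)
      counts[i, pos] <- sample.int(spec$rare_max_count, k, replace = TRUE)
    }
  }
  blocks <- c(rep("diff", nd), rep("null", nn), rep("rare", nr))
  rownames(counts) <- sprintf("%s_%04d", blocks, seq_len(m))
  colnames(counts) <- sprintf("S%03d", seq_len(n))
  labels <- group_assignment(rep(c("healthy", "sick"), each = N))
  truth <- c(rep(TRUE, nd), rep(FALSE, nn + nr))
  new_simulated_dataset(abundance_matrix(counts), labels, truth, spec)
}

#' Resample-split global-null dataset from a source table
#'
#' The data-driven global-null protocol: select 2N distinct samples from a
#' source table (nominally all from one biological group) and split them
#' uniformly at random into two pseudo-groups of N. No taxon is truly
#' differential, but the dependence across taxa of the source data is
#' preserved, so the false-positive behaviour of a procedure can be measured
#' on realistic correlation structure.
#'
#' @param x source abundance matrix with at least `2 * n_per_group` samples.
#' @param n_per_group pseudo-group size N.
#' @param seed integer seed.
#' @return a `simulated_dataset` with all-false truth.
#' @export
resample_split_null <- function(x, n_per_group, seed = NULL) {
  validate_abundance(x)
  N <- as.integer(n_per_group)
  if (ncol(x) < 2L * N)
    stop("source table has ", ncol(x), " samples; need at least ", 2L * N,
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cols <- sample.int(ncol(x), 2L * N)
  labels <- group_assignment(sample(rep(0:1, each = N)))
  new_simulated_dataset(x[, cols, drop = FALSE], labels,
                        rep(FALSE, nrow(x)), NULL)
}

#' Spike differential signals into a dataset
#'
#' The data-driven signal protocol: choose k taxa uniformly at random
#' (preferring taxa nonzero in at least one sample), multiply their counts in
#' the sick group (label 1) by `effect_size` -- rounding half up, with a floor
#' of 1 wherever the pre-spike count was positive -- and mark them true in the
#' truth vector. With k = 0 the dataset is returned unchanged.
#'
#' @param dataset a `simulated_dataset` (e.g. from [resample_split_null()]).
#' @param k number of taxa to spike.
#' @param effect_size positive multiplier, different from 1.
#' @param seed integer seed.
#' @return the modified `simulated_dataset`.
#' @export
spike_signals <- function(dataset, k, effect_size, seed = NULL) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  k <- as.integer(k)
  if (k > nrow(dataset$matrix))
    stop("k exceeds the number of taxa", call. = FALSE)
  if (k == 0L) return(dataset)
  stopifnot(effect_size > 0, effect_size != 1)
  if (!is.null(seed)) set.seed(seed)
  x <- dataset$matrix
  nonzero <- which(rowSums(x) > 0)
  pool <- if (length(nonzero) >= k) nonzero else seq_len(nrow(x))
  chosen <- sample(pool, k)
  sick <- dataset$groups == 1L
  pre <- x[chosen, sick, drop = FALSE]
  post <- floor(pre * effect_size + 0.5)
  post[pre > 0 & post < 1] <- 1
  x[chosen, sick] <- post
  truth <- dataset$truth
  truth[chosen] <- TRUE
  new_simulated_dataset(x, dataset$groups, truth, dataset$spec)
}
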