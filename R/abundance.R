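# The package represents an abundance table as a plain numeric matrix
# (features in rows, samples in columns) with unique dimnames, in the style of
# limma/edgeR. Group labels are an integer 0/1 vector with a "group_names"
# attribute.

#' Construct and validate a feature-by-sample abundance matrix
#'
#' Abundance tables are ordinary numeric matrices with features (taxa, OTUs)
#' in rows and samples in columns. Values must be nonnegative and finite
#' (counts or relative abundances); feature and sample identifiers must be
#' unique. All statistics in this package are rank based, so per-feature
#' monotone rescaling (e.g. counts vs relative abundances) does not change
#' any result; cross-sample depth normalisation, if desired, is the caller's
#' responsibility.
#'
#' @param values numeric matrix, or an object coercible to one.
#' @param feature_ids character vector of row identifiers; defaults to
#'   existing rownames.
#' @param sample_ids character vector of column identifiers; defaults to
#'   existing colnames.
#' @return the validated numeric matrix with dimnames set.
#' @export
abundance_matrix <- function(values, feature_ids = rownames(values),
                             sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(feature_ids)) rownames(values) <- feature_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  validate_abundance(values)
  values
}

validate_abundance <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("abundance table must be a numeric matrix", call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("abundance table must have at least one feature and one sample",
         call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("abundance table must carry feature ids (rownames) and sample ids (colnames)",
         call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- rownames(x)[apply(x, 1L, function(r) anyNA(r) || any(!is.finite(r)))]
    stop("missing or non-finite values in features: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(x < 0)) {
    bad <- rownames(x)[apply(x, 1L, function(r) any(r < 0))]
    stop("negative values in features: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' Construct a two-group sample labelling
#'
#' Coerces a grouping vector (factor, character, logical or 0/1 numeric) into
#' the internal representation: an integer vector of 0s and 1s with a
#' `group_names` attribute giving the category each label codes for. Both
#' groups must be nonempty.
#'
#' @param groups grouping vector, one entry per sample.
#' @param group_values optional length-2 character vector fixing which
#'   category maps to 0 and which to 1 (in that order). Defaults to sorted
#'   order of the two observed values.
#' @return integer vector in \{0, 1\} with attribute `group_names`.
#' @export
group_assignment <- function(groups, group_values = NULL) {
  if (is.numeric(groups) && all(groups %in% c(0, 1)) && is.null(group_values)) {
    labels <- as.integer(groups)
    names_pair <- c("0", "1")
  } else {
    g <- as.character(groups)
    vals <- sort(unique(g))
    if (!is.null(group_values)) {
      group_values <- as.character(group_values)
      if (length(group_values) != 2L || anyDuplicated(group_values))
        stop("group_values must name two distinct categories", call. = FALSE)
      missing_vals <- setdiff(group_values, vals)
      if (length(missing_vals))
        stop("group_values not present in data: ",
             paste(missing_vals, collapse = ", "), call. = FALSE)
      vals <- group_values
      keep <- g %in% vals
      if (!all(keep))
        stop("samples with group values outside group_values; drop them first",
             call. = FALSE)
    }
    if (length(vals) != 2L)
      stop("grouping must have exactly 2 distinct values, got ",
           length(vals), call. = FALSE)
    labels <- as.integer(g == vals[2L])
    names_pair <- vals
  }
  if (length(labels) < 2L || sum(labels == 1L) == 0L || sum(labels == 0L) == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  attr(labels, "group_names") <- names_pair
  labels
}

check_alignment <- function(x, labels) {
  if (length(labels) != ncol(x))
    stop("group labels (", length(labels), ") do not match the number of samples (",
         ncol(x), ")", call. = FALSE)
  invisible(TRUE)
}

#' Remove low-abundance features
#'
#' Keeps features whose total abundance (row sum) is at least
#' `min_total_abundance`; row order is preserved. A threshold of 0 is the
#' identity. Filtering everything away yields an empty matrix with a warning,
#' not an error, so sweeps over aggressive thresholds keep running.
#'
#' @param x abundance matrix (see [abundance_matrix()]).
#' @param min_total_abundance nonnegative scalar threshold (inclusive).
#' @return the filtered matrix.
#' @export
filter_taxa <- function(x, min_total_abundance) {
  validate_abundance(x)
  stopifnot(is.numeric(min_total_abundance), length(min_total_abundance) == 1L,
            min_total_abundance >= 0)
  keep <- rowSums(x) >= min_total_abundance
  if (!any(keep))
    warning("all features removed at threshold ", min_total_abundance,
            call. = FALSE)
  x[keep, , drop = FALSE]
}
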