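# Readers and writers for feature tables, QIIME-style mapping files and
# result tables. Readers validate rather than coerce: duplicate ids, missing
# values and negative entries are errors naming the offender.

#' Read a feature-by-sample table
#'
#' TSV dialect: first column holds feature ids, the header row holds sample
#' ids, the body is tab-separated numbers (integers, decimals or scientific
#' notation; dot decimal separator). BIOM tables (features as observations)
#' are read through the `biomformat` package.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"biom"`.
#' @return a validated abundance matrix.
#' @export
read_feature_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM tables requires the 'biomformat' package",
           call. = FALSE)
    b <- biomformat::read_biom(path)
    x <- as(biomformat::biom_data(b), "matrix")
    return(abundance_matrix(x))
  }
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, comment.char = "",
                           quote = "", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L)
    stop("feature table needs a feature-id column and at least one sample",
         call. = FALSE)
  ids <- raw[[1L]]
  body <- raw[, -1L, drop = FALSE]
  num <- suppressWarnings(
    vapply(body, as.numeric, numeric(nrow(body)), USE.NAMES = TRUE))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L,
                                      dimnames = list(NULL, colnames(body)))
  bad <- which(apply(num, 1L, anyNA))
  if (length(bad))
    stop("non-numeric or missing values in feature(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  rownames(num) <- ids
  abundance_matrix(num)
}

#' Write a feature table as TSV
#'
#' Inverse of [read_feature_table()]'s TSV dialect; `read` then `write`
#' round-trips exactly for integer counts.
#'
#' @param x abundance matrix.
#' @param path output path.
#' @param id_column header name of the feature-id column.
#' @export
write_feature_table <- function(x, path, id_column = "#OTU ID") {
  validate_abundance(x)
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a QIIME-style sample mapping file
#'
#' Tab-separated, first header field `#SampleID`, string-valued metadata
#' columns. Sample ids must be unique.
#'
#' @param path file path.
#' @return data.frame with a `sample_id` column followed by the metadata
#'   columns.
#' @export
read_mapping_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, comment.char = "",
                          quote = "", stringsAsFactors = FALSE,
                          colClasses = "character")
  first <- colnames(df)[1L]
  if (!first %in% c("#SampleID", "sample_id", "SampleID", "#Sample ID"))
    stop("mapping file must start with a '#SampleID' column, found '",
         first, "'", call. = FALSE)
  colnames(df)[1L] <- "sample_id"
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in mapping file: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  df
}

#' Align a feature table with sample metadata and extract two-group labels
#'
#' Restricts the table to the samples present in both the table and the
#' metadata (preserving the table's column order), drops samples whose value
#' in `group_column` is not one of the two group values, and returns the
#' aligned matrix together with the 0/1 labelling. Counts of dropped samples
#' are reported via [message()].
#'
#' @param x abundance matrix.
#' @param metadata data.frame from [read_mapping_file()].
#' @param group_column metadata column naming the two groups.
#' @param group_values optional length-2 vector choosing/ordering the two
#'   category values (first maps to 0); defaults to lexicographic order of
#'   the two values observed, which must then be exactly two.
#' @return list with the aligned `matrix` and the `groups` labelling.
#' @export
align_and_label <- function(x, metadata, group_column, group_values = NULL) {
  validate_abundance(x)
  if (!group_column %in% colnames(metadata))
    stop("metadata has no column '", group_column, "'", call. = FALSE)
  shared <- intersect(colnames(x), metadata$sample_id)
  if (length(shared) < 1L)
    stop("no shared sample ids between table and metadata", call. = FALSE)
  dropped_meta <- nrow(metadata) - length(shared)
  dropped_table <- ncol(x) - length(shared)
  if (dropped_meta > 0L)
    message(dropped_meta, " metadata sample(s) absent from the table; dropped")
  if (dropped_table > 0L)
    message(dropped_table, " table sample(s) absent from the metadata; dropped")
  x <- x[, colnames(x) %in% shared, drop = FALSE]
  vals <- metadata[[group_column]][match(colnames(x), metadata$sample_id)]
  if (!is.null(group_values)) {
    keep <- vals %in% group_values
    if (sum(!keep) > 0L)
      message(sum(!keep), " sample(s) with other '", group_column,
              "' values; dropped")
    x <- x[, keep, drop = FALSE]
    vals <- vals[keep]
  }
  if (length(unique(vals)) != 2L)
    stop("grouping column '", group_column, "' has ",
         length(unique(vals)), " distinct values among aligned samples; ",
         "need exactly 2 (use group_values to select)", call. = FALSE)
  list(matrix = x, groups = group_assignment(vals, group_values))
}

#' Write a differential-abundance result table
#'
#' One row per feature: feature_id, statistic, raw_p, adjusted_p, rejected,
#' method, q, B, seed; tab-separated with one header line.
#'
#' @param result a `dsfdr_test` object.
#' @param path output path.
#' @export
write_dsfdr_results <- function(result, path) {
  stopifnot(inherits(result, "dsfdr_test"))
  tab <- result$table
  tab$method <- result$method
  tab$q <- result$q
  tab$B <- result$B
  tab$seed <- if (is.null(result$seed)) NA_integer_ else result$seed
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
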