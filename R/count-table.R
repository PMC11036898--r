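#' Coerce to a sample-by-ASV count matrix
#'
#' The pipeline's central object is a non-negative integer matrix with
#' samples in rows and ASVs in columns, both dimensions named. Tabular
#' input in the on-disk layout (first column `ASV_ID`, one column per
#' sample, as written by [write_count_table()]) is transposed into that
#' shape; a named numeric matrix is validated and returned as-is.
#'
#' @param x A matrix (samples x ASVs) or a data frame whose first column
#'   holds ASV identifiers and whose remaining columns are samples.
#' @return A validated integer matrix with unique row (sample) and column
#'   (ASV) names.
#' @export
as_count_matrix <- function(x) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    m <- t(as.matrix(x[, -1, drop = FALSE]))
    colnames(m) <- ids
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("count table must be a numeric matrix or an ASV_ID-keyed data frame",
         call. = FALSE)
  }
  validate_count_matrix(x)
  storage.mode(x) <- "double"
  x
}

validate_count_matrix <- function(x) {
  if (length(x) == 0L) stop("empty count table", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("count table needs sample rownames and ASV colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate ASV ids", call. = FALSE)
  bad <- which(!is.finite(x) | x < 0 | x != round(x))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(x))
    stop(sprintf(
      "count table entries must be non-negative integers; first offender sample '%s', ASV '%s' = %s",
      rownames(x)[i[1]], colnames(x)[i[2]], format(x[bad[1]])), call. = FALSE)
  }
  invisible(x)
}

#' Convert a count matrix to a long tibble
#'
#' @param counts Sample-by-ASV count matrix.
#' @return A tibble with columns `sample_id`, `asv_id`, `count`.
#' @export
count_tibble <- function(counts) {
  counts <- as_count_matrix(counts)
  tibble::as_tibble(counts, rownames = "sample_id") %>%
    tidyr::pivot_longer(-"sample_id", names_to = "asv_id", values_to = "count")
}

# split metadata into biological samples and negative controls, matching
# the count matrix rows; shared by preprocess and pipeline code
check_metadata <- function(counts, meta) {
  stopifnot(is.data.frame(meta))
  need <- c("sample_id", "is_negative_control")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(rownames(counts), meta$sample_id)
  if (length(absent)) {
    stop("samples absent from metadata: ", paste(utils::head(absent, 5), collapse = ", "),
         call. = FALSE)
  }
  meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
}
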