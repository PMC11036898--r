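#' Remove globally rare ASVs
#'
#' Drops every ASV whose pooled relative abundance — its total count across
#' all samples divided by the grand total — is strictly below `threshold`.
#' The default 1e-5 is the "<0.001%" cutoff used for 16S ASV tables.
#'
#' @param counts Sample-by-ASV count matrix (or tabular equivalent, see
#'   [as_count_matrix()]).
#' @param threshold Pooled relative-abundance cutoff in `[0, 1)`.
#' @return The count matrix restricted to surviving ASVs.
#' @export
filter_low_frequency <- function(counts, threshold = 1e-5) {
  counts <- as_count_matrix(counts)
  stopifnot(threshold >= 0, threshold < 1)
  frac <- colSums(counts) / sum(counts)
  counts[, frac >= threshold, drop = FALSE]
}

#' Negative-control decontamination
#'
#' Implements the two-step reagent-background rule. (1) An ASV present
#' (count > 0) in strictly more than `control_prevalence` of the negative
#' controls and strictly fewer than `sample_prevalence` of the biological
#' samples is removed outright. (2) For every remaining ASV, its mean count
#' across the negative controls is subtracted from each biological sample's
#' count; the result is clamped at zero and rounded half away from zero so
#' the table stays integer for the count models downstream. Control samples
#' are dropped from the output. If the metadata contains no negative
#' controls the biological table is returned unchanged.
#'
#' @param counts Count matrix containing biological and control samples.
#' @param meta Metadata with `sample_id` and logical `is_negative_control`.
#' @param control_prevalence,sample_prevalence Presence-fraction cutoffs
#'   (defaults 0.15 and 0.15).
#' @return Decontaminated count matrix over biological samples only.
#' @export
remove_control_artifacts <- function(counts, meta, control_prevalence = 0.15,
                                     sample_prevalence = 0.15) {
  counts <- as_count_matrix(counts)
  meta <- check_metadata(counts, meta)
  is_nc <- as.logical(meta$is_negative_control)
  bio <- counts[!is_nc, , drop = FALSE]
  if (nrow(bio) == 0L) stop("no biological samples in count table", call. = FALSE)
  if (!any(is_nc)) return(bio)
  ctl <- counts[is_nc, , drop = FALSE]

  prev_ctl <- colMeans(ctl > 0)
  prev_bio <- colMeans(bio > 0)
  drop <- prev_ctl > control_prevalence & prev_bio < sample_prevalence
  bio <- bio[, !drop, drop = FALSE]
  ctl <- ctl[, !drop, drop = FALSE]

  ctl_mean <- colMeans(ctl)
  adj <- sweep(bio, 2, ctl_mean, "-")
  adj[adj < 0] <- 0
  out <- floor(adj + 0.5)          # round half away from zero (values are >= 0)
  validate_count_matrix(out)
  out
}

#' Prevalence filter
#'
#' Removes ASVs present (count > 0) in strictly fewer than `min_prevalence`
#' of the samples; the 10% default is applied before differential-abundance
#' testing and SparCC network inference.
#'
#' @param counts Sample-by-ASV count matrix.
#' @param min_prevalence Presence-fraction cutoff in `[0, 1]`.
#' @return The count matrix restricted to surviving ASVs.
#' @export
prevalence_filter <- function(counts, min_prevalence = 0.10) {
  counts <- as_count_matrix(counts)
  stopifnot(min_prevalence >= 0, min_prevalence <= 1)
  prev <- colMeans(counts > 0)
  counts[, prev >= min_prevalence, drop = FALSE]
}

#' Per-sample relative abundances
#'
#' @param counts Sample-by-ASV count matrix; every sample total must be
#'   positive.
#' @return Matrix of the same shape whose rows sum to 1.
#' @export
relative_abundance <- function(counts) {
  counts <- as_count_matrix(counts)
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    stop("zero-depth sample(s): ",
         paste(rownames(counts)[tot == 0], collapse = ", "), call. = FALSE)
  }
  sweep(counts, 1, tot, "/")
}
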