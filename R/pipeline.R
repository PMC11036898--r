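#' Read an ASV count table
#'
#' TSV layout: rows are ASVs, columns are samples, first column `ASV_ID`
#' (the on-disk transpose of the in-memory sample-by-ASV matrix). BIOM
#' input goes through the biomformat package.
#'
#' @param path File path.
#' @param format `"tsv"` or `"biom"`.
#' @return A validated sample-by-ASV count matrix.
#' @export
read_count_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("BIOM input needs the biomformat package", call. = FALSE)
    }
    bm <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(bm), "matrix")  # ASVs x samples
    return(as_count_matrix(t(m)))
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "ASV_ID") {
    stop("expected first column 'ASV_ID' in ", path, call. = FALSE)
  }
  as_count_matrix(df)
}

#' Write an ASV count table as TSV
#'
#' @param counts Sample-by-ASV count matrix.
#' @param path Output path.
#' @export
write_count_table <- function(counts, path) {
  counts <- as_count_matrix(counts)
  df <- data.frame(ASV_ID = colnames(counts), t(counts), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata CSV
#'
#' @param path CSV with at least `sample_id`; a missing
#'   `is_negative_control` column defaults to all-`FALSE`.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!("sample_id" %in% names(df))) stop("metadata needs sample_id", call. = FALSE)
  if (!("is_negative_control" %in% names(df))) df$is_negative_control <- FALSE
  df$is_negative_control <- as.logical(df$is_negative_control)
  df
}

#' Read a rooted Newick tree
#'
#' @param path Newick file.
#' @param asv_ids Optional ids to check leaf coverage against; leaves
#'   missing from this set only raise a warning.
#' @return An [ape] `phylo` object; missing branch lengths default to 0
#'   with a warning.
#' @export
read_tree <- function(path, asv_ids = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("unparseable Newick file: ", path, call. = FALSE)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels in tree", call. = FALSE)
  }
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; defaulting to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (!is.null(asv_ids)) {
    missing_tips <- setdiff(asv_ids, tr$tip.label)
    if (length(missing_tips)) {
      warning("ids absent from tree: ", paste(utils::head(missing_tips, 5), collapse = ", "))
    }
  }
  tr
}

#' Pipeline configuration
#'
#' All analysis thresholds with their study defaults: low-frequency cutoff
#' 1e-5 (0.001%), decontamination prevalences 15%/15%, DA/SparCC prevalence
#' 10%, SparCC module threshold 0.5, FDR 0.05 and `|log2FC|` 1. Unknown
#' arguments are rejected up front.
#'
#' @param ... Named overrides of the defaults listed above, plus `seed`,
#'   `n_permutations`, `beta_metric`, `covariates`, and `output_dir`.
#' @return A validated list of class `mb_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    low_freq_threshold = 1e-5,
    control_prevalence = 0.15,
    sample_prevalence = 0.15,
    min_prevalence = 0.10,
    module_threshold = 0.5,
    q_threshold = 0.05,
    lfc_threshold = 1,
    exclusion_threshold = 0.1,
    max_exclusions = 10,
    beta_metric = "weighted_unifrac",
    covariates = c("subtype", "surgery"),
    n_permutations = 999,
    seed = 1L,
    output_dir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "mb_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates preprocessing (low-frequency filter, negative-control
#' decontamination), alpha diversity with a group comparison, the
#' beta-diversity distance matrix with PERMANOVA, prevalence filtering,
#' multi-model differential abundance with the effect filter, SparCC
#' module detection and module-EIM logistic association. When
#' `config$output_dir` is set, every result is also written as TSV along
#' with a JSON run log recording the seed and every threshold used.
#'
#' @param counts Sample-by-ASV count matrix including any negative
#'   controls.
#' @param meta Sample metadata (`sample_id`, `is_negative_control`,
#'   `group`, covariates).
#' @param tree Rooted `phylo` tree over the ASVs (required for UniFrac
#'   metrics).
#' @param config A [pipeline_config()] object.
#' @return A list of class `mb_pipeline` with elements `counts_clean`,
#'   `alpha`, `alpha_tests`, `beta_dm`, `permanova`, `da`, `da_significant`,
#'   `sparcc_rho`, `modules`, `module_associations`, `config`.
#' @export
run_pipeline <- function(counts, meta, tree = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "mb_config"))
  counts <- as_count_matrix(counts)

  counts <- filter_low_frequency(counts, config$low_freq_threshold)
  clean <- remove_control_artifacts(counts, meta,
                                    config$control_prevalence,
                                    config$sample_prevalence)
  clean <- clean[, colSums(clean) > 0, drop = FALSE]
  bio_meta <- dplyr::filter(tibble::as_tibble(meta), !.data$is_negative_control)

  alpha <- alpha_diversity(clean)
  am <- dplyr::left_join(alpha, bio_meta, by = "sample_id")
  alpha_tests <- dplyr::bind_rows(
    dplyr::mutate(rank_compare(am$shannon[am$group == "EIM"],
                               am$shannon[am$group == "C"]), index = "shannon"),
    dplyr::mutate(rank_compare(am$pielou[am$group == "EIM"],
                               am$pielou[am$group == "C"]), index = "pielou")
  )

  dm <- beta_distance_matrix(clean, config$beta_metric, tree)
  perm <- permanova(dm, bio_meta, terms = "group",
                    n_permutations = config$n_permutations, seed = config$seed)

  prev <- prevalence_filter(clean, config$min_prevalence)
  da <- differential_abundance(prev, bio_meta, covariates = config$covariates)
  da_sig <- effect_filter(da, config$q_threshold, config$lfc_threshold)

  rho <- sparcc(prev, config$exclusion_threshold, config$max_exclusions)
  modules <- detect_modules(rho, config$module_threshold)
  assoc <- associate_modules(module_abundance(prev, modules), bio_meta)

  res <- structure(list(
    counts_clean = clean, alpha = alpha, alpha_tests = alpha_tests,
    beta_dm = dm, permanova = perm, da = da, da_significant = da_sig,
    sparcc_rho = rho, modules = modules, module_associations = assoc,
    config = config
  ), class = "mb_pipeline")
  if (!is.null(config$output_dir)) write_pipeline_results(res, config$output_dir)
  res
}

write_pipeline_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(dir, f)
  write_count_table(res$counts_clean, out("counts_clean.tsv"))
  utils::write.table(res$alpha, out("alpha_diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(res$beta_dm), res$beta_dm,
                                check.names = FALSE),
                     out("beta_distance.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(res$permanova, out("permanova.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$da, out("differential_abundance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$da_significant, out("da_significant.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(ASV_ID = rownames(res$sparcc_rho),
                                unclass(res$sparcc_rho), check.names = FALSE),
                     out("sparcc_rho.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(res$modules, out("modules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$module_associations, out("module_associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- res$config
  log <- c(unclass(cfg)[!vapply(cfg, is.null, logical(1))],
           list(r_version = as.character(getRversion()),
                package_version = as.character(utils::packageVersion("eimbiome")),
                timestamp = format(Sys.time(), tz = "UTC")))
  jsonlite::write_json(log, out("run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
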