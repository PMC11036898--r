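#' Simulation parameters for the synthetic community generator
#'
#' Bundles and validates everything [generate_community()] and
#' [generate_negative_controls()] need: cohort dimensions, sequencing-depth
#' model, planted co-abundance modules, planted group effects and reagent
#' contaminants. Defaults mirror a two-group 16S study of moderate size.
#'
#' @param n_samples_per_group Biological samples in each of the EIM and
#'   control groups.
#' @param n_asvs Number of ASVs in the simulated community.
#' @param n_controls Number of negative-control (reagent blank) samples.
#' @param depth_mean,depth_dispersion Mean and dispersion (negative binomial
#'   `size`) of the per-sample library size; depths are floored at 1000 reads.
#' @param module_spec Data frame with columns `size` and `r`: each row plants
#'   one co-abundance module of `size` ASVs whose log-scale basis abundances
#'   correlate at `r` (0 < r < 1). Module members are assigned to the first
#'   ASVs in index order and never overlap.
#' @param effect_spec Data frame with columns `asv` (ASV index),
#'   `log2_effect` (group log2 fold effect, EIM relative to control) and
#'   optionally `zero_prob_eim`, `zero_prob_control` (structural-zero
#'   probability per group, default 0).
#' @param contaminant_spec Data frame with columns `asv` (ASV index),
#'   `control_mean` (expected contaminant count in a negative control) and
#'   `carryover_prob` (probability a biological sample picks the contaminant
#'   up at a comparable expected count).
#' @param seed Integer seed; each generator call derives its own stream from
#'   it, so identical parameters reproduce identical output.
#' @param allow_module_effects Planted effects on module-member ASVs are
#'   rejected by default because they confound module-recovery tests; set
#'   `TRUE` to plant a group-depleted (or enriched) module deliberately,
#'   e.g. for module-phenotype association tests.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_samples_per_group = 65, n_asvs = 200, n_controls = 8,
                       depth_mean = 25000, depth_dispersion = 5,
                       module_spec = NULL, effect_spec = NULL,
                       contaminant_spec = NULL, seed = 1L,
                       allow_module_effects = FALSE) {
  stopifnot(n_samples_per_group >= 1, n_asvs >= 2, n_controls >= 0,
            depth_mean > 0, depth_dispersion > 0)
  module_spec <- normalise_spec(module_spec, c("size", "r"))
  effect_spec <- normalise_spec(effect_spec, c("asv", "log2_effect"))
  contaminant_spec <- normalise_spec(contaminant_spec,
                                     c("asv", "control_mean", "carryover_prob"))
  if (nrow(module_spec)) {
    stopifnot(all(module_spec$size >= 2), all(module_spec$r > 0),
              all(module_spec$r < 1))
    if (sum(module_spec$size) > n_asvs) {
      stop("module sizes exceed n_asvs", call. = FALSE)
    }
  }
  if (nrow(effect_spec)) {
    if (is.null(effect_spec$zero_prob_eim)) effect_spec$zero_prob_eim <- 0
    if (is.null(effect_spec$zero_prob_control)) effect_spec$zero_prob_control <- 0
    stopifnot(all(effect_spec$asv >= 1), all(effect_spec$asv <= n_asvs),
              all(effect_spec$zero_prob_eim >= 0), all(effect_spec$zero_prob_eim <= 1),
              all(effect_spec$zero_prob_control >= 0), all(effect_spec$zero_prob_control <= 1))
    n_module_asvs <- sum(module_spec$size)
    if (!allow_module_effects && any(effect_spec$asv <= n_module_asvs)) {
      stop("planted effects on module-member ASVs are rejected: they confound module recovery tests",
           call. = FALSE)
    }
  } else {
    effect_spec$zero_prob_eim <- numeric(0)
    effect_spec$zero_prob_control <- numeric(0)
  }
  if (nrow(contaminant_spec)) {
    stopifnot(all(contaminant_spec$asv >= 1), all(contaminant_spec$asv <= n_asvs),
              all(contaminant_spec$control_mean > 0),
              all(contaminant_spec$carryover_prob >= 0),
              all(contaminant_spec$carryover_prob <= 1))
  }
  structure(list(
    n_samples_per_group = as.integer(n_samples_per_group),
    n_asvs = as.integer(n_asvs), n_controls = as.integer(n_controls),
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    module_spec = module_spec, effect_spec = effect_spec,
    contaminant_spec = contaminant_spec, seed = as.integer(seed)
  ), class = "sim_params")
}

normalise_spec <- function(x, required) {
  if (is.null(x)) {
    x <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(required)),
                                       required))
  }
  x <- as.data.frame(x)
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    stop("spec is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x
}

# block-diagonal log-scale correlation realising the module spec
basis_correlation_matrix <- function(params) {
  D <- params$n_asvs
  R <- diag(D)
  at <- 1L
  for (k in seq_len(nrow(params$module_spec))) {
    sz <- params$module_spec$size[k]
    r <- params$module_spec$r[k]
    idx <- at:(at + sz - 1L)
    R[idx, idx] <- r
    diag(R)[idx] <- 1
    at <- at + sz
  }
  R
}

module_membership_vector <- function(params) {
  m <- rep(NA_integer_, params$n_asvs)
  at <- 1L
  for (k in seq_len(nrow(params$module_spec))) {
    sz <- params$module_spec$size[k]
    m[at:(at + sz - 1L)] <- k
    at <- at + sz
  }
  m
}

#' Simulate a two-group ASV count table with planted structure
#'
#' Per-sample basis abundances are multivariate log-normal: log-scale
#' correlation is block-diagonal over the planted modules (identity
#' elsewhere, imposed through a Cholesky factor, matching SparCC's
#' log-normal basis model), per-ASV log-means are drawn once to give a
#' realistic uneven rank-abundance curve, and the EIM group's log-means are
#' shifted by `log2_effect * ln 2` for every planted effect. Structural
#' zeros knock the basis to zero per-sample with the stated per-group
#' probability before counts are drawn. Observed counts are multinomial
#' draws from the normalised basis at a negative-binomially distributed
#' library size (floored at 1000 reads), so each sample's counts sum
#' exactly to its drawn depth. Contaminant carryover (from
#' `contaminant_spec`) enters the basis of a biological sample with the
#' stated probability at a mass calibrated so its expected count matches
#' `control_mean`.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `mb_sim` with elements `counts` (sample x ASV
#'   integer matrix), `metadata` (tibble: `sample_id`, `group`, `subtype`,
#'   `surgery`, `is_negative_control`, `depth`) and `truth` (list:
#'   `basis_correlation`, `planted_effects` named by ASV,
#'   `module_membership` named by ASV, `log_basis` the latent log-abundance
#'   matrix before structural zeros).
#' @export
generate_community <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed, {
    D <- params$n_asvs
    n <- 2L * params$n_samples_per_group
    asv_ids <- sprintf("ASV_%03d", seq_len(D))
    sample_ids <- sprintf("S%03d", seq_len(n))
    group <- rep(c("EIM", "C"), each = params$n_samples_per_group)

    R <- basis_correlation_matrix(params)
    L <- chol(R)
    mu <- stats::rnorm(D, mean = 0, sd = 1.5)   # rank-abundance spread
    Z <- matrix(stats::rnorm(n * D), n, D) %*% L
    logb <- sweep(Z, 2, mu, "+")
    es <- params$effect_spec
    for (k in seq_len(nrow(es))) {
      j <- es$asv[k]
      logb[group == "EIM", j] <- logb[group == "EIM", j] + es$log2_effect[k] * log(2)
    }
    basis <- exp(logb)
    # structural zeros on the basis, before multinomial sampling
    for (k in seq_len(nrow(es))) {
      j <- es$asv[k]
      pz <- ifelse(group == "EIM", es$zero_prob_eim[k], es$zero_prob_control[k])
      basis[stats::runif(n) < pz, j] <- 0
    }
    # contaminants are reagent-borne, not community members: their basis is
    # zero except where carryover deposits them at the control-level mass
    cs <- params$contaminant_spec
    for (k in seq_len(nrow(cs))) {
      j <- cs$asv[k]
      basis[, j] <- 0
      hit <- stats::runif(n) < cs$carryover_prob[k]
      mass <- cs$control_mean[k] / params$depth_mean * rowSums(basis[hit, , drop = FALSE])
      basis[hit, j] <- mass
    }
    depth <- pmax(stats::rnbinom(n, mu = params$depth_mean,
                                 size = params$depth_dispersion), 1000)
    counts <- t(vapply(seq_len(n), function(i) {
      stats::rmultinom(1, depth[i], prob = basis[i, ])[, 1]
    }, numeric(D)))
    dimnames(counts) <- list(sample_ids, asv_ids)
    dimnames(logb) <- list(sample_ids, asv_ids)
    dimnames(R) <- list(asv_ids, asv_ids)

    metadata <- tibble::tibble(
      sample_id = sample_ids,
      group = group,
      subtype = sample(c("CD", "UC"), n, replace = TRUE, prob = c(0.62, 0.38)),
      surgery = stats::runif(n) < 0.34,
      is_negative_control = FALSE,
      depth = depth
    )
    effects <- stats::setNames(rep(0, D), asv_ids)
    effects[es$asv] <- es$log2_effect
    truth <- list(
      basis_correlation = R,
      planted_effects = effects,
      module_membership = stats::setNames(module_membership_vector(params), asv_ids),
      log_basis = logb
    )
    structure(list(counts = counts, metadata = metadata, truth = truth),
              class = "mb_sim")
  })
}

#' Simulate negative-control (reagent blank) samples
#'
#' Controls are near-sterile: every ASV draws from a tiny Poisson baseline
#' except the contaminants, which draw Poisson counts at their stated
#' control means. The contaminants' carryover into biological samples is
#' handled by [generate_community()] from the same `contaminant_spec`.
#'
#' @param params A [sim_params()] object.
#' @param asv_ids Optional ASV identifiers; defaults to the ids
#'   [generate_community()] uses for the same `params`.
#' @return A `n_controls` x ASV count matrix (zero rows if `n_controls` is 0).
#' @export
generate_negative_controls <- function(params, asv_ids = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(asv_ids)) asv_ids <- sprintf("ASV_%03d", seq_len(params$n_asvs))
  nc <- params$n_controls
  out <- matrix(0, nrow = nc, ncol = length(asv_ids),
                dimnames = list(if (nc) sprintf("NC%02d", seq_len(nc)) else character(0),
                                asv_ids))
  if (nc == 0L) return(out)
  withr::with_seed(params$seed + 1000L, {
    out[] <- stats::rpois(length(out), lambda = 0.02)
    cs <- params$contaminant_spec
    for (k in seq_len(nrow(cs))) {
      out[, cs$asv[k]] <- stats::rpois(nc, lambda = cs$control_mean[k])
    }
  })
  out
}

#' Simulate a random rooted phylogeny over a set of ASVs
#'
#' A rooted binary tree with strictly positive branch lengths, suitable for
#' UniFrac. Deterministic for a given id set and seed.
#'
#' @param asv_ids Two or more unique leaf labels.
#' @param seed Integer seed.
#' @return An [ape] `phylo` object.
#' @export
generate_random_tree <- function(asv_ids, seed = 1L) {
  asv_ids <- as.character(asv_ids)
  if (length(asv_ids) < 2) stop("need at least 2 ASV ids", call. = FALSE)
  if (anyDuplicated(asv_ids)) stop("duplicate ASV ids", call. = FALSE)
  withr::with_seed(seed, {
    tr <- ape::rtree(length(asv_ids), rooted = TRUE)
    tr$tip.label <- asv_ids   # assign our labels in tip order
    tr$edge.length <- pmax(tr$edge.length, 1e-6)
    tr
  })
}

#' Build the study's enrollment fixture
#'
#' Emulates the cohort bookkeeping of the underlying study: 156 enrolled
#' IBD patients of whom 25 carried clinical symptoms of EIMs without a
#' specialist-confirmed diagnosis (excluded downstream), 86 with confirmed
#' EIMs (60 CD, 26 UC; 52 female) and 45 without EIMs (21 CD, 24 UC; 18
#' female). Sex and surgery counts per subgroup follow the study's
#' characteristics table; the number of EIMs per confirmed case is drawn
#' from 1-3. Record order is shuffled under the seed.
#'
#' @param seed Integer seed controlling shuffling and per-record draws.
#' @return A tibble with one row per enrolled participant: `participant_id`,
#'   `subtype`, `eim_status` (`confirmed`/`unconfirmed`/`none`), `n_eims`,
#'   `sex`, `surgery`, `excluded_reason`.
#' @export
make_cohort_fixture <- function(seed = 1L) {
  withr::with_seed(seed, {
    block <- function(n, subtype, status, n_female, n_surgery) {
      tibble::tibble(
        subtype = rep(subtype, n),
        eim_status = rep(status, n),
        n_eims = if (status == "none") rep(0L, n) else
          sample(1:3, n, replace = TRUE, prob = c(0.7, 0.22, 0.08)),
        sex = sample(rep(c("F", "M"), c(n_female, n - n_female))),
        surgery = sample(rep(c(TRUE, FALSE), c(n_surgery, n - n_surgery))),
        excluded_reason = if (status == "unconfirmed")
          rep("EIM diagnosis not confirmed by specialist at study time", n)
        else rep(NA_character_, n)
      )
    }
    rec <- dplyr::bind_rows(
      block(60, "CD", "confirmed", 36, 29),   # CD-EIM
      block(26, "UC", "confirmed", 16, 3),    # UC-EIM
      block(21, "CD", "none", 9, 12),         # CD-C
      block(24, "UC", "none", 9, 0),          # UC-C
      block(15, "CD", "unconfirmed", 8, 5),
      block(10, "UC", "unconfirmed", 5, 1)
    )
    rec <- rec[sample(nrow(rec)), ]
    rec$participant_id <- sprintf("P%03d", seq_len(nrow(rec)))
    dplyr::relocate(rec, "participant_id")
  })
}
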