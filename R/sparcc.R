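#' Posterior-mean fraction estimates
#'
#' Compositional fractions with a uniform Dirichlet prior: per sample,
#' `(count + 1) / (total + D)` where `D` is the number of ASVs. This is the
#' deterministic posterior mean (no resampling), so every fraction is
#' strictly positive and each row sums to 1.
#'
#' @param counts Sample-by-ASV count matrix with positive sample totals.
#' @return Matrix of fractions, same shape and names.
#' @export
estimate_fractions <- function(counts) {
  counts <- as_count_matrix(counts)
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    stop("zero-depth sample(s): ",
         paste(rownames(counts)[tot == 0], collapse = ", "), call. = FALSE)
  }
  (counts + 1) / (tot + ncol(counts))
}

#' Log-ratio variation matrix
#'
#' `T[i, j]` is the sample variance (unbiased, n-1 denominator) of
#' `log(f_i / f_j)` across samples: SparCC's sufficient statistic.
#'
#' @param fractions Sample-by-ASV matrix of strictly positive fractions.
#' @return Symmetric ASV-by-ASV matrix with zero diagonal.
#' @export
variation_matrix <- function(fractions) {
  stopifnot(is.matrix(fractions), nrow(fractions) >= 2)
  if (any(fractions <= 0)) stop("fractions must be strictly positive", call. = FALSE)
  lf <- log(fractions)
  V <- stats::cov(lf)
  v <- diag(V)
  Tm <- outer(v, v, "+") - 2 * V
  Tm[abs(Tm) < 1e-15] <- 0
  diag(Tm) <- 0
  dimnames(Tm) <- list(colnames(fractions), colnames(fractions))
  Tm
}

#' SparCC compositional correlations
#'
#' Estimates linear correlations of the unobserved basis abundances from
#' compositional counts. Basis variances solve the sparsity-approximation
#' linear system `t = M omega^2` with `t_i = sum_j T[i, j]` and
#' `M = (D - 2) I + 1 1'`; correlations follow as
#' `rho[i, j] = (omega_i^2 + omega_j^2 - T[i, j]) / (2 omega_i omega_j)`,
#' clamped to `[-1, 1]`. Strongly correlated pairs violate the sparsity
#' assumption, so up to `max_exclusions` times the not-yet-excluded pair
#' with the largest `|rho| >= exclusion_threshold` is removed from the
#' system (its variation-matrix contribution dropped from `t`, the
#' corresponding coefficients of `M` decremented) and the solution
#' recomputed. Negative solved basis variances are clamped to 1e-10 with a
#' warning; a component that loses all partners gets `rho = 0` to
#' non-excluded partners, also with a warning.
#'
#' @param counts Prevalence-filtered sample-by-ASV count matrix with at
#'   least 4 ASVs.
#' @param exclusion_threshold Minimum `|rho|` for a pair to be eligible for
#'   exclusion (default 0.1).
#' @param max_exclusions Maximum number of excluded pairs (default 10).
#' @return ASV-by-ASV correlation matrix of class `mb_sparcc` with unit
#'   diagonal; attributes `excluded_pairs` (two-column matrix of ids) and
#'   `basis_variance`.
#' @export
sparcc <- function(counts, exclusion_threshold = 0.1, max_exclusions = 10) {
  counts <- as_count_matrix(counts)
  D <- ncol(counts)
  if (D < 4) stop("basis system underdetermined: need at least 4 ASVs", call. = FALSE)
  Tm <- variation_matrix(estimate_fractions(counts))

  M <- matrix(1, D, D) + diag(D - 2, D)
  tvec <- rowSums(Tm)
  active <- matrix(TRUE, D, D)   # pair (i, j) still in the system
  diag(active) <- FALSE

  solve_rho <- function(M, tvec) {
    omega2 <- tryCatch(solve(M, tvec), error = function(e) {
      as.vector(MASS::ginv(M) %*% tvec)
    })
    if (any(omega2 < 0)) {
      warning("negative basis variance clamped to 1e-10")
      omega2 <- pmax(omega2, 1e-10)
    }
    omega <- sqrt(omega2)
    rho <- (outer(omega2, omega2, "+") - Tm) / (2 * outer(omega, omega))
    rho[rho > 1] <- 1
    rho[rho < -1] <- -1
    diag(rho) <- 1
    list(rho = rho, omega2 = omega2)
  }

  sol <- solve_rho(M, tvec)
  excluded <- matrix(integer(0), ncol = 2)
  for (iter in seq_len(max_exclusions)) {
    cand <- abs(sol$rho)
    cand[!active] <- 0
    m <- max(cand)
    if (m < exclusion_threshold) break
    ij <- which(cand == m, arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    active[i, j] <- active[j, i] <- FALSE
    tvec[i] <- tvec[i] - Tm[i, j]
    tvec[j] <- tvec[j] - Tm[i, j]
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    M[i, j] <- M[i, j] - 1
    M[j, i] <- M[j, i] - 1
    excluded <- rbind(excluded, c(i, j))
    sol <- solve_rho(M, tvec)
  }
  rho <- sol$rho
  orphan <- which(rowSums(active) == 0)
  if (length(orphan)) {
    warning("component(s) excluded from all pairs; their correlations set to 0: ",
            paste(colnames(counts)[orphan], collapse = ", "))
    rho[orphan, ] <- 0
    rho[, orphan] <- 0
    diag(rho) <- 1
  }
  dimnames(rho) <- list(colnames(counts), colnames(counts))
  structure(rho,
            excluded_pairs = matrix(colnames(counts)[excluded], ncol = 2),
            basis_variance = stats::setNames(sol$omega2, colnames(counts)),
            class = c("mb_sparcc", "matrix", "array"))
}

#' Detect co-association modules in a correlation matrix
#'
#' Builds a graph with an edge wherever the (signed, by default)
#' correlation meets the threshold and returns its connected components of
#' size at least 2 as modules.
#'
#' @param rho Symmetric correlation matrix (e.g. from [sparcc()]).
#' @param threshold Edge threshold (default 0.5).
#' @param absolute Use `|rho| >= threshold` instead of the signed rule.
#' @return A tibble of class `mb_modules` with columns `module` (integer
#'   id) and `asv_id`; attribute `threshold`. Zero rows when no module
#'   forms.
#' @export
detect_modules <- function(rho, threshold = 0.5, absolute = FALSE) {
  rho <- unclass(rho)
  stopifnot(is.matrix(rho), isSymmetric(unname(rho)))
  vals <- if (absolute) abs(rho) else rho
  adj <- vals >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  keep <- which(comp$csize >= 2)
  out <- tibble::tibble(
    module = match(comp$membership, keep),
    asv_id = colnames(rho)
  )
  out <- dplyr::filter(out, !is.na(.data$module))
  out <- dplyr::arrange(out, .data$module, .data$asv_id)
  attr(out, "threshold") <- threshold
  class(out) <- c("mb_modules", class(out))
  out
}

#' Per-sample module abundances
#'
#' Module abundance is the sum of the member ASVs' relative abundances in
#' each sample.
#'
#' @param counts Sample-by-ASV count matrix.
#' @param modules Tibble from [detect_modules()].
#' @return Sample-by-module matrix of summed fractions (zero columns when
#'   no modules).
#' @export
module_abundance <- function(counts, modules) {
  counts <- as_count_matrix(counts)
  fr <- relative_abundance(counts)
  mids <- sort(unique(modules$module))
  out <- matrix(0, nrow(counts), length(mids),
                dimnames = list(rownames(counts),
                                if (length(mids)) paste0("module_", mids) else NULL))
  for (k in seq_along(mids)) {
    members <- modules$asv_id[modules$module == mids[k]]
    unknown <- setdiff(members, colnames(fr))
    if (length(unknown)) {
      stop("module member(s) absent from counts: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    out[, k] <- rowSums(fr[, members, drop = FALSE])
  }
  out
}

#' Simple logistic regression of a binary outcome on one predictor
#'
#' Intercept-plus-slope logistic model fit by iteratively reweighted least
#' squares, with a two-sided Wald p-value on the slope. Complete separation
#' (diverging slope) is flagged: the slope is reported but its p-value is
#' `NA`.
#'
#' @param y Binary outcome (0/1 or logical), both classes present.
#' @param x Numeric predictor.
#' @return A tibble: `slope`, `se`, `p`, `separated`.
#' @export
logistic_fit <- function(y, x) {
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), length(y) == length(x))
  if (length(unique(y)) < 2) stop("outcome has a single class", call. = FALSE)
  if (stats::var(x) == 0) {
    return(tibble::tibble(slope = 0, se = NA_real_, p = NA_real_,
                          separated = FALSE))
  }
  fit <- suppressWarnings(stats::glm(
    y ~ x, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  sm <- summary(fit)$coefficients
  slope <- sm["x", "Estimate"]
  se <- sm["x", "Std. Error"]
  mu <- fit$fitted.values
  separated <- !fit$converged || abs(slope) > 1e3 ||
    all(abs(mu - y) < 1e-8)
  tibble::tibble(slope = slope, se = se,
                 p = if (separated) NA_real_ else 2 * stats::pnorm(-abs(slope / se)),
                 separated = separated)
}

#' Associate co-abundance modules with EIM status
#'
#' Per module: the predictor is `log10(abundance + delta)` with `delta`
#' half the smallest nonzero module abundance, standardized to unit
#' variance, and regressed against EIM (1) vs control (0) by
#' [logistic_fit()]. Records are sorted by p-value; `direction` is
#' `"depleted"` for a negative slope, `"enriched"` otherwise.
#'
#' @param module_abund Sample-by-module abundance matrix from
#'   [module_abundance()].
#' @param meta Metadata with `sample_id` and `group` (`"EIM"`/`"C"`).
#' @return A tibble of class `mb_module_assoc`: `module`, `slope`, `se`,
#'   `p`, `direction`, `separated`.
#' @export
associate_modules <- function(module_abund, meta) {
  meta <- as.data.frame(meta)
  meta <- meta[match(rownames(module_abund), meta$sample_id), , drop = FALSE]
  y <- as.numeric(meta$group == "EIM")
  rows <- purrr::map_dfr(seq_len(ncol(module_abund)), function(k) {
    a <- module_abund[, k]
    nz <- a[a > 0]
    delta <- if (length(nz)) min(nz) / 2 else 1e-6
    x <- log10(a + delta)
    if (stats::sd(x) > 0) x <- (x - mean(x)) / stats::sd(x)
    res <- logistic_fit(y, x)
    res$module <- colnames(module_abund)[k]
    res
  })
  if (!nrow(rows)) {
    out <- tibble::tibble(module = character(0), slope = numeric(0),
                          se = numeric(0), p = numeric(0),
                          direction = character(0), separated = logical(0))
  } else {
    out <- rows %>%
      dplyr::mutate(direction = ifelse(.data$slope < 0, "depleted", "enriched")) %>%
      dplyr::select("module", "slope", "se", "p", "direction", "separated") %>%
      dplyr::arrange(.data$p)
  }
  class(out) <- c("mb_module_assoc", class(out))
  out
}
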