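#' Alpha diversity per sample
#'
#' Observed richness, Shannon diversity (natural log, over present ASVs
#' only) and Pielou's evenness `J = H / ln(richness)`. Evenness is `NA`
#' when a sample holds a single ASV (the normaliser is zero).
#'
#' @param counts Sample-by-ASV count matrix with positive sample totals.
#' @return A tibble: `sample_id`, `observed`, `shannon`, `pielou`.
#' @export
alpha_diversity <- function(counts) {
  counts <- as_count_matrix(counts)
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    stop("zero-depth sample(s): ",
         paste(rownames(counts)[tot == 0], collapse = ", "), call. = FALSE)
  }
  res <- purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    p <- counts[i, ] / tot[i]
    p <- p[p > 0]
    s <- length(p)
    h <- -sum(p * log(p))
    tibble::tibble(sample_id = rownames(counts)[i],
                   observed = s,
                   shannon = h,
                   pielou = if (s > 1) h / log(s) else NA_real_)
  })
  res
}

# tips-by-edges incidence of a rooted tree: which tips descend from each edge
branch_incidence <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  nt <- length(tree$tip.label)
  tre <- stats::reorder(tree, "postorder")
  E <- tre$edge
  desc <- matrix(FALSE, nt, nrow(E))
  node_tips <- vector("list", nt + tre$Nnode)
  for (i in seq_len(nt)) node_tips[[i]] <- i
  for (e in seq_len(nrow(E))) {
    tips <- node_tips[[E[e, 2]]]
    desc[tips, e] <- TRUE
    node_tips[[E[e, 1]]] <- c(node_tips[[E[e, 1]]], tips)
  }
  list(length = tre$edge.length, desc = desc, tip_label = tre$tip.label)
}

# align a named community vector to the tree's tip order
align_to_tips <- function(x, tip_label) {
  if (is.null(names(x))) stop("community vectors must be named by ASV id",
                              call. = FALSE)
  extra <- setdiff(names(x)[x > 0], tip_label)
  if (length(extra)) {
    stop("present ASVs missing from tree: ", paste(utils::head(extra, 5), collapse = ", "),
         call. = FALSE)
  }
  out <- stats::setNames(numeric(length(tip_label)), tip_label)
  common <- intersect(names(x), tip_label)
  out[common] <- x[common]
  out
}

#' Unweighted UniFrac distance between two communities
#'
#' Fraction of total branch length leading only to tips present (count > 0)
#' in exactly one of the two communities, out of the branch length leading
#' to tips present in either.
#'
#' @param a,b Named count vectors (names are ASV ids, all present ASVs must
#'   be tree leaves).
#' @param tree Rooted `phylo` tree with branch lengths.
#' @return A distance in `[0, 1]`.
#' @export
unweighted_unifrac <- function(a, b, tree) {
  bi <- branch_incidence(tree)
  a <- align_to_tips(a, bi$tip_label) > 0
  b <- align_to_tips(b, bi$tip_label) > 0
  if (!any(a) && !any(b)) stop("both communities are empty", call. = FALSE)
  in_a <- as.vector(a %*% bi$desc > 0)
  in_b <- as.vector(b %*% bi$desc > 0)
  shared_or_unique <- in_a | in_b
  sum(bi$length[xor(in_a, in_b)]) / sum(bi$length[shared_or_unique])
}

#' Weighted UniFrac distance between two communities
#'
#' Per branch, the absolute difference between the fractions of each
#' community descending from it, weighted by branch length. The normalized
#' variant (default) divides by the branch-length-weighted sum of the two
#' fractions and lies in `[0, 1]`.
#'
#' @inheritParams unweighted_unifrac
#' @param normalized Return the normalized variant (default `TRUE`).
#' @return A non-negative distance; in `[0, 1]` when normalized.
#' @export
weighted_unifrac <- function(a, b, tree, normalized = TRUE) {
  bi <- branch_incidence(tree)
  a <- align_to_tips(a, bi$tip_label)
  b <- align_to_tips(b, bi$tip_label)
  if (sum(a) == 0 || sum(b) == 0) stop("zero-total community", call. = FALSE)
  pa <- as.vector((a / sum(a)) %*% bi$desc)
  pb <- as.vector((b / sum(b)) %*% bi$desc)
  raw <- sum(bi$length * abs(pa - pb))
  if (!normalized) return(raw)
  raw / sum(bi$length * (pa + pb))
}

#' Pairwise beta-diversity distance matrix
#'
#' @param counts Sample-by-ASV count matrix.
#' @param metric One of `"unweighted_unifrac"`, `"weighted_unifrac"`,
#'   `"bray_curtis"`.
#' @param tree Rooted `phylo` tree; required for the UniFrac metrics.
#' @param normalized Passed to [weighted_unifrac()].
#' @return A symmetric, zero-diagonal distance matrix named by sample id.
#' @export
beta_distance_matrix <- function(counts,
                                 metric = c("unweighted_unifrac",
                                            "weighted_unifrac", "bray_curtis"),
                                 tree = NULL, normalized = TRUE) {
  counts <- as_count_matrix(counts)
  metric <- match.arg(metric)
  n <- nrow(counts)
  ids <- rownames(counts)
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  if (metric %in% c("unweighted_unifrac", "weighted_unifrac")) {
    if (is.null(tree)) stop("UniFrac metrics require a tree", call. = FALSE)
    bi <- branch_incidence(tree)
    A <- t(apply(counts, 1, align_to_tips, tip_label = bi$tip_label))
    if (metric == "unweighted_unifrac") {
      M <- (A > 0) %*% bi$desc > 0           # sample x edge presence
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        u <- sum(bi$length[xor(M[i, ], M[j, ])])
        tot <- sum(bi$length[M[i, ] | M[j, ]])
        dm[i, j] <- dm[j, i] <- u / tot
      }
    } else {
      P <- sweep(A, 1, rowSums(A), "/") %*% bi$desc  # sample x edge mass
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        raw <- sum(bi$length * abs(P[i, ] - P[j, ]))
        d <- if (normalized) raw / sum(bi$length * (P[i, ] + P[j, ])) else raw
        dm[i, j] <- dm[j, i] <- d
      }
    }
  } else {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dm[i, j] <- dm[j, i] <-
        sum(abs(counts[i, ] - counts[j, ])) / sum(counts[i, ] + counts[j, ])
    }
  }
  dm
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance with sequential (Type I)
#' sums of squares, as in `vegan::adonis2` with `by = "terms"`. The squared
#' distance matrix is Gower-centred into an inner-product matrix `G`;
#' per-term sums of squares come from traces of nested hat-matrix
#' projections of `G`; significance is assessed by permuting sample
#' identities, with the "+1" estimator
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations)`.
#'
#' @param dm Symmetric distance matrix named by sample id.
#' @param meta Metadata data frame with `sample_id` and the model terms.
#' @param terms Character vector of term names, in fitting order.
#' @param n_permutations Number of random permutations, or a matrix whose
#'   rows are explicit permutations of the sample indices (supply the full
#'   permutation group for an exact test; in that case
#'   `p = mean(F_perm >= F_obs)` over the supplied rows).
#' @param seed Integer seed for the permutation stream.
#' @return A tibble of class `mb_permanova` with one row per term plus
#'   `Residual` and `Total` rows: `term`, `df`, `ss`, `r2`, `pseudo_f`, `p`,
#'   `n_permutations`.
#' @export
permanova <- function(dm, meta, terms, n_permutations = 999, seed = 1L) {
  dm <- as.matrix(dm)
  stopifnot(isSymmetric(unname(dm)), all(diag(dm) == 0))
  meta <- as.data.frame(meta)
  if (!("sample_id" %in% names(meta))) stop("metadata needs sample_id", call. = FALSE)
  if (!setequal(rownames(dm), meta$sample_id)) {
    stop("distance matrix and metadata sample sets differ", call. = FALSE)
  }
  meta <- meta[match(rownames(dm), meta$sample_id), , drop = FALSE]
  miss <- setdiff(terms, names(meta))
  if (length(miss)) stop("missing term(s): ", paste(miss, collapse = ", "), call. = FALSE)

  n <- nrow(dm)
  C <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * C %*% (dm^2) %*% C

  hats <- vector("list", length(terms) + 1L)
  X0 <- matrix(1, n, 1)
  hats[[1]] <- X0 %*% solve(crossprod(X0)) %*% t(X0)
  ranks <- numeric(length(terms) + 1L)
  ranks[1] <- 1
  for (k in seq_along(terms)) {
    f <- stats::as.formula(paste("~", paste(terms[seq_len(k)], collapse = "+")))
    X <- stats::model.matrix(f, data = meta)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      if (k == length(terms)) stop("singular full design", call. = FALSE)
      X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    }
    ranks[k + 1] <- qr(X)$rank
    hats[[k + 1]] <- X %*% solve(crossprod(X)) %*% t(X)
  }
  df_terms <- diff(ranks)
  df_resid <- n - ranks[length(ranks)]
  H_full <- hats[[length(hats)]]

  ss_decompose <- function(Gp) {
    tr <- vapply(hats, function(H) sum(H * Gp), numeric(1))  # tr(H G), G symmetric
    ss_terms <- diff(tr)
    ss_resid <- sum(diag(Gp)) - tr[length(tr)]
    list(ss = ss_terms, resid = ss_resid)
  }
  obs <- ss_decompose(G)
  ss_total <- sum(diag(G))
  f_obs <- (obs$ss / df_terms) / (obs$resid / df_resid)
  if (any(obs$ss < -1e-8)) warning("negative term sum of squares (non-Euclidean distances)")

  perm_f <- function(idx) {
    d <- ss_decompose(G[idx, idx])
    (d$ss / df_terms) / (d$resid / df_resid)
  }
  if (is.matrix(n_permutations)) {
    P <- n_permutations
    stopifnot(ncol(P) == n)
    Fp <- t(apply(P, 1, perm_f))
    if (length(terms) == 1L) Fp <- matrix(Fp, ncol = 1)
    p <- colMeans(sweep(Fp, 2, f_obs, ">=") | abs(sweep(Fp, 2, f_obs, "-")) < 1e-12)
    nperm <- nrow(P)
  } else {
    stopifnot(n_permutations >= 1)
    p <- withr::with_seed(seed, {
      exceed <- numeric(length(terms))
      for (b in seq_len(n_permutations)) {
        fp <- perm_f(sample.int(n))
        exceed <- exceed + (fp >= f_obs - 1e-12)
      }
      (1 + exceed) / (1 + n_permutations)
    })
    nperm <- n_permutations
  }

  out <- tibble::tibble(
    term = c(terms, "Residual", "Total"),
    df = c(df_terms, df_resid, n - 1),
    ss = c(obs$ss, obs$resid, ss_total),
    r2 = c(obs$ss, obs$resid, ss_total) / ss_total,
    pseudo_f = c(f_obs, NA, NA),
    p = c(p, NA, NA),
    n_permutations = c(rep(nperm, length(terms)), NA, NA)
  )
  class(out) <- c("mb_permanova", class(out))
  out
}

#' Rank-based group comparison
#'
#' Two groups: Mann-Whitney U with the tie-corrected normal approximation,
#' two-sided. More than two groups (via `group`): Kruskal-Wallis H with its
#' chi-square p-value. Degenerate all-tied input returns `p = 1`.
#'
#' @param x Numeric values (first group, or all values when `group` given).
#' @param y Numeric values of the second group (two-sample form).
#' @param group Grouping factor aligned with `x` (k-sample form).
#' @return A tibble: `method`, `statistic`, `p`.
#' @export
rank_compare <- function(x, y = NULL, group = NULL) {
  if (!is.null(group)) {
    group <- as.factor(group)
    if (length(unique(x)) == 1L) {
      return(tibble::tibble(method = "kruskal_wallis", statistic = 0, p = 1))
    }
    kt <- stats::kruskal.test(x, group)
    return(tibble::tibble(method = "kruskal_wallis",
                          statistic = unname(kt$statistic), p = kt$p.value))
  }
  if (is.null(y) || !length(x) || !length(y)) stop("both groups must be non-empty", call. = FALSE)
  if (length(unique(c(x, y))) == 1L) {
    return(tibble::tibble(method = "mann_whitney",
                          statistic = length(x) * length(y) / 2, p = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
  tibble::tibble(method = "mann_whitney",
                 statistic = unname(wt$statistic), p = wt$p.value)
}
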