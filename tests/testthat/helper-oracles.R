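# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition, sharing no code with the
# implementation they check.

# UniFrac by explicit recursion over every branch of the tree
oracle_unifrac <- function(a, b, tree, weighted = FALSE, normalized = TRUE) {
  nt <- length(tree$tip.label)
  E <- tree$edge
  L <- tree$edge.length
  desc_tips <- function(node) {
    if (node <= nt) return(node)
    unlist(lapply(E[E[, 1] == node, 2], desc_tips))
  }
  uniq <- 0; either <- 0; raw <- 0; den <- 0
  for (e in seq_len(nrow(E))) {
    tips <- tree$tip.label[desc_tips(E[e, 2])]
    pa <- sum(a[tips]) / sum(a)
    pb <- sum(b[tips]) / sum(b)
    ia <- any(a[tips] > 0); ib <- any(b[tips] > 0)
    raw <- raw + L[e] * abs(pa - pb)
    den <- den + L[e] * (pa + pb)
    if (xor(ia, ib)) uniq <- uniq + L[e]
    if (ia || ib) either <- either + L[e]
  }
  if (!weighted) return(uniq / either)
  if (normalized) raw / den else raw
}

# BH step-up straight from its definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m), function(i) {
    cand <- vapply(which(ps >= ps[i] - 1e-15), function(j) min(1, m * ps[j] / j),
                   numeric(1))
    min(cand)
  }, numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# connected components of a thresholded correlation graph by BFS
oracle_components <- function(rho, threshold, absolute = FALSE) {
  D <- ncol(rho)
  vals <- if (absolute) abs(rho) else rho
  adj <- vals >= threshold
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, D)
  cid <- 0L
  for (s in seq_len(D)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  sizes <- table(comp)
  keep <- as.integer(names(sizes)[sizes >= 2])
  lapply(keep, function(k) sort(colnames(rho)[comp == k]))
}

# the three ASV-filter rules re-evaluated literally, column by column
oracle_filter_survivors <- function(counts, rule,
                                    threshold = NULL, is_control = NULL,
                                    control_prev = 0.15, sample_prev = 0.15,
                                    min_prev = 0.10) {
  keep <- logical(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    col <- counts[, j]
    keep[j] <- switch(rule,
      low_freq = !(sum(col) / sum(counts) < threshold),
      decontam = {
        pc <- mean(col[is_control] > 0)
        pb <- mean(col[!is_control] > 0)
        !(pc > control_prev && pb < sample_prev)
      },
      prevalence = !(mean(col > 0) < min_prev)
    )
  }
  colnames(counts)[keep]
}

# two-sided Fisher p by enumerating every table with the observed margins,
# using exact rational-style probabilities from choose()
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }, numeric(1))
  obs <- probs[a - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# all permutations of 1..n (n small), one per row
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# direct between/within sum-of-squares PERMANOVA for a single factor,
# from the pairwise-squared-distance identities
oracle_permanova_f <- function(dm, groups) {
  n <- nrow(dm)
  d2 <- dm^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    block <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(block[upper.tri(block)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  df1 <- length(unique(groups)) - 1
  df2 <- n - length(unique(groups))
  (ss_between / df1) / (ss_within / df2)
}

# small random community fixture shared by several tests
random_count_table <- function(n = 12, D = 8, seed = 1, lambda = 20) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n * D, lambda), n, D,
                dimnames = list(sprintf("s%02d", seq_len(n)),
                                sprintf("ASV_%03d", seq_len(D))))
    m
  })
}
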