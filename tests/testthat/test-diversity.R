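test_that("alpha diversity matches closed forms and vegan", {
  m <- rbind(uniform = c(5, 5, 5, 5), single = c(9, 0, 0, 0),
             skew = c(2, 1, 1, 0))
  colnames(m) <- paste0("ASV_", 1:4)
  a <- alpha_diversity(m)
  expect_equal(a$shannon[1], log(4), tolerance = 1e-12)
  expect_equal(a$pielou[1], 1, tolerance = 1e-12)
  expect_identical(a$observed[2], 1L)
  expect_equal(a$shannon[2], 0)
  expect_true(is.na(a$pielou[2]))
  # fractions (0.5, 0.25, 0.25)
  expect_equal(a$shannon[3], 1.039721, tolerance = 1e-6)
  expect_equal(a$pielou[3], 0.946395, tolerance = 1e-6)
  skip_if_not_installed("vegan")
  big <- random_count_table(seed = 4)
  expect_equal(alpha_diversity(big)$shannon,
               unname(vegan::diversity(big, index = "shannon")),
               tolerance = 1e-12)
})

test_that("shannon is maximal at uniform composition for fixed richness", {
  withr::with_seed(10, {
    for (i in 1:10) {
      cnt <- rbind(u = rep(50, 6), r = rmultinom(1, 300, runif(6))[, 1])
      colnames(cnt) <- paste0("a", 1:6)
      cnt["r", cnt["r", ] == 0] <- 1    # keep richness fixed
      a <- alpha_diversity(cnt)
      expect_lte(a$shannon[2], a$shannon[1] + 1e-12)
    }
  })
})

test_that("unweighted UniFrac obeys its closed-form special cases", {
  tr <- generate_random_tree(LETTERS[1:4], seed = 2)
  a <- stats::setNames(c(3, 1, 0, 0), LETTERS[1:4])
  expect_equal(unweighted_unifrac(a, a * 5, tr), 0)
  # communities on disjoint cherries of a balanced tree share no branches
  tr2 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  x <- stats::setNames(c(1, 1, 0, 0), LETTERS[1:4])
  y <- stats::setNames(c(0, 0, 1, 1), LETTERS[1:4])
  expect_equal(unweighted_unifrac(x, y, tr2), 1)
  expect_error(unweighted_unifrac(x * 0, y * 0, tr2), "empty")
})

test_that("both UniFrac variants match the exhaustive branch oracle", {
  withr::with_seed(21, {
    for (i in 1:12) {
      tr <- generate_random_tree(LETTERS[1:5], seed = 100 + i)
      a <- stats::setNames(rpois(5, 2), LETTERS[1:5])
      b <- stats::setNames(rpois(5, 2), LETTERS[1:5])
      if (sum(a) == 0 || sum(b) == 0) next
      expect_equal(unweighted_unifrac(a, b, tr),
                   oracle_unifrac(a, b, tr), tolerance = 1e-12)
      expect_equal(weighted_unifrac(a, b, tr),
                   oracle_unifrac(a, b, tr, weighted = TRUE), tolerance = 1e-12)
      expect_equal(weighted_unifrac(a, b, tr, normalized = FALSE),
                   oracle_unifrac(a, b, tr, weighted = TRUE, normalized = FALSE),
                   tolerance = 1e-12)
    }
  })
})

test_that("unweighted UniFrac is a metric; weighted is bounded and scale-free", {
  withr::with_seed(31, {
    for (i in 1:8) {
      tr <- generate_random_tree(LETTERS[1:5], seed = 200 + i)
      cm <- matrix(rpois(15, 2), 3, 5,
                   dimnames = list(c("x", "y", "z"), LETTERS[1:5]))
      cm[rowSums(cm) == 0, 1] <- 1
      x <- cm[1, ]; y <- cm[2, ]; z <- cm[3, ]
      dxy <- unweighted_unifrac(x, y, tr)
      dxz <- unweighted_unifrac(x, z, tr)
      dyz <- unweighted_unifrac(y, z, tr)
      expect_equal(dxy, unweighted_unifrac(y, x, tr))
      expect_equal(unweighted_unifrac(x, x, tr), 0)
      expect_lte(dxy, dxz + dyz + 1e-12)
      w <- weighted_unifrac(x, y, tr)
      expect_gte(w, 0); expect_lte(w, 1)
      expect_equal(w, weighted_unifrac(x * 7, y, tr), tolerance = 1e-12)
    }
  })
})

test_that("distance matrices are symmetric recomputations of the pairwise op", {
  m <- random_count_table(n = 5, D = 6, seed = 3)
  tr <- generate_random_tree(colnames(m), seed = 4)
  for (metric in c("unweighted_unifrac", "weighted_unifrac", "bray_curtis")) {
    dm <- beta_distance_matrix(m, metric, tr)
    expect_true(isSymmetric(unname(dm)))
    expect_true(all(diag(dm) == 0))
  }
  dm <- beta_distance_matrix(m, "weighted_unifrac", tr)
  expect_equal(dm["s01", "s03"],
               weighted_unifrac(m["s01", ], m["s03", ], tr), tolerance = 1e-12)
  dup <- m[c(1, 1, 2), ]
  rownames(dup) <- c("a", "b", "c")
  expect_equal(beta_distance_matrix(dup, "bray_curtis")["a", "b"], 0)
  expect_error(beta_distance_matrix(m, "weighted_unifrac"), "tree")
  one <- m[1, , drop = FALSE]
  expect_identical(dim(beta_distance_matrix(one, "bray_curtis")), c(1L, 1L))
})

test_that("permanova reproduces adonis2 and its algebraic identities", {
  skip_if_not_installed("vegan")
  withr::with_seed(17, {
    n <- 12
    pts <- matrix(rnorm(n * 3), n)
    dm <- as.matrix(dist(pts))
    dimnames(dm) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
    meta <- data.frame(sample_id = rownames(dm),
                       group = rep(c("A", "B"), each = 6), cov = rnorm(n))
    pm <- permanova(dm, meta, c("group", "cov"), n_permutations = 99, seed = 1)
    ad <- vegan::adonis2(stats::as.dist(dm) ~ group + cov, data = meta,
                         permutations = 99, by = "terms")
    expect_equal(pm$ss[1:2], ad$SumOfSqs[1:2], tolerance = 1e-10)
    expect_equal(pm$pseudo_f[1:2], ad$F[1:2], tolerance = 1e-10)
    expect_equal(pm$r2[1:2], ad$R2[1:2], tolerance = 1e-10)
    # sequential SS + residual = total = tr(G)
    expect_equal(sum(pm$ss[1:3]), pm$ss[4], tolerance = 1e-8)
    # single two-level factor equals the direct between/within formula
    pm1 <- permanova(dm, meta, "group", n_permutations = 9, seed = 1)
    f_direct <- oracle_permanova_f(dm, meta$group)
    expect_equal(pm1$pseudo_f[1], f_direct, tolerance = 1e-10)
  })
})

test_that("permanova finds no structure in relabelled null data", {
  withr::with_seed(23, {
    n <- 20
    dm <- as.matrix(dist(matrix(rnorm(n * 4), n)))
    dimnames(dm) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
    meta <- data.frame(sample_id = rownames(dm),
                       group = sample(rep(c("A", "B"), each = 10)))
    pm <- permanova(dm, meta, "group", n_permutations = 199, seed = 5)
    expect_lt(pm$r2[1], 0.15)
    expect_gt(pm$p[1], 0.05)
  })
})

test_that("rank comparisons follow U and H conventions", {
  rc <- rank_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(rc$statistic, 4.5)    # n^2 / 2
  expect_gt(rc$p, 0.95)
  expect_equal(rank_compare(c(1, 2), c(3, 4))$statistic, 0)
  expect_equal(rank_compare(rep(2, 4), rep(2, 3))$p, 1)
  kw <- rank_compare(rep(1, 9), group = rep(letters[1:3], each = 3))
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p, 1)
  kw2 <- rank_compare(c(1, 2, 3, 7, 8, 9, 4, 5, 6),
                      group = rep(letters[1:3], each = 3))
  ref <- stats::kruskal.test(c(1, 2, 3, 7, 8, 9, 4, 5, 6),
                             factor(rep(letters[1:3], each = 3)))
  expect_equal(kw2$statistic, unname(ref$statistic))
  expect_error(rank_compare(numeric(0), c(1)), "non-empty")
})
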