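test_that("fraction estimates are Dirichlet posterior means", {
  m <- matrix(c(1, 1, 3, 0), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  fr <- estimate_fractions(m)
  expect_equal(unname(fr["s1", ]), c(0.5, 0.5))
  expect_equal(unname(fr["s2", ]), c(4 / 5, 1 / 5))
  big <- random_count_table(seed = 5)
  expect_true(all(abs(rowSums(estimate_fractions(big)) - 1) < 1e-12))
  expect_true(all(estimate_fractions(big) > 0))
})

test_that("the variation matrix is the log-ratio variance", {
  # perfectly proportional components have zero log-ratio variance
  fr <- matrix(c(0.1, 0.2, 0.7, 0.2, 0.4, 0.4), 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  Tm <- variation_matrix(fr)
  expect_equal(Tm["a", "b"], 0)
  expect_true(all(diag(Tm) == 0))
  expect_true(isSymmetric(unname(Tm)))
  # two samples with log-ratios {0, 2}: unbiased variance 2
  f2 <- matrix(c(0.5, 0.5, exp(2) / (1 + exp(2)), 1 / (1 + exp(2))),
               2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_equal(variation_matrix(f2)["a", "b"], 2, tolerance = 1e-12)
  expect_error(variation_matrix(fr * 0), "positive")
})

test_that("sparcc output is a valid correlation matrix", {
  m <- random_count_table(n = 30, D = 10, seed = 6, lambda = 50)
  rho <- sparcc(m)
  expect_true(isSymmetric(unname(unclass(rho))))
  expect_true(all(diag(rho) == 1))
  expect_true(all(rho >= -1 & rho <= 1))
  expect_error(sparcc(m[, 1:3]), "underdetermined")
})

test_that("sparcc is insensitive to per-sample scaling at high depth", {
  p <- sim_params(n_samples_per_group = 50, n_asvs = 20, n_controls = 0,
                  depth_mean = 20000, seed = 14)
  sim <- generate_community(p)
  rho1 <- sparcc(sim$counts)
  scaled <- sim$counts
  scaled[3, ] <- scaled[3, ] * 5L        # rescale one sample's library
  rho2 <- sparcc(scaled)
  expect_lt(max(abs(rho1 - rho2)), 0.02)
})

test_that("sparcc recovers a planted correlation block", {
  p <- sim_params(n_samples_per_group = 100, n_asvs = 50, n_controls = 0,
                  module_spec = data.frame(size = 5, r = 0.8), seed = 15)
  sim <- generate_community(p)
  rho <- sparcc(sim$counts)
  blk <- rho[1:5, 1:5]
  expect_lt(abs(mean(blk[upper.tri(blk)]) - 0.8), 0.15)
})

test_that("module detection equals brute-force connected components", {
  ids <- paste0("a", 1:6)
  rho <- diag(6); dimnames(rho) <- list(ids, ids)
  expect_identical(nrow(detect_modules(rho, 0.5)), 0L)
  # two planted blocks
  rho2 <- rho
  rho2[1, 2] <- rho2[2, 1] <- 0.9
  rho2[3, 4] <- rho2[4, 3] <- 0.9
  mods <- detect_modules(rho2, 0.5)
  expect_identical(sort(unique(mods$module)), 1:2)
  expect_identical(mods$asv_id[mods$module == 1], c("a1", "a2"))
  expect_identical(mods$asv_id[mods$module == 2], c("a3", "a4"))
  # chain connectivity is transitive through components
  rho3 <- rho
  rho3[1, 2] <- rho3[2, 1] <- 0.6
  rho3[2, 3] <- rho3[3, 2] <- 0.6
  rho3[1, 3] <- rho3[3, 1] <- 0.1
  m3 <- detect_modules(rho3, 0.5)
  expect_identical(m3$asv_id, c("a1", "a2", "a3"))
  expect_identical(unique(m3$module), 1L)
  # negative correlations only count in absolute mode
  rho4 <- rho
  rho4[5, 6] <- rho4[6, 5] <- -0.8
  expect_identical(nrow(detect_modules(rho4, 0.5)), 0L)
  expect_identical(detect_modules(rho4, 0.5, absolute = TRUE)$asv_id,
                   c("a5", "a6"))
  withr::with_seed(41, {
    for (i in 1:8) {
      D <- sample(4:12, 1)
      S <- matrix(runif(D * D, -1, 1), D)
      S <- (S + t(S)) / 2; diag(S) <- 1
      dimnames(S) <- list(paste0("v", 1:D), paste0("v", 1:D))
      got <- detect_modules(S, 0.3)
      want <- oracle_components(S, 0.3)
      got_sets <- unname(split(got$asv_id, got$module))
      expect_identical(length(got_sets), length(want))
      expect_true(setequal(lapply(got_sets, sort), want))
      expect_false(anyDuplicated(got$asv_id) > 0)   # modules are disjoint
    }
  })
})

test_that("module abundance sums member fractions per sample", {
  m <- random_count_table(n = 4, D = 5, seed = 8)
  mods <- tibble::tibble(module = c(1L, 1L), asv_id = colnames(m)[1:2])
  ma <- module_abundance(m, mods)
  fr <- relative_abundance(m)
  expect_equal(unname(ma[, 1]), unname(fr[, 1] + fr[, 2]))
  all_mod <- tibble::tibble(module = 1L, asv_id = colnames(m))
  expect_equal(unname(module_abundance(m, all_mod)[, 1]), rep(1, 4))
  none <- tibble::tibble(module = integer(0), asv_id = character(0))
  expect_identical(ncol(module_abundance(m, none)), 0L)
  bad <- tibble::tibble(module = 1L, asv_id = "nope")
  expect_error(module_abundance(m, bad), "nope")
})

test_that("logistic slopes match the closed-form 2x2 log odds ratio", {
  withr::with_seed(9, {
    for (i in 1:6) {
      tb <- matrix(sample(3:20, 4, replace = TRUE), 2)
      y <- rep(c(1, 1, 0, 0), c(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]))
      x <- rep(c(1, 0, 1, 0), c(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]))
      fit <- logistic_fit(y, x)
      lor <- log(tb[1, 1] * tb[2, 2] / (tb[1, 2] * tb[2, 1]))
      expect_equal(fit$slope, lor, tolerance = 1e-8)
    }
  })
  expect_equal(logistic_fit(c(0, 1, 0, 1), rep(2, 4))$slope, 0)
  expect_error(logistic_fit(rep(1, 5), rnorm(5)), "single class")
  sep <- logistic_fit(c(0, 0, 0, 1, 1, 1), c(1, 2, 3, 10, 11, 12))
  expect_true(sep$separated)
  expect_true(is.na(sep$p))
})

test_that("logistic regression recovers a known slope", {
  withr::with_seed(19, {
    ok <- replicate(10, {
      x <- rnorm(500)
      y <- rbinom(500, 1, plogis(0.3 - 1.5 * x))
      abs(logistic_fit(y, x)$slope - (-1.5)) < 0.5
    })
    expect_gte(mean(ok), 0.9)
  })
})

test_that("module association flags planted depletion with direction", {
  p <- sim_params(n_samples_per_group = 65, n_asvs = 30, n_controls = 0,
                  module_spec = data.frame(size = 5, r = 0.8),
                  effect_spec = data.frame(asv = 1:5, log2_effect = -1.5),
                  seed = 16, allow_module_effects = TRUE)
  sim <- generate_community(p)
  mods <- tibble::tibble(module = 1L, asv_id = colnames(sim$counts)[1:5])
  assoc <- associate_modules(module_abundance(sim$counts, mods), sim$metadata)
  expect_identical(assoc$direction, ifelse(assoc$slope < 0, "depleted", "enriched"))
  expect_lt(assoc$slope[1], 0)
  expect_lt(assoc$p[1], 0.05)
  empty <- associate_modules(
    module_abundance(sim$counts,
                     tibble::tibble(module = integer(0), asv_id = character(0))),
    sim$metadata)
  expect_identical(nrow(empty), 0L)
})
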