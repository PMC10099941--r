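gene_features <- function(G, len) {
  feature_table(sprintf("g%04d", seq_len(G)), rep("gene", G),
                length_bp = len)
}

test_that("TPM follows the length-normalized formula", {
  ## single gene: whatever the count, TPM = 1e6
  ft <- gene_features(1, 500)
  m <- matrix(7L, 1, 2, dimnames = list("g0001", c("s1", "s2")))
  expect_equal(unname(compute_tpm(m, ft)), matrix(1e6, 1, 2),
               ignore_attr = TRUE)
  ## equal per-base rates -> equal TPM
  ft2 <- gene_features(2, c(1000, 2000))
  m2 <- matrix(c(10L, 20L), 2, 1,
               dimnames = list(c("g0001", "g0002"), "s1"))
  expect_equal(unname(compute_tpm(m2, ft2))[, 1], c(5e5, 5e5))
  ## all-zero sample warns and yields zeros
  m3 <- matrix(c(1L, 1L, 0L, 0L), 2,
               dimnames = list(c("g0001", "g0002"), c("s1", "s2")))
  expect_warning(tpm3 <- compute_tpm(m3, ft2), "all-zero")
  expect_equal(unname(tpm3[, 2]), c(0, 0))
})

test_that("TPM matches a naive per-cell oracle and columns sum to 1e6", {
  set.seed(21)
  G <- 100
  len <- sample(200:3000, G)
  m <- nb_matrix(G, mu = 200, size = 2, n_samples = 5)
  ft <- gene_features(G, len)
  tpm <- compute_tpm(m, ft)
  oracle <- matrix(0, G, 5)
  for (s in 1:5) {
    denom <- sum(m[, s] / len)
    for (g in 1:G) oracle[g, s] <- 1e6 * (m[g, s] / len[g]) / denom
  }
  expect_equal(unname(tpm), oracle, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unname(colSums(tpm)), rep(1e6, 5))
})

test_that("CPM normalizes to 1e6 with prior 0 and matches the oracle", {
  m <- matrix(c(1L, 3L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(compute_cpm(m))[, 1], c(2.5e5, 7.5e5))
  set.seed(22)
  m2 <- nb_matrix(50, 100, 3, 4)
  expect_equal(unname(colSums(compute_cpm(m2))), rep(1e6, 4))
  ## prior convention: p_s = prior * N_s / mean(N); denom N_s + 2 p_s
  prior <- 0.5
  N <- colSums(m2)
  pr <- prior * N / mean(N)
  oracle <- sweep(sweep(m2, 2, pr, "+"), 2, N + 2 * pr, "/") * 1e6
  expect_equal(unname(compute_cpm(m2, prior = prior)), unname(oracle),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(compute_cpm(m2, prior = -1), ">= 0")
})

test_that("TMM factors are 1 for identical or proportional columns", {
  set.seed(23)
  a <- rnbinom(300, mu = 150, size = 3) + 1L
  m <- cbind(s1 = a, s2 = a, s3 = a)
  rownames(m) <- paste0("g", 1:300)
  expect_equal(unname(tmm_factors(m)), rep(1, 3))
  m2 <- cbind(s1 = a, s2 = 2L * a)
  rownames(m2) <- paste0("g", 1:300)
  expect_equal(unname(tmm_factors(m2)), c(1, 1))
})

test_that("TMM matches the reference implementation to 1e-8", {
  set.seed(24)
  G <- 200
  m <- nb_matrix(G, mu = 2^runif(G, 4, 9), size = 4, n_samples = 6)
  ## 5% high-count contaminant genes in one sample
  m[sample(G, 10), 3] <- m[sample(G, 10), 3] + 50000L
  skip_if_not_installed("edgeR")
  expect_equal(unname(tmm_factors(m)),
               unname(edgeR::calcNormFactors(m, method = "TMM")),
               tolerance = 1e-8)
  ## geometric mean exactly 1
  expect_equal(exp(mean(log(tmm_factors(m)))), 1, tolerance = 1e-9)
})

test_that("TMM is insensitive to scaling a single column", {
  ## library-size scaling leaves M-values untouched; only the
  ## inverse-variance weights move, so factors agree to ~1%
  set.seed(25)
  m <- nb_matrix(150, 300, 5, 4)
  f1 <- tmm_factors(m)
  m2 <- m
  m2[, 2] <- m2[, 2] * 3L
  expect_equal(unname(tmm_factors(m2)), unname(f1), tolerance = 0.02)
})

test_that("expression filter is strict and monotone", {
  m <- rbind(at_threshold = rep(2, 4), above3 = c(3, 3, 3, 0),
             above2 = c(3, 3, 0, 0))
  colnames(m) <- paste0("s", 1:4)
  expect_false("at_threshold" %in% filter_expressed(m, 2, 3))
  expect_true("above3" %in% filter_expressed(m, 2, 3))
  expect_false("above2" %in% filter_expressed(m, 2, 3))
  set.seed(26)
  r <- matrix(runif(500, 0, 10), 100, 5,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:5)))
  for (v in c(1, 2, 5)) {
    expect_true(all(filter_expressed(r, v + 1, 2) %in%
                      filter_expressed(r, v, 2)))
  }
})

test_that("binomial thinning equalizes group means and never inflates", {
  st <- two_group_table(n = 3)
  set.seed(27)
  m <- cbind(nb_matrix(200, 2000, 10, 3), nb_matrix(200, 1000, 10, 3))
  colnames(m) <- st$sample_id
  storage.mode(m) <- "integer"
  ## zero cells stay zero; thinned cells never exceed the originals
  m[1, ] <- 0L
  thin <- downsample_to_group_mean(m, st, seed = 4)
  expect_true(all(thin <= m))
  expect_true(all(thin[1, ] == 0))
  ## already equal group means: unchanged (probability-1 branch)
  m_eq <- cbind(m[, 1:3], m[, 1:3])
  colnames(m_eq) <- st$sample_id
  expect_identical(downsample_to_group_mean(m_eq, st, seed = 4), m_eq)
  ## expectation: mean of 50 replicate thinnings within 1% of target
  lib <- colSums(m)
  target <- min(tapply(lib, st$group, mean))
  tots <- replicate(50, {
    seed <- sample.int(1e6, 1)
    mean(colSums(downsample_to_group_mean(m, st, seed = seed))[1:3])
  })
  expect_lt(abs(mean(tots) - target) / target, 0.01)
})
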