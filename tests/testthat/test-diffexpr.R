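test_that("BH adjustment matches the hand step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  ## independent step-up oracle on random p-values
  set.seed(31)
  p <- runif(200)^2
  m <- length(p)
  o <- order(p)
  q_oracle <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    cands <- vapply(seq(rank_i, m), function(r) {
      min(m * p[o[r]] / r, 1)
    }, numeric(1))
    q_oracle[i] <- min(cands)
  }
  expect_equal(bh_adjust(p), q_oracle, tolerance = 1e-12)
})

test_that("dispersion estimation recovers known truth", {
  st <- two_group_table()
  ## Poisson data: shrunken dispersion collapses toward 0
  set.seed(32)
  G <- 2000
  mu <- 2^runif(G, 4, 10)
  Y <- cbind(matrix(rpois(G * 6, mu), G), matrix(rpois(G * 6, mu), G))
  dimnames(Y) <- list(sprintf("g%04d", 1:G), st$sample_id)
  d <- estimate_dispersions(Y, st)
  expect_lt(median(d$shrunken, na.rm = TRUE), 0.02)
  ## NB with dispersion 0.1
  Y2 <- cbind(matrix(rnbinom(G * 6, mu = mu, size = 10), G),
              matrix(rnbinom(G * 6, mu = mu, size = 10), G))
  dimnames(Y2) <- dimnames(Y)
  d2 <- estimate_dispersions(Y2, st)
  med <- median(d2$shrunken, na.rm = TRUE)
  expect_gt(med, 0.07)
  expect_lt(med, 0.13)
  ## shrunken lies between raw and common
  ok <- !is.na(d2$raw)
  lo <- pmin(d2$raw[ok], d2$common)
  hi <- pmax(d2$raw[ok], d2$common)
  expect_true(all(d2$shrunken[ok] >= lo - 1e-12 &
                    d2$shrunken[ok] <= hi + 1e-12))
})

test_that("identical counts in every sample give raw dispersion 0", {
  st <- two_group_table(n = 3)
  Y <- matrix(50L, 2, 6, dimnames = list(c("gA", "gB"), st$sample_id))
  Y[2, ] <- 10L  # second gene keeps TMM well-defined
  d <- estimate_dispersions(Y, st)
  expect_equal(unname(d$raw["gA"]), 0)
})

test_that("all-zero genes are flagged and excluded from testing", {
  st <- two_group_table(n = 3)
  Y <- nb_matrix(20, 100, 5, 6, seed = 33)
  colnames(Y) <- st$sample_id
  Y[5, ] <- 0L
  d <- estimate_dispersions(Y, st)
  expect_identical(d$excluded, "g0005")
  expect_true(is.na(d$shrunken["g0005"]))
  r <- pairwise_contrast(Y, st, "flower", "Co2", "Cg2", d)
  expect_true(is.na(r$pvalue[r$feature_id == "g0005"]))
  expect_identical(r$status[r$feature_id == "g0005"], "ns")
})

test_that("contrasts are antisymmetric and detect a large true effect", {
  st <- two_group_table()
  set.seed(34)
  G <- 500
  mu <- 2^runif(G, 5, 9)
  Y <- cbind(matrix(rnbinom(G * 6, mu = mu, size = 100), G),
             matrix(rnbinom(G * 6, mu = mu, size = 100), G))
  Y[1, 1:6] <- rnbinom(6, mu = mu[1] * 8, size = 100)  # true 8-fold
  dimnames(Y) <- list(sprintf("g%04d", 1:G), st$sample_id)
  d <- estimate_dispersions(Y, st)
  ab <- pairwise_contrast(Y, st, "flower", "Co2", "Cg2", d)
  ba <- pairwise_contrast(Y, st, "flower", "Cg2", "Co2", d)
  expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-8)
  expect_equal(ab$qvalue, ba$qvalue, tolerance = 1e-8)
  map <- c(up = "down", down = "up", ns = "ns")
  expect_identical(unname(map[ab$status]), ba$status)
  expect_identical(ab$status[1], "up")
  expect_lt(ab$qvalue[1], 1e-3)
  expect_gt(ab$log2fc[1], 2.5)
})

test_that("raising the fold-change threshold never adds DEGs", {
  st <- two_group_table()
  set.seed(35)
  G <- 800
  mu <- 2^runif(G, 4, 9)
  fc <- ifelse(runif(G) < 0.1, 2^rnorm(G, 0, 2), 1)
  Y <- cbind(matrix(rnbinom(G * 6, mu = mu * fc, size = 15), G),
             matrix(rnbinom(G * 6, mu = mu, size = 15), G))
  dimnames(Y) <- list(sprintf("g%04d", 1:G), st$sample_id)
  d <- estimate_dispersions(Y, st)
  n_deg <- vapply(c(1.5, 2, 3, 6), function(f) {
    th <- analysis_thresholds(fc_threshold = f)
    r <- pairwise_contrast(Y, st, "flower", "Co2", "Cg2", d, thresholds = th)
    sum(r$status != "ns")
  }, numeric(1))
  expect_true(all(diff(n_deg) <= 0))
  expect_gt(n_deg[1], 0)
})

test_that("with dispersion 0 the LRT equals the Poisson deviance test", {
  st <- two_group_table(n = 4)
  set.seed(36)
  G <- 50
  mu <- 2^runif(G, 6, 10)
  Y <- matrix(rpois(G * 8, rep(mu, 8)), G,
              dimnames = list(sprintf("g%04d", 1:G), st$sample_id))
  N <- colSums(Y)
  disp0 <- structure(list(
    raw = setNames(rep(0, G), rownames(Y)),
    shrunken = setNames(rep(0, G), rownames(Y)),
    common = 0, prior_df = 10, df_res = 6,
    effective_sizes = setNames(N, colnames(Y)),
    excluded = character(0), samples = st, tissue = "flower"),
    class = "dispersion_estimates")
  r <- pairwise_contrast(Y, st, "flower", "Co2", "Cg2", disp0)
  grp <- factor(st$group)
  p_oracle <- vapply(seq_len(G), function(g) {
    f0 <- glm(Y[g, ] ~ offset(log(N)), family = poisson)
    f1 <- glm(Y[g, ] ~ grp + offset(log(N)), family = poisson)
    pchisq(deviance(f0) - deviance(f1), df = 1, lower.tail = FALSE)
  }, numeric(1))
  expect_equal(r$pvalue, p_oracle, tolerance = 1e-6)
})

test_that("deg_summary tabulates and swaps with the contrast", {
  ids <- paste0("g", 1:6)
  r1 <- fake_de(ids, c("up", "up", "up", "down", "ns", "ns"),
                "F2", "Co2")
  s <- deg_summary(r1)
  expect_equal(c(s$up, s$down, s$total), c(3, 1, 4))
  r2 <- fake_de(ids, c("down", "down", "down", "up", "ns", "ns"),
                "Co2", "F2")
  s2 <- deg_summary(list(a = r1, b = r2))
  expect_equal(s2$up, c(3, 1))
  expect_equal(s2$down, c(1, 3))
  empty <- fake_de(ids, rep("ns", 6), "F2", "Co2")
  expect_equal(deg_summary(empty)$total, 0)
})
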