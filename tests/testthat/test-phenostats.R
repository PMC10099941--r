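test_that("one-way ANOVA equals t-squared for two groups and the SS oracle", {
  set.seed(71)
  v <- c(rnorm(8, 0), rnorm(8, 1))
  g <- rep(c("a", "b"), each = 8)
  a <- one_way_anova(v, g)
  tt <- t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic^2), tolerance = 1e-10)
  ## direct sum-of-squares oracle on 4 unbalanced groups
  v2 <- rnorm(37)
  g2 <- sample(letters[1:4], 37, replace = TRUE)
  a2 <- one_way_anova(v2, g2)
  gm <- mean(v2)
  means <- tapply(v2, g2, mean)
  ns <- table(g2)
  ss_between <- sum(ns * (means - gm)^2)
  ss_within <- sum((v2 - means[g2])^2)
  k <- length(means)
  F_oracle <- (ss_between / (k - 1)) / (ss_within / (length(v2) - k))
  expect_equal(a2$F, F_oracle, tolerance = 1e-10)
  ## SS decomposition
  expect_equal(ss_between + ss_within, sum((v2 - gm)^2), tolerance = 1e-9)
  expect_equal(unname(a2$df), c(k - 1, length(v2) - k))
  expect_error(one_way_anova(rep(1, 10), rep(c("a", "b"), 5)),
               "zero total variance")
  expect_error(one_way_anova(rnorm(5), rep("a", 5)), ">= 2 groups")
})

test_that("widely separated groups get all-distinct Tukey letters", {
  set.seed(72)
  v <- c(rnorm(10, 0, 1), rnorm(10, 50, 1), rnorm(10, 100, 1))
  g <- rep(c("lo", "mid", "hi"), each = 10)
  r <- tukey_hsd_letters(v, g)
  expect_equal(sort(unname(r$letters)), c("a", "b", "c"))
  expect_equal(unname(r$letters["hi"]), "a")  # highest mean gets "a"
  single <- tukey_hsd_letters(rnorm(5), rep("only", 5))
  expect_equal(unname(single$letters), "a")
})

test_that("letters agree with the pairwise significance matrix", {
  set.seed(73)
  for (rep_i in 1:50) {
    k <- sample(3:6, 1)
    n <- sample(4:8, 1)
    shift <- sample(c(0, 1, 3), k, replace = TRUE)
    v <- rnorm(k * n) + rep(shift, each = n)
    g <- rep(paste0("G", seq_len(k)), each = n)
    r <- tukey_hsd_letters(v, g)
    for (p in seq_len(nrow(r$pairwise))) {
      g1 <- r$pairwise$group1[p]
      g2 <- r$pairwise$group2[p]
      shared <- any(strsplit(r$letters[[g1]], "")[[1]] %in%
                      strsplit(r$letters[[g2]], "")[[1]])
      expect_identical(shared, r$pairwise$p_adj[p] >= 0.05,
                       info = sprintf("rep %d pair %s-%s", rep_i, g1, g2))
    }
  }
})

test_that("quasi-binomial fit shares binomial coefficients, scales SEs", {
  set.seed(74)
  obs <- data.frame(numerator = rbinom(40, 500, 0.7), denominator = 500,
                    is_hybrid = rep(c(TRUE, FALSE), 20),
                    is_tetraploid = rep(c(TRUE, FALSE), each = 20))
  fit <- quasibinomial_glm(obs, c("is_hybrid", "is_tetraploid"),
                           "is_hybrid:is_tetraploid")
  plain <- glm(cbind(numerator, denominator - numerator) ~
                 is_hybrid * is_tetraploid, family = binomial, data = obs)
  expect_equal(fit$coefficients$estimate, unname(coef(plain)),
               tolerance = 1e-8)
  se_plain <- summary(plain)$coefficients[, 2]
  expect_equal(fit$coefficients$se / unname(se_plain),
               rep(sqrt(fit$dispersion), 4), tolerance = 1e-6)
  ## dispersion = Pearson chi-square / residual df
  expect_equal(fit$dispersion,
               sum(residuals(plain, type = "pearson")^2) /
                 df.residual(plain))
})

test_that("type II deviance F-tests match the car oracle", {
  skip_if_not_installed("car")
  set.seed(75)
  obs <- data.frame(numerator = rbinom(60, 400, 0.6), denominator = 400,
                    is_hybrid = sample(c(TRUE, FALSE), 60, replace = TRUE),
                    is_tetraploid = sample(c(TRUE, FALSE), 60,
                                           replace = TRUE),
                    lane = sample(c("l1", "l2", "l3"), 60, replace = TRUE))
  fit <- quasibinomial_glm(obs, c("is_hybrid", "is_tetraploid", "lane"),
                           "is_hybrid:is_tetraploid")
  g <- glm(cbind(numerator, denominator - numerator) ~ is_hybrid +
             is_tetraploid + lane + is_hybrid:is_tetraploid,
           family = quasibinomial, data = obs)
  ca <- car::Anova(g, type = 2, test.statistic = "F")
  expect_equal(fit$anova_table$F, ca$`F value`[seq_len(4)],
               tolerance = 1e-8)
  expect_equal(fit$anova_table$pvalue, ca$`Pr(>F)`[seq_len(4)],
               tolerance = 1e-8)
  expect_error(quasibinomial_glm(
    transform(obs, denominator = 0), "is_hybrid"), "> 0")
})

test_that("the dispersion estimate is calibrated on pure binomial data", {
  set.seed(76)
  phis <- replicate(200, {
    obs <- data.frame(numerator = rbinom(70, 600, 0.85), denominator = 600,
                      is_hybrid = rep(c(TRUE, FALSE), 35),
                      is_tetraploid = rep(c(TRUE, FALSE), each = 35))
    quasibinomial_glm(obs, c("is_hybrid", "is_tetraploid"),
                      "is_hybrid:is_tetraploid")$dispersion
  })
  expect_gt(mean(phis > 0.7 & phis < 1.4), 0.9)
  expect_equal(mean(phis), 1, tolerance = 0.05)
})

test_that("the phenotype report recovers the configured group structure", {
  sim <- simulate_experiment(small_config(rng_seed = 77))
  rep <- phenotype_report(sim$phenotypes)
  for (tr in c("stem_length", "flowering_time", "pollen_per_flower")) {
    expect_equal(length(rep[[tr]]$letters), 7)
    expect_true(all(nchar(rep[[tr]]$letters) >= 1))
  }
  ## fitted viability group means within 3 SE of the configured map
  cfg <- sim$config
  ph <- sim$phenotypes
  for (g in GROUP_LEVELS) {
    sel <- ph$group == g
    phat <- sum(ph$pollen_viable[sel]) / sum(ph$pollen_examined[sel])
    p0 <- cfg$pheno_viability_by_group[[g]]
    ## beta-binomial SE at the configured intra-class correlation
    n_ind <- sum(sel)
    m <- ph$pollen_examined[sel][1]
    se <- sqrt(p0 * (1 - p0) * (1 + (m - 1) * cfg$pheno_rho) / (n_ind * m))
    expect_lt(abs(phat - p0), 3 * se)
  }
  ## the configured interaction (WGD helps hybrids, hurts nonhybrids)
  tab <- rep$pollen_viability$anova_table
  expect_lt(tab$pvalue[tab$term == "is_hybrid:is_tetraploid"], 0.05)
  expect_s3_class(rep$viability_alloh_vs_f2$anova_table, "data.frame")
  expect_equal(length(rep$selfed_seed_set), 7)
})
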