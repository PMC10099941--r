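seven_group_table <- function(n = 6, tissue = "flower") {
  grid <- expand.grid(line = seq_len(n), group = GROUP_LEVELS,
                      stringsAsFactors = FALSE)
  sample_table(paste0(grid$group, "_", grid$line), grid$group, tissue,
               grid$line, "lane1")
}

test_that("extreme counts conserve and find constructed extremes", {
  st <- seven_group_table()
  N <- nrow(st)
  G <- 30
  set.seed(51)
  cpm <- matrix(runif(G * N, 2, 100), G, N,
                dimnames = list(sprintf("g%03d", 1:G), st$sample_id))
  cpm[, 1] <- 1000  # individual 1 is highest for every gene
  ex <- rank_extremes(cpm, st, "flower", seed = 1)
  expect_equal(ex$n_rank_high[ex$individual_id == st$sample_id[1]], G)
  expect_equal(sum(ex$n_rank_low), G)
  expect_equal(sum(ex$n_rank_high), G)
  expect_equal(attr(ex, "N"), 42)
  ## single gene with distinct values: exactly one low and one high
  one <- cpm[1, , drop = FALSE]
  ex1 <- rank_extremes(one, st, "flower", seed = 1,
                       thresholds = analysis_thresholds(min_cpm = 0.5))
  expect_equal(sum(ex1$n_rank_low == 1), 1)
  expect_equal(sum(ex1$n_rank_high == 1), 1)
})

test_that("ties conserve under random tie-breaking, drop mode drops", {
  st <- seven_group_table(n = 2, tissue = "leaf")
  G <- 40
  cpm <- matrix(5, G, nrow(st),
                dimnames = list(sprintf("g%03d", 1:G), st$sample_id))
  ex <- rank_extremes(cpm, st, "leaf", seed = 3)
  expect_equal(sum(ex$n_rank_low), G)
  expect_equal(sum(ex$n_rank_high), G)
  exd <- rank_extremes(cpm, st, "leaf", seed = 3, tie_mode = "drop")
  expect_equal(sum(exd$n_extreme), 0)
  ## identical seed reproduces identical counts
  ex2 <- rank_extremes(cpm, st, "leaf", seed = 3)
  expect_identical(ex, ex2)
})

test_that("under an exchangeable null extremes spread as 2G/N", {
  st <- seven_group_table()
  N <- nrow(st)
  G <- 2000
  set.seed(52)
  cpm <- matrix(rlnorm(G * N, 3, 1), G, N,
                dimnames = list(sprintf("g%04d", 1:G), st$sample_id))
  ex <- rank_extremes(cpm, st, "flower", seed = 7)
  expect_equal(mean(ex$n_extreme), 2 * G / N)  # conservation identity
  sd_bin <- sqrt(2 * G * (1 / N) * (1 - 1 / N))
  expect_true(all(abs(ex$n_extreme - 2 * G / N) < 4 * sd_bin))
})

test_that("restricting the gene set never increases extreme counts", {
  st <- seven_group_table()
  set.seed(53)
  cpm <- matrix(rlnorm(500 * nrow(st), 3, 1), 500, nrow(st),
                dimnames = list(sprintf("g%04d", 1:500), st$sample_id))
  full <- rank_extremes(cpm, st, "flower", seed = 2)
  sub <- rank_extremes(cpm, st, "flower", seed = 2,
                       gene_set = sprintf("g%04d", 1:200))
  expect_true(all(sub$n_extreme <= full$n_extreme))
  expect_error(rank_extremes(cpm[, 1, drop = FALSE], st, "flower"),
               ">= 2 individuals")
})

test_that("the relaxed parental-DE rule keeps the right genes", {
  ids <- c("small_fc", "high_q", "true_ped", "untested")
  de <- fake_de(ids, c("ns", "ns", "up", "ns"), "Cg2", "Co2",
                log2fc = c(0.1, 3, 3, 0))
  de$qvalue <- c(0.001, 0.5, 0.001, NA)
  kept <- nonped_gene_set(de)
  expect_true(all(c("small_fc", "high_q", "untested") %in% kept))
  expect_false("true_ped" %in% kept)
})

test_that("the group ANOVA p-value is uniform under an exchangeable null", {
  st <- seven_group_table()
  G <- 300
  pvals <- vapply(seq_len(200), function(i) {
    set.seed(9000 + i)
    cpm <- matrix(rlnorm(G * nrow(st), 3, 1), G, nrow(st),
                  dimnames = list(sprintf("g%04d", seq_len(G)),
                                  st$sample_id))
    ex <- rank_extremes(cpm, st, "flower", seed = 9000 + i)
    extreme_group_test(ex)$pvalue
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("group tests on extreme counts behave at null and signal", {
  st <- seven_group_table()
  base <- rep(c(90, 95, 100, 105, 110, 115), times = 7)
  ex <- data.frame(individual_id = st$sample_id, group = st$group,
                   n_rank_low = 0, n_rank_high = 0, n_extreme = base)
  r <- extreme_group_test(ex)
  expect_lt(r$F, 1e-10)
  expect_equal(length(unique(r$letters)), 1)
  shifted <- ex
  shifted$n_extreme[shifted$group == "F2"] <-
    shifted$n_extreme[shifted$group == "F2"] + 10 * sd(base) * 10
  r2 <- extreme_group_test(shifted)
  expect_lt(r2$pvalue, 1e-6)
  others <- r2$letters[names(r2$letters) != "F2"]
  expect_false(r2$letters[["F2"]] %in% others)
})
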