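#' Simulation configuration for the seven-group factorial design
#'
#' Bundles every generator parameter: the size of the gene/TE annotation,
#' the negative-binomial expression model (baseline abundance, per-gene
#' dispersion), the fraction and effect size of parentally differential
#' (PED) genes, the distribution of hybrid expression modes among PED genes
#' (additive, expression-level dominance toward either parent,
#' transgressive up/down, conserved), the whole-genome-duplication effect
#' (zero by default: tetraploids share the relative expression of their
#' diploids), sequencing library sizes, the per-lane TE read fraction, and
#' the phenotype model (group viability / normal-seed proportions with
#' beta-binomial overdispersion).
#'
#' Defaults encode the study design this package targets: 7 groups x 2
#' tissues x 6 lines with one sequenced individual per line (84 expression
#' samples) and 6 phenotyped individuals per line (252 plants), lanes in a
#' balanced block (each group x tissue has two samples on each of three
#' lanes).
#'
#' @param n_genes,n_te number of gene / TE features.
#' @param te_class_weights simplex over TE classes.
#' @param groups group labels.
#' @param lines_per_group,individuals_per_line design sizes.
#' @param tissues tissue labels.
#' @param baseline_logmean_mu,baseline_logmean_sd log2-scale baseline
#'   abundance distribution.
#' @param dispersion_meanlog,dispersion_sdlog lognormal model for per-gene
#'   NB dispersion.
#' @param pi_ped fraction of genes differentially expressed between the
#'   parents.
#' @param ped_logfc_sd,ped_logfc_min parental log2 fold-changes are
#'   N(0, sd) truncated to |logFC| >= min.
#' @param hybrid_mode_fractions simplex over hybrid expression modes,
#'   applied to PED genes (non-PED genes are all "conserved"). A missing
#'   "conserved" entry absorbs the remainder.
#' @param tre_shift log2 offset beyond the more extreme parent for
#'   transgressive genes.
#' @param wgd_effect_fraction,wgd_logfc fraction of genes whose relative
#'   expression shifts (by \code{wgd_logfc} log2 units) in tetraploids.
#' @param library_size_meanlog,library_size_sdlog lognormal read-pair
#'   library sizes.
#' @param te_fraction named per-lane expected proportion of TE reads.
#' @param tissue_logsd sd of the per-gene log2 offset between tissues.
#' @param line_sd sd of an optional per-(gene, line) random effect
#'   (log2 scale); 0 disables it.
#' @param pheno_viability_by_group,pheno_normal_seed_by_group group ->
#'   proportion maps for pollen viability and normal seeds.
#' @param pheno_stem_mean,pheno_flowering_mean,pheno_pollen_count_mean
#'   group -> mean maps for stem length (cm), flowering time (d) and
#'   pollen grains per flower; the parents sit at the extremes with
#'   hybrids intermediate and a tetraploid offset.
#' @param pheno_stem_sd,pheno_flowering_sd,pheno_pollen_count_sd residual
#'   sds for those traits.
#' @param pheno_selfed_prob group -> probability of autonomous selfed seed
#'   set.
#' @param pheno_rho beta-binomial overdispersion (intra-class correlation)
#'   for proportion phenotypes; > 0 makes quasi-binomial dispersion > 1.
#' @param pollen_examined_per_flower,flowers_per_individual pollen assay
#'   sizes (>= 300 grains per flower, two flowers).
#' @param fruits_per_individual,seeds_per_fruit_mean seed assay sizes.
#' @param rng_seed integer seed.
#' @return list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(
    n_genes = 10000, n_te = 400,
    te_class_weights = c(LTR = 0.40, Helitron = 0.25, SINE = 0.15,
                         LINE = 0.15, other = 0.05),
    groups = GROUP_LEVELS, lines_per_group = 6, individuals_per_line = 6,
    tissues = TISSUE_LEVELS,
    baseline_logmean_mu = 4, baseline_logmean_sd = 2,
    dispersion_meanlog = log(0.05), dispersion_sdlog = 0.5,
    pi_ped = 0.25,
    ped_logfc_sd = 1.5, ped_logfc_min = 1,
    hybrid_mode_fractions = c(additive = 0.17, ELD_P1 = 0.03, ELD_P2 = 0.03,
                              TRE_up = 1e-4, TRE_down = 1e-4),
    tre_shift = 1.5,
    wgd_effect_fraction = 0, wgd_logfc = 1.5,
    library_size_meanlog = log(2e7), library_size_sdlog = 0.15,
    te_fraction = c(lane1 = 0.053, lane2 = 0.015, lane3 = 0.048),
    tissue_logsd = 1, line_sd = 0,
    pheno_viability_by_group = c(Cg2 = 0.966, Co2 = 0.985, F2 = 0.827,
                                 `Allo-d` = 0.813, `Allo-h` = 0.878,
                                 Co4 = 0.831, Cg4 = 0.914),
    pheno_normal_seed_by_group = c(F2 = 0.57, `Allo-h` = 0.78,
                                   `Allo-d` = 0.70, Co2 = 0.97, Cg2 = 0.95,
                                   Co4 = 0.85, Cg4 = 0.88),
    pheno_stem_mean = c(Co2 = 20, Cg2 = 45, F2 = 33, Co4 = 24, Cg4 = 49,
                        `Allo-d` = 37, `Allo-h` = 36),
    pheno_flowering_mean = c(Co2 = 30, Cg2 = 45, F2 = 37, Co4 = 33,
                             Cg4 = 48, `Allo-d` = 42, `Allo-h` = 38),
    pheno_pollen_count_mean = c(Co2 = 3000, Cg2 = 9000, F2 = 6000,
                                Co4 = 3100, Cg4 = 7500, `Allo-d` = 6000,
                                `Allo-h` = 6200),
    pheno_stem_sd = 4, pheno_flowering_sd = 3, pheno_pollen_count_sd = 800,
    pheno_selfed_prob = c(Co2 = 1, Cg2 = 0, F2 = 22 / 29, Co4 = 1, Cg4 = 0,
                          `Allo-d` = 27 / 35, `Allo-h` = 1),
    pheno_rho = 0.02,
    pollen_examined_per_flower = 320, flowers_per_individual = 2,
    fruits_per_individual = 10, seeds_per_fruit_mean = 20,
    rng_seed = 1L) {
  if (n_genes < 1 || n_te < 0) stop("degenerate config: n_genes >= 1 required")
  if (length(groups) < 1) stop("degenerate config: no groups")
  check_groups(groups)
  fr <- hybrid_mode_fractions
  modes <- c("additive", "ELD_P1", "ELD_P2", "TRE_up", "TRE_down", "conserved")
  if (!all(names(fr) %in% modes)) stop("unknown hybrid mode in fractions")
  if (!"conserved" %in% names(fr)) {
    rem <- 1 - sum(fr)
    if (rem < -1e-9) stop("hybrid_mode_fractions sum to more than 1")
    fr <- c(fr, conserved = max(rem, 0))
  }
  if (abs(sum(fr) - 1) > 1e-9) stop("hybrid_mode_fractions must sum to 1")
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (abs(sum(te_class_weights) - 1) > 1e-9) {
    stop("te_class_weights must sum to 1")
  }
  if (pi_ped < 0 || pi_ped > 1 || wgd_effect_fraction < 0 ||
      wgd_effect_fraction > 1) {
    stop("fractions must lie in [0, 1]")
  }
  for (map in list(pheno_viability_by_group, pheno_normal_seed_by_group,
                   pheno_selfed_prob)) {
    if (!all(groups %in% names(map))) {
      stop("group proportion map must cover all groups")
    }
    if (any(map < 0 | map > 1)) stop("proportions must lie in [0, 1]")
  }
  if (pollen_examined_per_flower < 300) {
    stop("pollen_examined_per_flower must be >= 300")
  }
  cfg <- as.list(environment())
  cfg$fr <- NULL
  cfg$map <- NULL
  cfg$modes <- NULL
  cfg$rem <- NULL
  cfg$hybrid_mode_fractions <- fr[modes]
  structure(cfg, class = "simulation_config")
}

#' Assign per-gene ground truth
#'
#' Draws, for each gene, its parental log2 fold-change (P1 = the maternal
#' *C. orientalis*-like parent relative to P2), a hybrid expression mode,
#' and whether it shifts upon WGD; then computes the expected log2 mean of
#' each of the seven groups. Modes requiring a parental difference (ELD,
#' TRE) are only drawn among PED genes; non-PED genes are "conserved". A
#' PED gene drawn "conserved" takes the midparent expectation (identical
#' expectation to "additive"; the label is bookkeeping only).
#'
#' Uses the current RNG state; callers wanting reproducibility should
#' \code{set.seed()} first (as \code{\link{simulate_experiment}} does).
#'
#' @param config a \code{\link{simulation_config}}.
#' @return data.frame with feature_id, parental_log2fc, hybrid_mode,
#'   wgd_shifted and one \code{mu_<group>} column per group (expected
#'   log2 mean, flower-tissue reference).
#' @export
assign_gene_truth <- function(config) {
  n <- config$n_genes
  id <- sprintf("G%05d", seq_len(n))
  base <- stats::rnorm(n, config$baseline_logmean_mu,
                       config$baseline_logmean_sd)
  ped <- stats::runif(n) < config$pi_ped
  fc <- numeric(n)
  need <- which(ped)
  while (length(need) > 0) {  # rejection sampling of the truncated normal
    draw <- stats::rnorm(length(need), 0, config$ped_logfc_sd)
    ok <- abs(draw) >= config$ped_logfc_min
    fc[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  mode <- rep("conserved", n)
  frac <- config$hybrid_mode_fractions
  if (any(ped)) {
    mode[ped] <- sample(names(frac), sum(ped), replace = TRUE, prob = frac)
  }
  mu_p1 <- base + fc / 2
  mu_p2 <- base - fc / 2
  mid <- (mu_p1 + mu_p2) / 2
  mu_h <- mid
  mu_h[mode == "ELD_P1"] <- mu_p1[mode == "ELD_P1"]
  mu_h[mode == "ELD_P2"] <- mu_p2[mode == "ELD_P2"]
  up <- mode == "TRE_up"
  dn <- mode == "TRE_down"
  mu_h[up] <- pmax(mu_p1[up], mu_p2[up]) + config$tre_shift
  mu_h[dn] <- pmin(mu_p1[dn], mu_p2[dn]) - config$tre_shift
  wgd <- stats::runif(n) < config$wgd_effect_fraction
  shift <- ifelse(wgd, config$wgd_logfc, 0)
  truth <- data.frame(feature_id = id, parental_log2fc = fc,
                      hybrid_mode = mode, wgd_shifted = wgd,
                      stringsAsFactors = FALSE, check.names = FALSE)
  truth[["mu_Co2"]] <- mu_p1
  truth[["mu_Cg2"]] <- mu_p2
  truth[["mu_F2"]] <- mu_h
  truth[["mu_Co4"]] <- mu_p1 + shift
  truth[["mu_Cg4"]] <- mu_p2 + shift
  truth[["mu_Allo-d"]] <- mu_h + shift
  truth[["mu_Allo-h"]] <- mu_h + shift
  truth
}

#' Simulate a full experiment
#'
#' Generates the count matrix (genes + TE features x samples), feature and
#' sample tables, phenotype table and per-gene ground truth for the
#' configured design. One individual per (group, tissue, line) is
#' "sequenced"; lanes follow a balanced block (lines 1..6 -> lanes
#' 1,2,3,1,2,3 within each group x tissue). Each sample's library size is
#' drawn lognormally and allocated multinomially over gamma-perturbed
#' feature weights, so per-feature counts are negative-binomial with the
#' configured dispersion while the sample total equals the drawn library
#' size. TE features receive the lane's expected share of reads.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with \code{counts} (integer matrix, canonical lexicographic
#'   row/column order), \code{features}, \code{samples}, \code{phenotypes},
#'   \code{truth}, \code{library_sizes} and the \code{config}.
#' @export
simulate_experiment <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  set.seed(config$rng_seed)
  truth <- assign_gene_truth(config)
  n_te <- config$n_te
  te_id <- if (n_te > 0) sprintf("TE%04d", seq_len(n_te)) else character(0)
  te_class <- if (n_te > 0) {
    sample(names(config$te_class_weights), n_te, replace = TRUE,
           prob = config$te_class_weights)
  } else character(0)
  gene_len <- pmax(200, round(stats::rlnorm(config$n_genes, log(1500), 0.4)))
  te_len <- if (n_te > 0) {
    pmax(80, round(stats::rlnorm(n_te, log(800), 0.5)))
  } else numeric(0)
  features <- feature_table(
    feature_id = c(truth$feature_id, te_id),
    feature_kind = c(rep("gene", config$n_genes), rep("TE", n_te)),
    te_class = c(rep(NA, config$n_genes), te_class),
    length_bp = c(gene_len, te_len))

  disp_gene <- stats::rlnorm(config$n_genes, config$dispersion_meanlog,
                             config$dispersion_sdlog)
  disp_te <- if (n_te > 0) {
    stats::rlnorm(n_te, config$dispersion_meanlog, config$dispersion_sdlog)
  } else numeric(0)
  te_weight <- if (n_te > 0) stats::rlnorm(n_te, 0, 1) else numeric(0)
  tissue_off <- stats::rnorm(config$n_genes, 0, config$tissue_logsd)

  lanes <- names(config$te_fraction)
  grid <- expand.grid(line = seq_len(config$lines_per_group),
                      tissue = config$tissues, group = config$groups,
                      stringsAsFactors = FALSE)
  grid$lane <- lanes[((grid$line - 1) %% length(lanes)) + 1]
  grid$sample_id <- sprintf("%s_%s_%d", grid$group, grid$tissue, grid$line)
  samples <- sample_table(grid$sample_id, grid$group, grid$tissue,
                          grid$line, grid$lane)

  line_eff <- NULL
  if (config$line_sd > 0) {
    line_eff <- matrix(stats::rnorm(config$n_genes * config$lines_per_group *
                                      length(config$groups), 0,
                                    config$line_sd),
                       nrow = config$n_genes)
    colnames(line_eff) <- paste(rep(config$groups,
                                    each = config$lines_per_group),
                                seq_len(config$lines_per_group), sep = "_")
  }

  mu_cols <- paste0("mu_", config$groups)
  lib <- stats::rlnorm(nrow(grid), config$library_size_meanlog,
                       config$library_size_sdlog)
  counts <- matrix(0L, nrow = config$n_genes + n_te, ncol = nrow(grid),
                   dimnames = list(c(truth$feature_id, te_id),
                                   grid$sample_id))
  for (s in seq_len(nrow(grid))) {
    g <- grid$group[s]
    mu <- truth[[paste0("mu_", g)]]
    if (grid$tissue[s] == "leaf") mu <- mu + tissue_off
    if (!is.null(line_eff)) {
      mu <- mu + line_eff[, paste(g, grid$line[s], sep = "_")]
    }
    w_gene <- 2^mu
    tef <- if (n_te > 0) unname(config$te_fraction[grid$lane[s]]) else 0
    w <- c((1 - tef) * w_gene / sum(w_gene),
           if (n_te > 0) tef * te_weight / sum(te_weight))
    shape <- 1 / c(disp_gene, disp_te)
    u <- w * stats::rgamma(length(w), shape = shape, rate = shape)
    counts[, s] <- stats::rmultinom(1, size = round(lib[s]), prob = u)[, 1]
  }
  fid <- sort(rownames(counts))
  sid <- sort(colnames(counts))
  counts <- counts[fid, sid, drop = FALSE]
  phenotypes <- simulate_phenotypes(config)
  names(lib) <- grid$sample_id
  list(counts = counts,
       features = features[match(fid, features$feature_id), ],
       samples = samples[match(sid, samples$sample_id), ],
       phenotypes = phenotypes, truth = truth,
       library_sizes = lib[sid], config = config)
}

## beta-binomial draw with intra-class correlation rho (rho = 0 -> binomial)
rbetabinom <- function(n, size, prob, rho) {
  out <- integer(n)
  degenerate <- prob <= 0 | prob >= 1 | rho <= 0
  if (length(prob) == 1) prob <- rep(prob, n)
  if (length(size) == 1) size <- rep(size, n)
  degenerate <- prob <= 0 | prob >= 1 | rho <= 0
  p <- prob
  if (any(!degenerate)) {
    nu <- 1 / rho - 1
    idx <- which(!degenerate)
    p[idx] <- stats::rbeta(length(idx), prob[idx] * nu, (1 - prob[idx]) * nu)
  }
  stats::rbinom(n, size, p)
}

#' Simulate the phenotype table
#'
#' One row per phenotyped individual (groups x lines x individuals). Pollen
#' viability: per flower, >= 300 grains are scored binomially with the
#' group's viability proportion, beta-binomial overdispersed with
#' intra-class correlation \code{pheno_rho}, and the two flowers of an
#' individual are summed. Normal seeds: total seeds over 10 fruits
#' (Poisson per fruit) scored the same way against the group's normal-seed
#' proportion. Stem length, flowering time and pollen grains per flower
#' are normal around group means ordered parent < hybrid < parent with a
#' tetraploid offset.
#'
#' Uses the current RNG state (seed inside \code{simulate_experiment}).
#'
#' @param config a \code{\link{simulation_config}}.
#' @return data.frame phenotype table.
#' @export
simulate_phenotypes <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  grid <- expand.grid(individual = seq_len(config$individuals_per_line),
                      line = seq_len(config$lines_per_group),
                      group = config$groups, stringsAsFactors = FALSE)
  n <- nrow(grid)
  g <- grid$group
  v <- unname(config$pheno_viability_by_group[g])
  sdp <- unname(config$pheno_normal_seed_by_group[g])
  rho <- config$pheno_rho
  per_flower <- config$pollen_examined_per_flower
  nf <- config$flowers_per_individual
  viable <- integer(n)
  for (f in seq_len(nf)) {
    viable <- viable + rbetabinom(n, per_flower, v, rho)
  }
  seeds_total <- vapply(seq_len(n), function(i) {
    sum(stats::rpois(config$fruits_per_individual,
                     config$seeds_per_fruit_mean))
  }, integer(1))
  seeds_normal <- rbetabinom(n, seeds_total, sdp, rho)
  data.frame(
    individual_id = sprintf("%s_L%d_I%d", g, grid$line, grid$individual),
    group = g, line = grid$line,
    stem_length = stats::rnorm(n, unname(config$pheno_stem_mean[g]),
                               config$pheno_stem_sd),
    flowering_time = stats::rnorm(n,
                                  unname(config$pheno_flowering_mean[g]),
                                  config$pheno_flowering_sd),
    pollen_per_flower = round(stats::rnorm(
      n, unname(config$pheno_pollen_count_mean[g]),
      config$pheno_pollen_count_sd)),
    pollen_viable = viable,
    pollen_examined = per_flower * nf,
    seeds_normal = seeds_normal,
    seeds_total = seeds_total,
    selfed_seed_set = stats::runif(n) < unname(config$pheno_selfed_prob[g]),
    stringsAsFactors = FALSE)
}
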