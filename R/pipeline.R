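#' Derive a per-stage seed from the pipeline seed
#'
#' Documented fan-out so stages are individually reproducible:
#' \code{(seed * 10007 + 101 * stage_index) mod (2^31 - 1)}.
#'
#' @param seed integer pipeline seed.
#' @param stage_index integer stage number.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 10007 + 101 * stage_index) %% 2147483647)
}

default_stages <- function() {
  list(downsample = TRUE, de = TRUE, classify = TRUE, extreme = TRUE,
       te = TRUE, phenotypes = TRUE, ordination = TRUE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> downsample -> expression filter ->
#' differential expression -> additive/nonadditive classification ->
#' extreme-expression ranks -> TE abundance GLMs -> phenotype statistics
#' -> MDS, writing one TSV per output and a manifest of content hashes.
#' Re-running with the same config and seed reproduces identical hashes.
#'
#' @param config a list, or path to a YAML file, with components:
#'   exactly one of \code{simulate} (a list of
#'   \code{\link{simulation_config}} overrides, TRUE for defaults) or
#'   \code{paths} (named list: counts, features, samples, phenotypes);
#'   optional \code{thresholds} overrides; optional \code{stages} toggles
#'   (downsample, de, classify, extreme, te, phenotypes, ordination);
#'   \code{seed}; \code{out_dir}.
#' @param out_dir output directory (overrides the config entry).
#' @return invisibly, a list with the stage results and the
#'   \code{manifest} data.frame (file, md5).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  has_sim <- !is.null(config$simulate) && !isFALSE(config$simulate)
  has_paths <- !is.null(config$paths)
  if (has_sim == has_paths) {
    stop("config error: exactly one of 'simulate' or 'paths' must be given")
  }
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("config error: out_dir required")
  if (has_paths) {
    need <- c("counts", "features", "samples", "phenotypes")
    miss <- setdiff(need, names(config$paths))
    if (length(miss) > 0) {
      stop("config error: missing path(s): ", paste(miss, collapse = ", "))
    }
    for (p in unlist(config$paths[need])) {
      if (!file.exists(p)) stop("config error: no such file: ", p)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  th <- do.call(analysis_thresholds,
                config$thresholds %||% list())
  stages <- utils::modifyList(default_stages(), config$stages %||% list())
  results <- list()
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_table(df, path)
    files <<- c(files, path)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  ## --- input stage -------------------------------------------------------
  sim <- run_stage("input", {
    if (has_sim) {
      overrides <- if (isTRUE(config$simulate)) list() else config$simulate
      if (is.null(overrides$rng_seed)) {
        overrides$rng_seed <- stage_seed(seed, 1)
      }
      s <- simulate_experiment(do.call(simulation_config, overrides))
      emit(data.frame(feature_id = rownames(s$counts), s$counts,
                      check.names = FALSE), "counts.tsv")
      emit(s$features, "features.tsv")
      emit(s$samples, "samples.tsv")
      emit(s$phenotypes, "phenotypes.tsv")
      emit(s$truth, "truth.tsv")
      s
    } else {
      ftab <- validate_feature_table(read_table(config$paths$features))
      sraw <- read_table(config$paths$samples)
      stab <- sample_table(sraw$sample_id, sraw$group, sraw$tissue,
                           sraw$line, sraw$lane)
      list(counts = read_count_matrix(config$paths$counts, ftab, stab),
           features = ftab, samples = stab,
           phenotypes = read_table(config$paths$phenotypes), truth = NULL)
    }
  })
  counts <- sim$counts
  features <- sim$features
  samples <- sim$samples

  if (isTRUE(stages$downsample)) {
    counts <- run_stage("downsample", {
      downsample_to_group_mean(counts, samples, seed = stage_seed(seed, 2))
    })
    emit(data.frame(feature_id = rownames(counts), counts,
                    check.names = FALSE), "counts_downsampled.tsv")
  }
  gene_rows <- features$feature_id[features$feature_kind == "gene"]
  gcounts <- counts[rownames(counts) %in% gene_rows, , drop = FALSE]
  tpm <- compute_tpm(gcounts, features)
  expressed <- filter_expressed(tpm, th$min_tpm, th$min_tpm_samples)
  tissues <- unique(samples$tissue)

  if (isTRUE(stages$de)) {
    results$de <- run_stage("de", {
      de <- list()
      for (tis in tissues) {
        sub <- gcounts[expressed, , drop = FALSE]
        disp <- estimate_dispersions(sub, samples, tissue = tis,
                                     thresholds = th)
        hy <- intersect(HYBRID_GROUPS, unique(samples$group))
        contrasts <- c(lapply(hy, function(h) c(h, "Co2")),
                       lapply(hy, function(h) c(h, "Cg2")),
                       list(c("Cg2", "Co2"), c("Co4", "Co2"),
                            c("Cg4", "Cg2")))
        for (ct in contrasts) {
          if (!all(ct %in% samples$group)) next
          r <- pairwise_contrast(sub, samples, tis, ct[1], ct[2], disp,
                                 thresholds = th)
          key <- paste(tis, ct[1], "vs", ct[2], sep = "_")
          de[[key]] <- r
          emit(r, paste0("de_", key, ".tsv"))
        }
      }
      emit(deg_summary(de), "deg_summary.tsv")
      de
    })
  }

  if (isTRUE(stages$classify) && isTRUE(stages$de)) {
    results$classify <- run_stage("classify", {
      props <- list()
      for (tis in tissues) {
        ped <- results$de[[paste(tis, "Cg2_vs_Co2", sep = "_")]]
        if (is.null(ped)) next
        for (h in intersect(HYBRID_GROUPS, unique(samples$group))) {
          k1 <- paste(tis, h, "vs", "Co2", sep = "_")
          k2 <- paste(tis, h, "vs", "Cg2", sep = "_")
          if (is.null(results$de[[k1]]) || is.null(results$de[[k2]])) next
          cl <- classify_hybrid_group(results$de[[k1]], results$de[[k2]],
                                      ped)
          emit(cl$categories, paste0("categories_", tis, "_", h, ".tsv"))
          props[[paste(tis, h, sep = "_")]] <-
            data.frame(tissue = tis, hybrid = h,
                       t(cl$proportions), stringsAsFactors = FALSE)
        }
      }
      ptab <- do.call(rbind, props)
      if (!is.null(ptab)) emit(ptab, "category_proportions.tsv")
      ptab
    })
  }

  if (isTRUE(stages$extreme)) {
    results$extreme <- run_stage("extreme", {
      ex <- list()
      for (tis in tissues) {
        cpm <- compute_cpm(gcounts[, samples$tissue == tis, drop = FALSE])
        e <- rank_extremes(cpm, samples, tis, seed = stage_seed(seed, 3),
                           thresholds = th)
        emit(e, paste0("extreme_", tis, ".tsv"))
        ex[[tis]] <- e
        ped <- results$de[[paste(tis, "Cg2_vs_Co2", sep = "_")]]
        if (!is.null(ped)) {
          e2 <- rank_extremes(cpm, samples, tis,
                              gene_set = nonped_gene_set(ped, th),
                              seed = stage_seed(seed, 3), thresholds = th)
          emit(e2, paste0("extreme_nonped_", tis, ".tsv"))
          ex[[paste0(tis, "_nonped")]] <- e2
        }
      }
      ex
    })
  }

  if (isTRUE(stages$te) && any(features$feature_kind == "TE")) {
    results$te <- run_stage("te", {
      tes <- list()
      for (tis in tissues) {
        keep <- samples$tissue == tis
        obs <- te_proportions(counts[, keep, drop = FALSE], features,
                              samples[keep, , drop = FALSE])
        emit(obs, paste0("te_", tis, ".tsv"))
        fit <- te_glm(obs, include_lane = length(unique(obs$lane)) > 1)
        emit(fit$anova_table, paste0("te_glm_", tis, ".tsv"))
        tes[[tis]] <- list(obs = obs, fit = fit)
      }
      tes
    })
  }

  if (isTRUE(stages$phenotypes) && !is.null(sim$phenotypes)) {
    results$phenotypes <- run_stage("phenotypes", {
      rep <- phenotype_report(sim$phenotypes, alpha = th$alpha_phenotype)
      for (tr in c("stem_length", "flowering_time", "pollen_per_flower")) {
        emit(data.frame(group = names(rep[[tr]]$letters),
                        mean = as.numeric(rep[[tr]]$group_means[
                          names(rep[[tr]]$letters)]),
                        letters = unname(rep[[tr]]$letters)),
             paste0("pheno_", tr, ".tsv"))
      }
      glms <- rbind(
        cbind(trait = "pollen_viability",
              rep$pollen_viability$anova_table),
        cbind(trait = "normal_seeds", rep$normal_seeds$anova_table),
        cbind(trait = "viability_alloh_vs_f2",
              rep$viability_alloh_vs_f2$anova_table))
      emit(glms, "pheno_glm.tsv")
      rep
    })
  }

  if (isTRUE(stages$ordination)) {
    results$ordination <- run_stage("ordination", {
      ords <- list()
      sub <- gcounts[expressed, , drop = FALSE]
      runs <- c(list(all = seq_len(ncol(sub))),
                stats::setNames(lapply(tissues,
                                       function(t) which(samples$tissue == t)),
                                tissues))
      for (nm in names(runs)) {
        cols <- runs[[nm]]
        if (length(cols) < 3) next
        fac <- tmm_factors(sub[, cols, drop = FALSE], th)
        logcpm <- compute_cpm(sub[, cols, drop = FALSE],
                              prior = th$cpm_prior_count,
                              effective_sizes =
                                colSums(sub[, cols, drop = FALSE]) * fac,
                              log = TRUE)
        d <- leading_logfc_distance(logcpm, top = th$mds_top_genes)
        m <- classical_mds(d, k = 2)
        emit(data.frame(sample_id = rownames(m$coordinates),
                        dim1 = m$coordinates[, 1],
                        dim2 = m$coordinates[, 2]),
             paste0("mds_", nm, ".tsv"))
        ords[[nm]] <- m
      }
      ords
    })
  }

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  write_table(manifest, file.path(out_dir, "manifest.tsv"))
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
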