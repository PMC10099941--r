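#' Per-individual counts of extreme expression ranks
#'
#' For each analyzed gene, the sequenced individuals of one tissue (all
#' seven groups jointly, normally 42 = 7 groups x 6 lines) are ranked
#' ascending by CPM; the individual at rank 1 and the one at rank N score
#' one "extreme expression" each. Ties are broken by a seeded random
#' permutation so ranks form a strict total order, which makes the
#' per-individual totals conserve exactly (each gene contributes exactly
#' one low and one high extreme) and keeps the exchangeable-null
#' expectation at 2G/N per individual. A "drop" tie mode is available for
#' sensitivity analysis: genes whose extreme value is tied score nobody.
#'
#' @param cpm CPM matrix (genes x samples).
#' @param samples sample table matching the columns.
#' @param tissue tissue to analyze.
#' @param gene_set optional gene ids to restrict to (intersected with the
#'   CPM filter).
#' @param seed integer seed for tie-breaking.
#' @param thresholds \code{\link{analysis_thresholds}} (CPM filter).
#' @param tie_mode "random" (default) or "drop".
#' @return data.frame: individual_id, group, n_rank_low, n_rank_high,
#'   n_extreme; attributes \code{G} (genes analyzed) and \code{N}
#'   (individuals ranked).
#' @export
rank_extremes <- function(cpm, samples, tissue, gene_set = NULL, seed = 1L,
                          thresholds = analysis_thresholds(),
                          tie_mode = c("random", "drop")) {
  tie_mode <- match.arg(tie_mode)
  samples <- samples[match(colnames(cpm), samples$sample_id), ]
  keep <- samples$tissue == tissue
  x <- cpm[, keep, drop = FALSE]
  sub <- samples[keep, , drop = FALSE]
  N <- ncol(x)
  if (N < 2) stop("need >= 2 individuals to rank")
  genes <- filter_expressed(x, thresholds$min_cpm, thresholds$min_cpm_samples)
  if (!is.null(gene_set)) genes <- intersect(genes, gene_set)
  x <- x[genes, , drop = FALSE]
  G <- nrow(x)
  low <- high <- integer(N)
  set.seed(seed)
  for (g in seq_len(G)) {
    v <- x[g, ]
    if (tie_mode == "random") {
      r <- rank(v, ties.method = "random")
      low[which(r == 1)] <- low[which(r == 1)] + 1L
      high[which(r == N)] <- high[which(r == N)] + 1L
    } else {
      if (sum(v == min(v)) == 1) {
        i <- which.min(v)
        low[i] <- low[i] + 1L
      }
      if (sum(v == max(v)) == 1) {
        i <- which.max(v)
        high[i] <- high[i] + 1L
      }
    }
  }
  out <- data.frame(individual_id = sub$sample_id, group = sub$group,
                    n_rank_low = low, n_rank_high = high,
                    n_extreme = low + high, stringsAsFactors = FALSE)
  attr(out, "G") <- G
  attr(out, "N") <- N
  out
}

#' Genes not differentially expressed between the parents
#'
#' The relaxed complement of the parental DEG set: a gene is kept iff its
#' parental fold-change is below the relaxed threshold (|log2FC| <
#' log2(1.2) by default) OR its FDR exceeds alpha. Genes never entering
#' the FDR step (no q-value) count as non-significant and are kept.
#'
#' @param de_parents \code{de_result} for the parental contrast.
#' @param thresholds \code{\link{analysis_thresholds}}.
#' @return character vector of gene ids.
#' @export
nonped_gene_set <- function(de_parents, thresholds = analysis_thresholds()) {
  fc_ok <- abs(de_parents$log2fc) < log2(thresholds$ped_relaxed_fc)
  q <- de_parents$qvalue
  fdr_ok <- is.na(q) | q > thresholds$fdr_alpha
  de_parents$feature_id[fc_ok | fdr_ok]
}

#' Group comparison of extreme-expression counts
#'
#' One-way ANOVA across the seven groups on the per-individual number of
#' extreme genes, with Tukey HSD letters.
#'
#' @param extremes result of \code{\link{rank_extremes}}.
#' @param alpha significance level for the letter display.
#' @return list with the ANOVA part (\code{F}, \code{df}, \code{pvalue},
#'   \code{group_means}) and the Tukey part (\code{pairwise},
#'   \code{letters}).
#' @export
extreme_group_test <- function(extremes, alpha = 0.05) {
  a <- one_way_anova(extremes$n_extreme, extremes$group)
  tk <- tukey_hsd_letters(extremes$n_extreme, extremes$group, alpha = alpha)
  c(a, tk)
}
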