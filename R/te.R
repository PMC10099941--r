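#' TE transcript proportions per sample
#'
#' numerator = reads on TE features (optionally one TE class), denominator
#' = reads on all annotated features (genes + TEs), one observation per
#' sample. Proportions over disjoint TE classes add up to the total TE
#' proportion.
#'
#' @param counts count matrix (genes + TE rows).
#' @param features feature table matching the rows.
#' @param samples sample table matching the columns.
#' @param te_class optional class filter ("LTR", "Helitron", "SINE",
#'   "LINE", "other").
#' @return data.frame of proportion observations: sample_id, group,
#'   tissue, line, lane, is_hybrid, is_tetraploid, numerator, denominator,
#'   proportion.
#' @export
te_proportions <- function(counts, features, samples, te_class = NULL) {
  features <- features[match(rownames(counts), features$feature_id), ]
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  te_rows <- features$feature_kind == "TE"
  if (!is.null(te_class)) te_rows <- te_rows & features$te_class %in% te_class
  if (!any(te_rows)) warning("no TE features; numerators are 0")
  num <- if (any(te_rows)) {
    colSums(counts[te_rows, , drop = FALSE])
  } else {
    rep(0, ncol(counts))
  }
  den <- colSums(counts)
  data.frame(sample_id = samples$sample_id, group = samples$group,
             tissue = samples$tissue, line = samples$line,
             lane = samples$lane, is_hybrid = samples$is_hybrid,
             is_tetraploid = samples$ploidy == 4,
             numerator = unname(num), denominator = unname(den),
             proportion = unname(num / den), stringsAsFactors = FALSE)
}

#' Quasi-binomial GLM on TE proportions
#'
#' Tests hybridization, WGD and their interaction (optionally plus the
#' sequencing lane as a main effect) on the proportion of TE reads, with
#' type II analysis-of-deviance F-tests. Run per tissue.
#'
#' @param obs result of \code{\link{te_proportions}} (one tissue).
#' @param include_lane add lane as a main effect.
#' @return a GLM fit list, see \code{\link{quasibinomial_glm}}.
#' @export
te_glm <- function(obs, include_lane = TRUE) {
  terms <- c("is_hybrid", "is_tetraploid")
  if (include_lane) terms <- c(terms, "lane")
  for (t in terms) {
    if (length(unique(obs[[t]])) < 2) {
      stop("factor '", t, "' has a single level")
    }
  }
  quasibinomial_glm(obs, terms = terms,
                    interactions = "is_hybrid:is_tetraploid")
}
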