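#' @keywords internal
"_PACKAGE"

## Group-level design constants for the seven-group factorial:
## two diploid parents (Co2 = C. orientalis-like, Cg2 = C. grandiflora-like),
## the diploid F hybrid (F2), the two autotetraploids (Co4, Cg4) and the two
## resynthesized allotetraploids (Allo-d doubling-first, Allo-h
## hybridization-first).

#' The seven design groups
#' @format character vector of group labels.
#' @export
GROUP_LEVELS <- c("Co2", "Cg2", "F2", "Co4", "Cg4", "Allo-d", "Allo-h")
TETRAPLOID_GROUPS <- c("Co4", "Cg4", "Allo-d", "Allo-h")
HYBRID_GROUPS <- c("F2", "Allo-d", "Allo-h")
TISSUE_LEVELS <- c("flower", "leaf")
TE_CLASSES <- c("LTR", "Helitron", "SINE", "LINE", "other")

#' Ploidy level implied by a group label
#'
#' Pure function of the group label: the four tetraploid groups are the two
#' autotetraploids and the two allotetraploids; everything else is diploid.
#'
#' @param group character vector of group labels.
#' @return integer vector, 2 or 4.
#' @export
group_ploidy <- function(group) {
  check_groups(group)
  ifelse(group %in% TETRAPLOID_GROUPS, 4L, 2L)
}

#' Hybrid state implied by a group label
#'
#' @param group character vector of group labels.
#' @return logical vector: TRUE for the diploid hybrid and both
#'   allotetraploid groups.
#' @export
group_is_hybrid <- function(group) {
  check_groups(group)
  group %in% HYBRID_GROUPS
}

check_groups <- function(group) {
  bad <- setdiff(unique(as.character(group)), GROUP_LEVELS)
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(GROUP_LEVELS, collapse = ", "))
  }
  invisible(TRUE)
}

#' Analysis thresholds
#'
#' The single bundle of numeric thresholds used across all analysis stages:
#' expression filters, fold-change and FDR cut-offs for differential
#' expression, the relaxed fold-change used to define genes *not*
#' differentially expressed between the parents, the phenotype-test alpha,
#' the number of top genes for the leading-logFC distance, TMM trim
#' fractions, and the prior count used for log-CPM.
#'
#' @param min_tpm TPM filter: keep genes with TPM strictly greater than this.
#' @param min_tpm_samples ...in at least this many samples.
#' @param min_cpm CPM filter used by the extreme-expression analysis.
#' @param min_cpm_samples ...in at least this many individuals.
#' @param fc_threshold linear fold-change threshold for calling DE.
#' @param fdr_alpha BH-adjusted significance level.
#' @param ped_relaxed_fc relaxed fold-change: genes with FC below this OR
#'   FDR above \code{fdr_alpha} in the parental contrast count as not
#'   parentally differential.
#' @param alpha_phenotype alpha for phenotype ANOVA/Tukey and GLM F-tests.
#' @param mds_top_genes number of top genes per sample pair in the
#'   leading-logFC distance.
#' @param tmm_logratio_trim,tmm_abs_trim TMM trim fractions for the M and A
#'   statistics.
#' @param cpm_prior_count prior count for log-CPM (0 = plain CPM).
#' @return a list of class \code{"analysis_thresholds"}.
#' @export
analysis_thresholds <- function(min_tpm = 2, min_tpm_samples = 3,
                                min_cpm = 1, min_cpm_samples = 2,
                                fc_threshold = 2, fdr_alpha = 0.05,
                                ped_relaxed_fc = 1.2, alpha_phenotype = 0.05,
                                mds_top_genes = 500,
                                tmm_logratio_trim = 0.3, tmm_abs_trim = 0.05,
                                cpm_prior_count = 0.5) {
  th <- list(min_tpm = min_tpm, min_tpm_samples = min_tpm_samples,
             min_cpm = min_cpm, min_cpm_samples = min_cpm_samples,
             fc_threshold = fc_threshold, fdr_alpha = fdr_alpha,
             ped_relaxed_fc = ped_relaxed_fc,
             alpha_phenotype = alpha_phenotype,
             mds_top_genes = mds_top_genes,
             tmm_logratio_trim = tmm_logratio_trim,
             tmm_abs_trim = tmm_abs_trim,
             cpm_prior_count = cpm_prior_count)
  num <- vapply(th, is.numeric, logical(1))
  if (!all(num)) stop("all thresholds must be numeric")
  pos <- setdiff(names(th), "cpm_prior_count")
  if (any(unlist(th[pos]) <= 0)) stop("thresholds must be strictly positive")
  if (th$cpm_prior_count < 0) stop("cpm_prior_count must be >= 0")
  if (th$fc_threshold <= 1) stop("fc_threshold must be > 1")
  if (th$fdr_alpha <= 0 || th$fdr_alpha >= 1) stop("fdr_alpha must be in (0, 1)")
  structure(th, class = "analysis_thresholds")
}

#' Construct and validate a feature table
#'
#' @param feature_id unique feature identifiers (genes and TE features).
#' @param feature_kind "gene" or "TE" per feature.
#' @param te_class TE class ("LTR", "Helitron", "SINE", "LINE", "other");
#'   must be NA for genes and non-NA for TEs.
#' @param length_bp feature length in bp; required (>= 1) for genes, may be
#'   NA for TE features.
#' @return data.frame of class \code{"feature_table"}.
#' @export
feature_table <- function(feature_id, feature_kind, te_class = NA,
                          length_bp = NA) {
  ft <- data.frame(feature_id = as.character(feature_id),
                   feature_kind = as.character(feature_kind),
                   te_class = as.character(te_class),
                   length_bp = as.numeric(length_bp),
                   stringsAsFactors = FALSE)
  validate_feature_table(ft)
}

validate_feature_table <- function(ft) {
  if (anyDuplicated(ft$feature_id)) {
    stop("duplicated feature_id: ",
         paste(unique(ft$feature_id[duplicated(ft$feature_id)])[1:3],
               collapse = ", "))
  }
  if (!all(ft$feature_kind %in% c("gene", "TE"))) {
    stop("feature_kind must be 'gene' or 'TE'")
  }
  is_te <- ft$feature_kind == "TE"
  if (any(is_te & is.na(ft$te_class))) stop("TE features require te_class")
  if (any(!is_te & !is.na(ft$te_class))) stop("genes must not carry a te_class")
  if (any(is_te & !ft$te_class %in% TE_CLASSES)) {
    stop("te_class must be one of ", paste(TE_CLASSES, collapse = ", "))
  }
  if (any(!is_te & (is.na(ft$length_bp) | ft$length_bp < 1))) {
    stop("genes require length_bp >= 1")
  }
  class(ft) <- c("feature_table", "data.frame")
  ft
}

#' Construct and validate a sample table
#'
#' Derives \code{ploidy} and \code{is_hybrid} from the group label and
#' checks any user-supplied values against the derivation.
#'
#' @param sample_id unique sample identifiers.
#' @param group group label (one of the seven design groups).
#' @param tissue "flower" or "leaf".
#' @param line line index within group.
#' @param lane sequencing lane/batch identifier.
#' @param ploidy,is_hybrid optional; validated against the group map.
#' @return data.frame of class \code{"sample_table"}.
#' @export
sample_table <- function(sample_id, group, tissue, line, lane,
                         ploidy = NULL, is_hybrid = NULL) {
  st <- data.frame(sample_id = as.character(sample_id),
                   group = as.character(group),
                   tissue = as.character(tissue),
                   line = as.integer(line),
                   lane = as.character(lane),
                   stringsAsFactors = FALSE)
  check_groups(st$group)
  if (!all(st$tissue %in% TISSUE_LEVELS)) {
    stop("tissue must be one of ", paste(TISSUE_LEVELS, collapse = ", "))
  }
  derived_p <- group_ploidy(st$group)
  derived_h <- group_is_hybrid(st$group)
  if (!is.null(ploidy) && !all(as.integer(ploidy) == derived_p)) {
    stop("supplied ploidy contradicts the group map for sample(s): ",
         paste(st$sample_id[as.integer(ploidy) != derived_p], collapse = ", "))
  }
  if (!is.null(is_hybrid) && !all(as.logical(is_hybrid) == derived_h)) {
    stop("supplied is_hybrid contradicts the group map")
  }
  st$ploidy <- derived_p
  st$is_hybrid <- derived_h
  if (anyDuplicated(st$sample_id)) stop("duplicated sample_id")
  key <- paste(st$group, st$tissue, st$line)
  if (anyDuplicated(key)) {
    stop("duplicated (group, tissue, line): ",
         paste(unique(key[duplicated(key)])[1:3], collapse = "; "))
  }
  class(st) <- c("sample_table", "data.frame")
  st
}

#' Summarize and validate the group x tissue design
#'
#' Counts samples per group and tissue and flags cells that deviate from the
#' modal cell size (unbalanced design).
#'
#' @param samples a sample table.
#' @return list with \code{n_samples}, the \code{counts} table
#'   (group x tissue), \code{cell_size} (the modal per-cell count) and
#'   \code{unbalanced}, a data.frame of deviating cells.
#' @export
validate_design <- function(samples) {
  check_groups(samples$group)
  counts <- table(factor(samples$group, levels = GROUP_LEVELS),
                  factor(samples$tissue, levels = unique(samples$tissue)))
  tab <- as.data.frame(counts, stringsAsFactors = FALSE)
  names(tab) <- c("group", "tissue", "n")
  modal <- as.integer(names(sort(table(tab$n[tab$n > 0]), decreasing = TRUE))[1])
  unbalanced <- tab[tab$n != modal, , drop = FALSE]
  ## re-derive and assert the ploidy/hybrid map
  stopifnot(all(samples$ploidy == group_ploidy(samples$group)),
            all(samples$is_hybrid == group_is_hybrid(samples$group)))
  list(n_samples = nrow(samples), counts = counts, cell_size = modal,
       unbalanced = unbalanced)
}
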