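#' Transcripts per million
#'
#' \code{TPM_gs = 1e6 * (c_gs / len_g) / sum_g' (c_g's / len_g')}, computed
#' over gene rows only (TE features carry no reliable length and are
#' excluded by default). No fragment-length correction is applied.
#'
#' @param counts count matrix (features x samples).
#' @param features feature table matching the rows.
#' @param genes_only drop TE rows before computing (default TRUE).
#' @return matrix of TPM values with attribute \code{method = "TPM"};
#'   columns of non-empty samples sum to 1e6.
#' @export
compute_tpm <- function(counts, features, genes_only = TRUE) {
  features <- features[match(rownames(counts), features$feature_id), ]
  if (genes_only) {
    keep <- features$feature_kind == "gene"
    counts <- counts[keep, , drop = FALSE]
    features <- features[keep, , drop = FALSE]
  }
  len <- features$length_bp
  if (any(is.na(len) | len < 1)) stop("all rows need length_bp >= 1 for TPM")
  rate <- counts / len
  tot <- colSums(rate)
  if (any(tot == 0)) {
    warning("all-zero sample(s): ",
            paste(colnames(counts)[tot == 0], collapse = ", "),
            "; TPM set to 0")
    tot[tot == 0] <- 1
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  attr(tpm, "method") <- "TPM"
  tpm
}

#' Counts per million
#'
#' With \code{prior = 0}, plain CPM: \code{1e6 * c_gs / N_s} (columns sum
#' to exactly 1e6). With a positive prior the prior count is scaled by the
#' relative library size and the denominator is augmented accordingly
#' (\code{CPM_gs = 1e6 (c_gs + p_s) / (N_s + 2 p_s)} with
#' \code{p_s = prior * N_s / mean(N)}), the convention used by the
#' standard count-model packages, so log-CPM is stable for zero counts.
#'
#' @param counts count matrix.
#' @param prior prior count (>= 0).
#' @param effective_sizes optional per-sample effective library sizes (for
#'   example library size x TMM factor); defaults to column sums.
#' @param log return log2 values.
#' @return matrix of (log-)CPM values.
#' @export
compute_cpm <- function(counts, prior = 0, effective_sizes = NULL,
                        log = FALSE) {
  if (prior < 0) stop("prior must be >= 0")
  N <- if (is.null(effective_sizes)) colSums(counts) else effective_sizes
  if (length(N) != ncol(counts)) stop("effective_sizes length mismatch")
  pr <- prior * N / mean(N)
  cpm <- sweep(sweep(counts, 2, pr, "+"), 2, N + 2 * pr, "/") * 1e6
  if (log) cpm <- log2(cpm)
  attr(cpm, "method") <- if (log) "logCPM" else "CPM"
  cpm
}

#' Trimmed mean of M-values scaling factors
#'
#' Between-sample normalization robust to asymmetric differential
#' expression. The reference sample is the one whose upper-quartile /
#' library-size ratio is closest to the mean of that ratio. For each
#' sample, gene-wise log2 ratios against the reference (M) and average
#' log2 abundances (A) are computed after library-size scaling; genes with
#' a zero count in either sample are excluded, the most extreme 30% of M
#' and 5% of A are trimmed, and the factor is 2 to the
#' inverse-variance-weighted mean of the remaining M values (weights =
#' asymptotic binomial variances). Factors are rescaled to geometric
#' mean 1.
#'
#' @param counts count matrix (>= 2 samples).
#' @param thresholds \code{\link{analysis_thresholds}} (trim fractions).
#' @return named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(counts, thresholds = analysis_thresholds()) {
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  f75 <- vapply(seq_len(ncol(counts)), function(j) {
    stats::quantile(counts[, j], 0.75) / lib[j]
  }, numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
             thresholds$tmm_logratio_trim, thresholds$tmm_abs_trim,
             colnames(counts)[j])
  }, numeric(1))
  fac <- fac / exp(mean(log(fac)))
  names(fac) <- colnames(counts)
  fac
}

tmm_pair <- function(obs, ref, nO, nR, logratio_trim, abs_trim, label) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) {
    warning("sample ", label, " shares no co-expressed genes with the ",
            "reference; TMM factor set to 1")
    return(1)
  }
  obs <- obs[keep]
  ref <- ref[keep]
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * abs_trim) + 1
  hiS <- n + 1 - loS
  rl <- rank(logR)
  ra <- rank(absE)
  keep2 <- rl >= loL & rl <= hiL & ra >= loS & ra <= hiS
  f <- sum(logR[keep2] / v[keep2]) / sum(1 / v[keep2])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Expression filter
#'
#' Keep genes whose normalized value is strictly greater than
#' \code{min_value} in at least \code{min_samples} samples (strict
#' inequality on both the value and the count threshold boundary: a gene
#' sitting exactly at the value threshold is excluded).
#'
#' @param norm normalized matrix (TPM or CPM) with feature rownames.
#' @param min_value value threshold (strict).
#' @param min_samples minimum number of samples above the threshold.
#' @return character vector of kept feature ids.
#' @export
filter_expressed <- function(norm, min_value, min_samples) {
  if (min_samples < 1) stop("min_samples must be >= 1")
  keep <- rowSums(norm > min_value) >= min_samples
  rownames(norm)[keep]
}

#' Binomial downsampling toward the smallest group-mean library size
#'
#' Equalizes average sequencing depth across groups: the target is the
#' minimum over groups of the group-mean library size, and every cell of a
#' sample in group g is thinned binomially with keep probability
#' target / group-mean(g) (capped at 1). Thinning never increases a cell
#' and preserves expected proportions within a sample.
#'
#' @param counts count matrix.
#' @param samples sample table matching the columns.
#' @param seed integer seed.
#' @return thinned integer count matrix.
#' @export
downsample_to_group_mean <- function(counts, samples, seed = 1L) {
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  lib <- colSums(counts)
  gmean <- tapply(lib, samples$group, mean)
  if (any(gmean == 0)) stop("group with zero mean library size")
  target <- min(gmean)
  p <- pmin(1, target / gmean[samples$group])
  set.seed(seed)
  out <- counts
  for (j in seq_len(ncol(counts))) {
    if (p[j] < 1) {
      out[, j] <- stats::rbinom(nrow(counts), counts[, j], p[j])
    }
  }
  mode(out) <- "integer"
  out
}
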