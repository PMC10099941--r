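## Negative-binomial group-means machinery.
##
## The model is log mu_gs = beta_{g,group(s)} + log(effective library size),
## i.e. ~0 + group with a log link, per-gene dispersion phi. Group
## intercepts are profiled out by a vectorized Newton iteration (the score
## for a single group intercept is sum (y - mu) / (1 + phi mu) with Fisher
## information sum mu / (1 + phi mu)).

nb_group_beta <- function(Y, effN, phi, beta = NULL, maxit = 25L) {
  rs <- rowSums(Y)
  if (is.null(beta)) beta <- log((rs + 0.5) / sum(effN))
  for (it in seq_len(maxit)) {
    mu <- exp(beta) %o% effN
    denom <- 1 + phi * mu
    U <- rowSums((Y - mu) / denom)
    I <- rowSums(mu / denom)
    step <- ifelse(I > 1e-300, U / I, 0)
    step <- pmax(pmin(step, 5), -5)
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  beta[rs == 0] <- -30
  beta
}

## per-gene NB log-likelihood, dropping the lgamma(y + 1) constant;
## continuous Poisson limit for phi below 1e-12
nb_loglik <- function(Y, mu, phi) {
  out <- numeric(nrow(Y))
  pois <- phi < 1e-12
  if (any(!pois)) {
    r <- 1 / phi[!pois]
    Yn <- Y[!pois, , drop = FALSE]
    mun <- mu[!pois, , drop = FALSE]
    t3 <- Yn * log(mun / (r + mun))
    t3[Yn == 0] <- 0
    out[!pois] <- rowSums(lgamma(Yn + r) - lgamma(r) +
                            r * log(r / (r + mun)) + t3)
  }
  if (any(pois)) {
    Yp <- Y[pois, , drop = FALSE]
    mup <- mu[pois, , drop = FALSE]
    t <- Yp * log(mup)
    t[Yp == 0] <- 0
    out[pois] <- rowSums(t - mup)
  }
  out
}

## per-row argmax over a uniform grid with quadratic interpolation;
## rows maximized at the lower boundary return -Inf (dispersion 0)
grid_argmax <- function(ll, x) {
  j <- max.col(ll, ties.method = "first")
  dx <- x[2] - x[1]
  out <- x[j]
  interior <- j > 1 & j < length(x)
  if (any(interior)) {
    i <- which(interior)
    l0 <- ll[cbind(i, j[i] - 1)]
    l1 <- ll[cbind(i, j[i])]
    l2 <- ll[cbind(i, j[i] + 1)]
    curv <- l0 - 2 * l1 + l2
    off <- ifelse(curv < 0, 0.5 * (l0 - l2) / curv, 0)
    out[i] <- x[j[i]] + pmax(pmin(off, 1), -1) * dx
  }
  out[j == 1] <- -Inf
  out
}

#' Estimate per-gene negative-binomial dispersions
#'
#' Fits the ~0 + group model (log link, offset = log TMM-effective library
#' size) to the samples of one tissue. Per-gene raw dispersions maximize
#' the Cox-Reid adjusted profile likelihood over a log-spaced grid with
#' quadratic interpolation; the common dispersion maximizes the summed
#' profile likelihood; the shrunken dispersion is the weighted combination
#' \code{(prior_df * common + df_res * raw) / (prior_df + df_res)}.
#' All-zero genes are flagged and excluded from testing.
#'
#' @param counts count matrix (typically expression-filtered gene rows).
#' @param samples sample table matching the columns.
#' @param tissue tissue to subset to (NULL = use all supplied samples).
#' @param thresholds \code{\link{analysis_thresholds}} (TMM trims).
#' @param prior_df prior degrees of freedom for shrinkage toward the
#'   common dispersion.
#' @param grid dispersion grid (log-spaced).
#' @return list of class \code{"dispersion_estimates"}: per-gene
#'   \code{raw} and \code{shrunken} dispersions (named, NA for excluded
#'   genes), \code{common}, \code{prior_df}, \code{df_res}, per-sample
#'   \code{effective_sizes}, \code{excluded} gene ids and the sample table
#'   used.
#' @export
estimate_dispersions <- function(counts, samples, tissue = NULL,
                                 thresholds = analysis_thresholds(),
                                 prior_df = 10,
                                 grid = 2^seq(-14, 4, by = 0.5)) {
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  if (!is.null(tissue)) {
    keep <- samples$tissue == tissue
    counts <- counts[, keep, drop = FALSE]
    samples <- samples[keep, , drop = FALSE]
  }
  sizes <- table(samples$group)
  if (sum(sizes >= 2) < 2) {
    stop("need >= 2 groups with >= 2 samples in the tissue")
  }
  groups <- names(sizes)
  lib <- colSums(counts)
  fac <- tmm_factors(counts, thresholds)
  effN <- lib * fac
  expressed <- rowSums(counts) > 0
  Y <- counts[expressed, , drop = FALSE]
  G <- nrow(Y)
  idx <- lapply(groups, function(g) which(samples$group == g))
  ll <- matrix(NA_real_, G, length(grid))
  betas <- vector("list", length(groups))
  for (k in seq_along(grid)) {
    phi <- rep(grid[k], G)
    tot <- numeric(G)
    for (gi in seq_along(groups)) {
      Yg <- Y[, idx[[gi]], drop = FALSE]
      b <- nb_group_beta(Yg, effN[idx[[gi]]], phi, beta = betas[[gi]],
                         maxit = if (k == 1) 25L else 8L)
      betas[[gi]] <- b
      mu <- exp(b) %o% effN[idx[[gi]]]
      info <- pmax(rowSums(mu / (1 + phi * mu)), 1e-300)
      tot <- tot + nb_loglik(Yg, mu, phi) - 0.5 * log(info)
    }
    ll[, k] <- tot
  }
  lx <- log2(grid)
  raw_l <- grid_argmax(ll, lx)
  raw <- ifelse(is.finite(raw_l), 2^raw_l, 0)
  common_l <- grid_argmax(matrix(colSums(ll), 1), lx)
  common <- if (is.finite(common_l)) 2^common_l else 0
  df_res <- ncol(Y) - length(groups)
  shrunken <- (prior_df * common + df_res * raw) / (prior_df + df_res)
  raw_full <- shrunken_full <- stats::setNames(
    rep(NA_real_, nrow(counts)), rownames(counts))
  raw_full[expressed] <- raw
  shrunken_full[expressed] <- shrunken
  structure(list(raw = raw_full, shrunken = shrunken_full, common = common,
                 prior_df = prior_df, df_res = df_res,
                 effective_sizes = stats::setNames(effN, colnames(counts)),
                 excluded = rownames(counts)[!expressed],
                 samples = samples, tissue = tissue),
            class = "dispersion_estimates")
}

#' Pairwise negative-binomial contrast between two groups
#'
#' Likelihood-ratio test of equal group means (shrunken per-gene
#' dispersion held fixed) on the samples of the two groups in one tissue.
#' The log2 fold-change (A relative to B) comes from the fitted group
#' abundances in CPM units with the configured prior count added to both
#' sides, capped at +/- 20. The BH adjustment is applied, by default,
#' within the subset of genes whose |log2FC| exceeds log2(fc_threshold)
#' ("subset_then_bh"); the alternative "bh_then_filter" adjusts all tested
#' genes and applies the fold-change filter afterwards. A gene is "up" iff
#' log2fc > log2(fc_threshold) and q < fdr_alpha ("down" symmetric).
#'
#' @param counts count matrix (same genes as used for \code{disp}).
#' @param samples sample table matching the columns.
#' @param tissue tissue of the contrast.
#' @param groupA,groupB groups to compare (A relative to B).
#' @param disp \code{\link{estimate_dispersions}} result for this tissue.
#' @param thresholds \code{\link{analysis_thresholds}}.
#' @param fdr_mode "subset_then_bh" (default) or "bh_then_filter".
#' @return data.frame of class \code{"de_result"}: feature_id, log2fc,
#'   pvalue, qvalue, status ("up"/"down"/"ns"); attributes
#'   \code{contrast} (A, B, tissue), \code{n_tested}, \code{fdr_mode}.
#' @export
pairwise_contrast <- function(counts, samples, tissue, groupA, groupB, disp,
                              thresholds = analysis_thresholds(),
                              fdr_mode = c("subset_then_bh",
                                           "bh_then_filter")) {
  fdr_mode <- match.arg(fdr_mode)
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  keep <- samples$tissue == tissue & samples$group %in% c(groupA, groupB)
  if (!any(samples$tissue == tissue & samples$group == groupA) ||
      !any(samples$tissue == tissue & samples$group == groupB)) {
    stop("both groups must be present in tissue ", tissue)
  }
  Y <- counts[, keep, drop = FALSE]
  sub <- samples[keep, , drop = FALSE]
  effN <- disp$effective_sizes[sub$sample_id]
  if (anyNA(effN)) stop("dispersion estimates do not cover these samples")
  phi <- unname(disp$shrunken[rownames(counts)])
  tested <- !is.na(phi) & rowSums(Y) > 0
  Yt <- Y[tested, , drop = FALSE]
  phit <- pmax(phi[tested], 0)
  iA <- sub$group == groupA
  iB <- sub$group == groupB
  bA <- nb_group_beta(Yt[, iA, drop = FALSE], effN[iA], phit)
  bB <- nb_group_beta(Yt[, iB, drop = FALSE], effN[iB], phit)
  bR <- nb_group_beta(Yt, effN, phit)
  llA <- nb_loglik(Yt[, iA, drop = FALSE], exp(bA) %o% effN[iA], phit)
  llB <- nb_loglik(Yt[, iB, drop = FALSE], exp(bB) %o% effN[iB], phit)
  llR <- nb_loglik(Yt, exp(bR) %o% effN, phit)
  lrt <- pmax(2 * (llA + llB - llR), 0)
  pv <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  pc <- thresholds$cpm_prior_count * 1e6 / mean(effN)
  l2 <- log2((exp(bA) * 1e6 + pc) / (exp(bB) * 1e6 + pc))
  l2 <- pmax(pmin(l2, 20), -20)
  log2fc <- numeric(nrow(counts))
  pvalue <- qvalue <- rep(NA_real_, nrow(counts))
  log2fc[tested] <- l2
  pvalue[tested] <- pv
  lfc_cut <- log2(thresholds$fc_threshold)
  if (fdr_mode == "subset_then_bh") {
    sel <- tested & abs(log2fc) > lfc_cut
    if (any(sel)) qvalue[sel] <- bh_adjust(pvalue[sel])
    n_tested <- sum(sel)
  } else {
    qvalue[tested] <- bh_adjust(pvalue[tested])
    n_tested <- sum(tested)
  }
  sig <- !is.na(qvalue) & qvalue < thresholds$fdr_alpha
  status <- rep("ns", nrow(counts))
  status[sig & log2fc > lfc_cut] <- "up"
  status[sig & log2fc < -lfc_cut] <- "down"
  out <- data.frame(feature_id = rownames(counts), log2fc = log2fc,
                    pvalue = pvalue, qvalue = qvalue, status = status,
                    stringsAsFactors = FALSE)
  attr(out, "contrast") <- list(groupA = groupA, groupB = groupB,
                                tissue = tissue)
  attr(out, "n_tested") <- n_tested
  attr(out, "fdr_mode") <- fdr_mode
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control (delegates to
#' \code{stats::p.adjust}).
#'
#' @param pvalues numeric vector in [0, 1].
#' @return monotone adjusted q-values, clipped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Summarize DE calls
#'
#' @param results a \code{de_result} or a (possibly named) list of them.
#' @return data.frame with one row per contrast: groupA, groupB, tissue,
#'   up, down, total.
#' @export
deg_summary <- function(results) {
  if (inherits(results, "de_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    ct <- attr(r, "contrast")
    data.frame(groupA = ct$groupA, groupB = ct$groupB, tissue = ct$tissue,
               up = sum(r$status == "up"), down = sum(r$status == "down"),
               total = sum(r$status != "ns"), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
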