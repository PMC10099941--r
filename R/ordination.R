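#' Leading-logFC distance matrix
#'
#' For every pair of samples, the distance is the root-mean-square of the
#' \code{top} largest squared log2 expression differences between the two
#' samples (genes re-ranked per pair). Computed on log-CPM with a prior
#' count so zeros are finite.
#'
#' @param logcpm log2-CPM matrix (genes x samples).
#' @param top number of top genes per pair (capped at the gene count with
#'   a warning).
#' @return symmetric distance matrix with zero diagonal.
#' @export
leading_logfc_distance <- function(logcpm, top = 500) {
  if (top < 1) stop("top must be >= 1")
  G <- nrow(logcpm)
  if (top > G) {
    warning("top exceeds gene count; using all ", G, " genes")
    top <- G
  }
  n <- ncol(logcpm)
  d <- matrix(0, n, n, dimnames = list(colnames(logcpm), colnames(logcpm)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d2 <- (logcpm[, i] - logcpm[, j])^2
      topv <- sort(d2, decreasing = TRUE)[seq_len(top)]
      d[i, j] <- d[j, i] <- sqrt(mean(topv))
    }
  }
  d
}

#' Classical (metric) multidimensional scaling
#'
#' Torgerson scaling: double-center the squared distances, eigendecompose,
#' and scale the top-k eigenvectors by the square roots of their
#' eigenvalues (via \code{stats::cmdscale}). Axis signs are
#' indeterminate. An exactly Euclidean distance matrix is reproduced to
#' numerical tolerance.
#'
#' @param dist symmetric distance matrix.
#' @param k number of dimensions.
#' @return list of class \code{"ordination"}: \code{coordinates}
#'   (samples x k), \code{explained} (non-increasing eigenvalue shares
#'   over positive eigenvalues), \code{method}, \code{distance_matrix}.
#' @export
classical_mds <- function(dist, k = 2) {
  n <- nrow(dist)
  if (max(abs(dist - t(dist))) > 1e-8 || any(diag(dist) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dist),
                                          k = min(k, n - 1), eig = TRUE))
  pos <- sum(fit$eig > 1e-8 * max(abs(fit$eig), 1))
  if (k > pos) {
    warning("only ", pos, " positive eigenvalue(s); coordinates truncated")
  }
  coords <- fit$points
  if (ncol(coords) < k) {
    coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
  }
  rownames(coords) <- rownames(dist)
  eigp <- pmax(fit$eig, 0)
  expl <- if (sum(eigp) > 0) {
    (eigp / sum(eigp))[seq_len(k)]
  } else {
    rep(0, k)
  }
  structure(list(coordinates = coords[, seq_len(k), drop = FALSE],
                 explained = expl, method = "leading_logFC_MDS",
                 distance_matrix = dist),
            class = "ordination")
}

#' PCA sample scores
#'
#' Gene-centered principal components of log2(normalized value + 1) (or
#' the raw values), scores by singular-value decomposition.
#'
#' @param norm normalized matrix (genes x samples), typically
#'   TMM-adjusted TPM.
#' @param log_transform apply log2(x + 1) first (default TRUE).
#' @return list of class \code{"ordination"}: \code{coordinates}
#'   (samples x components), \code{explained} variance shares,
#'   \code{method = "PCA"}.
#' @export
pca_scores <- function(norm, log_transform = TRUE) {
  if (ncol(norm) < 2) stop("need >= 2 samples")
  x <- if (log_transform) log2(norm + 1) else norm
  if (all(apply(x, 1, stats::var) == 0)) {
    warning("constant matrix; all scores zero")
    k <- ncol(x) - 1
    return(structure(list(coordinates = matrix(0, ncol(x), k,
                                               dimnames = list(colnames(x),
                                                               NULL)),
                          explained = rep(0, k), method = "PCA"),
                     class = "ordination"))
  }
  p <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  structure(list(coordinates = p$x, explained = expl, method = "PCA"),
            class = "ordination")
}
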