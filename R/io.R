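#' Read a count matrix from TSV or MatrixMarket
#'
#' The TSV layout is features in rows (first column = feature id, header row
#' = sample ids); the MTX layout is a triplet file with sidecar id files
#' \code{<path>.features} and \code{<path>.samples} (one id per line). Rows
#' and columns are aligned by id to the supplied tables and canonicalized
#' to lexicographic order, so downstream results do not depend on file
#' order. Features/samples present in the tables but missing from the file
#' are an error; extra rows in the file are dropped with a warning.
#'
#' @param path file path (".mtx" triggers MatrixMarket parsing).
#' @param features a \code{\link{feature_table}}.
#' @param samples a \code{\link{sample_table}}.
#' @return integer matrix with feature-id rownames and sample-id colnames,
#'   carrying the (reordered) tables as attributes "features" and "samples".
#' @export
read_count_matrix <- function(path, features, samples) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(paste0(path, ".features"))
    cn <- readLines(paste0(path, ".samples"))
    if (nrow(m) != length(rn) || ncol(m) != length(cn)) {
      stop("MTX dimensions do not match sidecar id files")
    }
    dimnames(m) <- list(rn, cn)
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    rn <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- rn
  }
  if (anyDuplicated(rownames(m))) stop("duplicated feature ids in file")
  if (anyDuplicated(colnames(m))) stop("duplicated sample ids in file")
  storage <- suppressWarnings(as.numeric(m))
  bad <- which(is.na(storage) | storage < 0 | storage != round(storage))
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% nrow(m)) + 1
    j <- ((bad[1] - 1) %/% nrow(m)) + 1
    stop("non-integer or negative count at feature '", rownames(m)[i],
         "', sample '", colnames(m)[j], "'")
  }
  missing_f <- setdiff(features$feature_id, rownames(m))
  if (length(missing_f) > 0) {
    stop("count matrix lacks ", length(missing_f),
         " annotated feature(s), e.g. ", missing_f[1])
  }
  missing_s <- setdiff(samples$sample_id, colnames(m))
  if (length(missing_s) > 0) {
    stop("count matrix lacks sample(s): ", paste(missing_s, collapse = ", "))
  }
  extra <- setdiff(rownames(m), features$feature_id)
  if (length(extra) > 0) {
    warning(length(extra), " unannotated feature row(s) dropped")
  }
  fid <- sort(features$feature_id)
  sid <- sort(samples$sample_id)
  out <- m[fid, sid, drop = FALSE]
  mode(out) <- "integer"
  attr(out, "features") <- features[match(fid, features$feature_id), ]
  attr(out, "samples") <- samples[match(sid, samples$sample_id), ]
  out
}

#' Write a count matrix as TSV
#'
#' @param counts integer matrix with dimnames.
#' @param path output path.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Write a result table deterministically
#'
#' Tab-separated, UTF-8, one header line, columns in their existing order,
#' floating-point values serialized with 6 significant digits so repeated
#' writes of the same records are byte-identical.
#'
#' @param records data.frame (may have zero rows).
#' @param path output path.
#' @export
write_table <- function(records, path) {
  records <- as.data.frame(records)
  num <- vapply(records, is.double, logical(1))
  records[num] <- lapply(records[num], function(x) signif(x, 6))
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

#' Read a table written by \code{\link{write_table}}
#' @param path file path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
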