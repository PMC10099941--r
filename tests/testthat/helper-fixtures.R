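## shared fixtures: small designs and seeded NB count matrices

two_group_table <- function(n = 6, groups = c("Co2", "Cg2"),
                            tissue = "flower") {
  ids <- paste0("s", seq_len(n * length(groups)))
  sample_table(ids, rep(groups, each = n), tissue,
               rep(seq_len(n), length(groups)), "lane1")
}

nb_matrix <- function(G, mu, size, n_samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(mu) == 1) mu <- rep(mu, G)
  m <- matrix(stats::rnbinom(G * n_samples, mu = mu, size = size),
              G, n_samples)
  dimnames(m) <- list(sprintf("g%04d", seq_len(G)),
                      paste0("s", seq_len(n_samples)))
  m
}

small_config <- function(...) {
  args <- utils::modifyList(list(n_genes = 300, n_te = 40,
                                 library_size_meanlog = log(5e5)),
                            list(...))
  do.call(simulation_config, args)
}

## a de_result built directly from statuses, for classifier tests
fake_de <- function(ids, status, groupA, groupB, tissue = "flower",
                    log2fc = NULL) {
  out <- data.frame(feature_id = ids,
                    log2fc = log2fc %||% ifelse(status == "up", 2,
                                                ifelse(status == "down",
                                                       -2, 0)),
                    pvalue = ifelse(status == "ns", 0.8, 1e-6),
                    qvalue = ifelse(status == "ns", NA, 1e-4),
                    status = status, stringsAsFactors = FALSE)
  attr(out, "contrast") <- list(groupA = groupA, groupB = groupB,
                                tissue = tissue)
  class(out) <- c("de_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

all_status_triples <- function() {
  st <- c("up", "down", "ns")
  expand.grid(c1 = st, c2 = st, c12 = st, stringsAsFactors = FALSE)
}
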