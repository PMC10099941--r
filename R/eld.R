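#' The ten expression categories
#'
#' Additive/nonadditive classification labels for hybrid gene expression.
#' Complete expression-level dominance (ELD) toward parent 1 (the maternal
#' *C. orientalis*-like parent) or parent 2, high or low; transgressive
#' expression above or below both parents; strict intermediate
#' (additive); no change; a parental difference the hybrid resolves to
#' neither parent ("unresolved"); and "ambiguous" for status patterns
#' that are incoherent under test noise.
#'
#' @format character vector of the 10 labels.
#' @export
EXPRESSION_CATEGORIES <- c(
  "no_change", "additive_intermediate",
  "ELD_P1_high", "ELD_P1_low", "ELD_P2_high", "ELD_P2_low",
  "transgressive_up", "transgressive_down",
  "unresolved_parental_difference", "ambiguous")

COMPLETE_ELD_CATEGORIES <- c("ELD_P1_high", "ELD_P1_low",
                             "ELD_P2_high", "ELD_P2_low")
TRE_CATEGORIES <- c("transgressive_up", "transgressive_down")

## The decision table, isolated as a single constant so an alternative
## category scheme can be swapped in. Keys are "c1|c2|c12" with
## c1 = hybrid vs P1, c2 = hybrid vs P2, c12 = P1 vs P2, each up/down/ns.
## Unlisted triples are "ambiguous".
build_classification_table <- function() {
  st <- c("up", "down", "ns")
  keys <- as.matrix(expand.grid(c1 = st, c2 = st, c12 = st,
                                stringsAsFactors = FALSE))
  lab <- rep("ambiguous", nrow(keys))
  set_rule <- function(c1, c2, c12, label) {
    hit <- (keys[, 1] %in% c1) & (keys[, 2] %in% c2) & (keys[, 3] %in% c12)
    lab[hit] <<- label
  }
  set_rule("up", "up", st, "transgressive_up")
  set_rule("down", "down", st, "transgressive_down")
  set_rule("ns", "ns", "ns", "no_change")
  set_rule("ns", "ns", c("up", "down"), "unresolved_parental_difference")
  set_rule("ns", "up", "up", "ELD_P1_high")
  set_rule("ns", "down", "down", "ELD_P1_low")
  set_rule("up", "ns", "down", "ELD_P2_high")
  set_rule("down", "ns", "up", "ELD_P2_low")
  set_rule("up", "down", "down", "additive_intermediate")
  set_rule("down", "up", "up", "additive_intermediate")
  stats::setNames(lab, paste(keys[, 1], keys[, 2], keys[, 3], sep = "|"))
}

CLASSIFICATION_TABLE <- build_classification_table()

#' Classify a status triple
#'
#' Maps the three contrast statuses of a gene — hybrid vs parent 1, hybrid
#' vs parent 2, and parent 1 vs parent 2 (each "up", "down" or "ns") — to
#' one of the ten expression categories. Total on all 27 ordered triples:
#' same-direction changes against both parents are transgressive; a gene
#' equal to one parent but moved toward the other parent's side is
#' complete ELD; significance against both parents in opposite directions
#' consistent with the parental difference is strict additive
#' (intermediate); no significance anywhere is "no change" (or
#' "unresolved" when the parents themselves differ); the 12 remaining,
#' internally inconsistent patterns are "ambiguous". Classification
#' depends only on the statuses, never on magnitudes.
#'
#' @param c1 status of hybrid vs P1 (character vector).
#' @param c2 status of hybrid vs P2.
#' @param c12 status of P1 vs P2.
#' @return character vector of category labels.
#' @export
classify_triple <- function(c1, c2, c12) {
  st <- c("up", "down", "ns")
  if (!all(c(c1, c2, c12) %in% st)) {
    stop("statuses must be 'up', 'down' or 'ns'")
  }
  unname(CLASSIFICATION_TABLE[paste(c1, c2, c12, sep = "|")])
}

#' Classify every gene of a hybrid group
#'
#' Combines three DE results sharing one gene universe, tissue and
#' thresholds — hybrid vs P1 (Co2), hybrid vs P2 (Cg2), and the parental
#' contrast — into per-gene categories plus summary proportions. The
#' parental contrast may be supplied in either orientation; it is
#' re-oriented internally to P1 vs P2 using its contrast attribute.
#'
#' @param de_h_p1 \code{de_result} for hybrid vs Co2.
#' @param de_h_p2 \code{de_result} for hybrid vs Cg2.
#' @param de_p1_p2 \code{de_result} for the parental contrast (Co2 vs Cg2
#'   or Cg2 vs Co2).
#' @return list with \code{categories} (data.frame feature_id, c1, c2,
#'   c12, category) and \code{proportions} (complete ELD, TRE,
#'   nonadditive = ELD + TRE, over the shared gene universe).
#' @export
classify_hybrid_group <- function(de_h_p1, de_h_p2, de_p1_p2) {
  ids <- de_h_p1$feature_id
  for (other in list(de_h_p2, de_p1_p2)) {
    diff <- length(union(ids, other$feature_id)) -
      length(intersect(ids, other$feature_id))
    if (diff > 0) {
      stop("gene universes differ between contrasts (symmetric difference ",
           diff, " genes)")
    }
  }
  c1 <- de_h_p1$status
  c2 <- de_h_p2$status[match(ids, de_h_p2$feature_id)]
  cp <- de_p1_p2$status[match(ids, de_p1_p2$feature_id)]
  ct <- attr(de_p1_p2, "contrast")
  if (!is.null(ct) && identical(ct$groupA, "Cg2")) {
    cp <- flip_status(cp)  # re-orient Cg2-vs-Co2 to P1 (Co2) vs P2
  }
  category <- classify_triple(c1, c2, cp)
  cats <- data.frame(feature_id = ids, c1 = c1, c2 = c2, c12 = cp,
                     category = category, stringsAsFactors = FALSE)
  n <- nrow(cats)
  props <- c(complete_eld = sum(category %in% COMPLETE_ELD_CATEGORIES) / n,
             tre = sum(category %in% TRE_CATEGORIES) / n,
             nonadditive = sum(category %in% c(COMPLETE_ELD_CATEGORIES,
                                               TRE_CATEGORIES)) / n)
  list(categories = cats, proportions = props)
}

flip_status <- function(s) {
  out <- s
  out[s == "up"] <- "down"
  out[s == "down"] <- "up"
  out
}

#' Intersection-region counts for 2-4 named gene sets
#'
#' Computes the count of every membership region (the regions partition
#' the union), as used for Venn-style comparisons of nonadditive gene
#' sets across hybrid groups and against parentally differential genes.
#'
#' @param sets named list of 2-4 character vectors of gene ids.
#' @return data.frame with one row per region: the membership pattern per
#'   set (logical columns) and \code{count}.
#' @export
overlap_analysis <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("sets must be named")
  }
  if (length(sets) < 2 || length(sets) > 4) stop("provide 2-4 sets")
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL,
                                                              names(sets)))
  pat <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))
  names(pat) <- names(sets)
  pat <- pat[rowSums(pat) > 0, , drop = FALSE]
  pat$count <- apply(pat, 1, function(p) {
    sum(apply(member, 1, function(m) all(m == p)))
  })
  rownames(pat) <- NULL
  pat
}
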