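#' One-way ANOVA
#'
#' Classical between/within decomposition with df (k - 1, n - k), via
#' \code{stats::lm}.
#'
#' @param values numeric response per individual.
#' @param groups group labels.
#' @return list: \code{F}, \code{df} (between, within), \code{pvalue},
#'   \code{group_means}.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (length(values) - nlevels(groups) < 2) stop("need >= 2 residual df")
  if (stats::var(values) == 0) {
    stop("zero total variance: F undefined")
  }
  tab <- stats::anova(stats::lm(values ~ groups))
  list(F = tab$`F value`[1], df = tab$Df, pvalue = tab$`Pr(>F)`[1],
       group_means = tapply(values, groups, mean))
}

#' Tukey HSD with compact letter display
#'
#' All pairwise comparisons via the studentized range distribution
#' (Tukey-Kramer for unbalanced groups, through \code{stats::TukeyHSD}),
#' encoded as letters by the insert-absorb algorithm: groups sharing a
#' letter are not significantly different at \code{alpha}. Letters are
#' assigned deterministically with groups ordered by mean descending.
#'
#' @param values numeric response per individual.
#' @param groups group labels.
#' @param alpha family-wise significance level.
#' @return list: \code{pairwise} (data.frame group1, group2, diff,
#'   p_adj), \code{letters} (named character vector),
#'   \code{group_means}.
#' @export
tukey_hsd_letters <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  means <- tapply(values, groups, mean)
  if (nlevels(groups) == 1) {
    return(list(pairwise = data.frame(group1 = character(0),
                                      group2 = character(0),
                                      diff = numeric(0),
                                      p_adj = numeric(0)),
                letters = stats::setNames("a", levels(groups)),
                group_means = means))
  }
  tk <- stats::TukeyHSD(stats::aov(values ~ groups))[[1]]
  ## reconstruct the pair order TukeyHSD uses (column-major lower
  ## triangle) rather than splitting rownames, which breaks on group
  ## labels that contain "-"
  lv <- levels(groups)
  idx <- which(lower.tri(matrix(0, nlevels(groups), nlevels(groups))),
               arr.ind = TRUE)
  stopifnot(identical(rownames(tk),
                      paste(lv[idx[, 1]], lv[idx[, 2]], sep = "-")))
  pairwise <- data.frame(group1 = lv[idx[, 1]], group2 = lv[idx[, 2]],
                         diff = tk[, "diff"], p_adj = tk[, "p adj"],
                         stringsAsFactors = FALSE)
  rownames(pairwise) <- NULL
  sig <- pairwise[pairwise$p_adj < alpha, , drop = FALSE]
  letters <- compact_letter_display(levels(groups)[order(means,
                                                         decreasing = TRUE)],
                                    sig)
  list(pairwise = pairwise, letters = letters[levels(groups)],
       group_means = means)
}

## insert-absorb compact letter display: start from one set holding all
## groups; every significant pair splits each set containing both; absorb
## sets that became subsets of others. `ordered_groups` fixes letter order.
compact_letter_display <- function(ordered_groups, sig_pairs) {
  sets <- list(ordered_groups)
  if (nrow(sig_pairs) > 0) {
    for (k in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs$group1[k]
      b <- sig_pairs$group2[k]
      new_sets <- list()
      for (s in sets) {
        if (a %in% s && b %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      ## absorb: drop sets contained in another set
      keep <- rep(TRUE, length(new_sets))
      for (i in seq_along(new_sets)) {
        for (j in seq_along(new_sets)) {
          if (i != j && keep[j] &&
              all(new_sets[[i]] %in% new_sets[[j]]) &&
              (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j)) {
            keep[i] <- FALSE
            break
          }
        }
      }
      sets <- new_sets[keep]
    }
  }
  ## order sets by the position of their best-ranked member, assign letters
  pos <- vapply(sets, function(s) min(match(s, ordered_groups)), numeric(1))
  sets <- sets[order(pos)]
  out <- stats::setNames(rep("", length(ordered_groups)), ordered_groups)
  for (i in seq_along(sets)) {
    l <- letters[i]
    for (g in sets[[i]]) out[g] <- paste0(out[g], l)
  }
  out
}

#' Quasi-binomial GLM with analysis-of-deviance F-tests
#'
#' Fits numerator/denominator proportion data with a binomial-logit GLM
#' whose dispersion is estimated from Pearson residuals (phi = Pearson
#' chi-square / residual df of the full model). Coefficient point
#' estimates equal the plain binomial fit; only standard errors and tests
#' scale with sqrt(phi). Terms are tested with type II
#' analysis-of-deviance F-tests (each main effect against the model
#' containing the other main effects; interactions last), F =
#' (delta deviance / delta df) / phi with (delta df, residual df) degrees
#' of freedom. Type III (each term dropped from the full model) is
#' available; the two differ only with interactions and unbalanced data.
#'
#' @param obs data.frame with \code{numerator} and \code{denominator}
#'   columns plus the covariates named in \code{terms}.
#' @param terms character vector of main-effect column names, in testing
#'   order.
#' @param interactions character vector of interaction terms such as
#'   \code{"a:b"} (may be empty).
#' @param type 2 (default) or 3.
#' @return list of class \code{"qb_glm"}: \code{coefficients} (estimate,
#'   SE on the logit scale), \code{dispersion}, \code{deviance},
#'   \code{df_residual}, \code{anova_table} (term, df, F, pvalue) and the
#'   underlying \code{fit}.
#' @export
quasibinomial_glm <- function(obs, terms, interactions = character(0),
                              type = 2) {
  if (any(obs$denominator <= 0)) stop("denominators must be > 0")
  if (any(obs$numerator < 0 | obs$numerator > obs$denominator)) {
    stop("numerators must lie in [0, denominator]")
  }
  all_terms <- c(terms, interactions)
  rhs <- function(tt) if (length(tt) == 0) "1" else paste(tt, collapse = " + ")
  form <- function(tt) {
    stats::as.formula(paste("cbind(numerator, denominator - numerator) ~",
                            rhs(tt)))
  }
  full <- stats::glm(form(all_terms), family = stats::quasibinomial("logit"),
                     data = obs)
  if (any(is.na(stats::coef(full)))) {
    stop("rank-deficient design; aliased: ",
         paste(names(stats::coef(full))[is.na(stats::coef(full))],
               collapse = ", "))
  }
  mu <- stats::fitted(full)
  if (any(mu < 1e-8 | mu > 1 - 1e-8)) {
    warning("fitted probabilities numerically 0 or 1 (separation); ",
            "estimates are profile-capped by the IRLS iteration limit")
  }
  phi <- sum(stats::residuals(full, type = "pearson")^2) /
    stats::df.residual(full)
  df2 <- stats::df.residual(full)
  dev <- function(tt) {
    f <- stats::glm(form(tt), family = stats::quasibinomial("logit"),
                    data = obs)
    c(stats::deviance(f), stats::df.residual(f))
  }
  dev_full <- c(stats::deviance(full), stats::df.residual(full))
  contains <- function(big, small) {
    all(strsplit(small, ":")[[1]] %in% strsplit(big, ":")[[1]])
  }
  rows <- lapply(all_terms, function(t) {
    if (type == 3) {
      reduced <- dev(setdiff(all_terms, t))
      base <- dev_full
    } else {
      ## type II: test t against the model holding every term that does
      ## not contain t (so main effects ignore their own interactions,
      ## while unrelated terms are tested with the interaction retained)
      others <- all_terms[all_terms != t &
                            !vapply(all_terms, contains, logical(1),
                                    small = t)]
      reduced <- dev(others)
      base <- dev(c(others, t))
    }
    ddf <- reduced[2] - base[2]
    Fv <- ((reduced[1] - base[1]) / ddf) / phi
    data.frame(term = t, df = ddf, F = Fv,
               pvalue = stats::pf(Fv, ddf, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  anova_table <- do.call(rbind, rows)
  sm <- summary(full)
  structure(list(coefficients = data.frame(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, 1],
    se = sm$coefficients[, 2], stringsAsFactors = FALSE),
    dispersion = phi, deviance = stats::deviance(full),
    df_residual = df2, anova_table = anova_table, fit = full),
    class = "qb_glm")
}

#' Full phenotype results bundle
#'
#' Runs ANOVA + Tukey letters on stem length, flowering time and pollen
#' grains per flower; quasi-binomial hybrid x WGD GLMs on pollen
#' viability (two flowers summed per individual) and the normal-seed
#' proportion; the targeted allotetraploid-vs-diploid-hybrid viability
#' contrast (Allo-h vs F2) as a single-factor quasi-binomial GLM; and a
#' descriptive summary of autonomous selfed seed set.
#'
#' @param pheno phenotype table (as from
#'   \code{\link{simulate_phenotypes}}).
#' @param alpha significance level for letter displays.
#' @return list with one entry per trait.
#' @export
phenotype_report <- function(pheno, alpha = 0.05) {
  pheno$is_hybrid <- group_is_hybrid(pheno$group)
  pheno$is_tetraploid <- group_ploidy(pheno$group) == 4
  anova_traits <- c("stem_length", "flowering_time", "pollen_per_flower")
  out <- lapply(anova_traits, function(tr) {
    v <- pheno[[tr]]
    ok <- !is.na(v)
    c(one_way_anova(v[ok], pheno$group[ok]),
      tukey_hsd_letters(v[ok], pheno$group[ok], alpha = alpha))
  })
  names(out) <- anova_traits
  pollen <- data.frame(numerator = pheno$pollen_viable,
                       denominator = pheno$pollen_examined,
                       is_hybrid = pheno$is_hybrid,
                       is_tetraploid = pheno$is_tetraploid,
                       group = pheno$group)
  out$pollen_viability <- quasibinomial_glm(
    pollen, terms = c("is_hybrid", "is_tetraploid"),
    interactions = "is_hybrid:is_tetraploid")
  seeds <- data.frame(numerator = pheno$seeds_normal,
                      denominator = pheno$seeds_total,
                      is_hybrid = pheno$is_hybrid,
                      is_tetraploid = pheno$is_tetraploid)
  out$normal_seeds <- quasibinomial_glm(
    seeds, terms = c("is_hybrid", "is_tetraploid"),
    interactions = "is_hybrid:is_tetraploid")
  ah_f2 <- pollen[pollen$group %in% c("Allo-h", "F2"), ]
  out$viability_alloh_vs_f2 <- quasibinomial_glm(
    ah_f2, terms = "is_tetraploid")
  out$selfed_seed_set <- tapply(pheno$selfed_seed_set, pheno$group, mean)
  out
}
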