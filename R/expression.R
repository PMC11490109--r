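#' One-vs-rest tissue overexpression ranking (moderated t)
#'
#' For each gene, contrasts the target tissue against all other samples:
#' `logfc = mean(target) - mean(rest)`, pooled two-group residual variance
#' `s2` with `d = n1 + n2 - 2` degrees of freedom, and a moderated variance
#' that shrinks `s2` toward an across-gene prior by a method-of-moments
#' inverse-gamma fit: `s2_tilde = (d0 * s0^2 + d * s2) / (d0 + d)`. The
#' moderated t is `logfc / (s_tilde * sqrt(1/n1 + 1/n2))` with `d + d0`
#' degrees of freedom; p-values are two-sided, FDR by Benjamini-Hochberg.
#' A gene is flagged overexpressed (`top5_flag`) iff `logfc > 0` and its t
#' lies in the top `top_fraction` of t-values among positive-logfc genes
#' (set `scope = "all"` to rank over all genes instead).
#'
#' With `prior_df = 0` the statistic reduces exactly to the ordinary
#' pooled-variance two-sample t.
#'
#' @param expr An [expression_matrix()].
#' @param target_tissue Tissue label to contrast against the rest.
#' @param top_fraction Fraction of top t-values flagged (default 0.05).
#' @param prior_df Prior degrees of freedom `d0`; `NULL` (default)
#'   estimates it by method of moments, `0` disables moderation.
#' @param scope Rank the top fraction within `"positive"`-logfc genes
#'   (default) or over `"all"` genes.
#' @return data.frame (`OverexpressionTable`): `gene`, `logfc`,
#'   `t_moderated`, `p_value`, `fdr`, `top5_flag`; prior parameters in
#'   attributes. Genes whose t is undefined (zero moderated variance with
#'   nonzero logfc) keep their `logfc` but have `t_moderated = NA` and are
#'   excluded from ranking; they are listed in `attr(, "dropped_genes")`.
#' @export
overexpression_rank <- function(expr, target_tissue, top_fraction = 0.05,
                                prior_df = NULL,
                                scope = c("positive", "all")) {
  scope <- match.arg(scope)
  stopifnot(inherits(expr, "expression_matrix"))
  in_t <- expr$tissue_of_sample == target_tissue
  n1 <- sum(in_t); n2 <- sum(!in_t)
  if (n1 < 2L || n2 < 2L) {
    stop("need at least 2 samples in the target tissue and in the rest")
  }
  x <- expr$values[, in_t, drop = FALSE]
  y <- expr$values[, !in_t, drop = FALSE]
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  logfc <- m1 - m2
  d <- n1 + n2 - 2
  s2 <- (rowSums((x - m1)^2) + rowSums((y - m2)^2)) / d

  if (is.null(prior_df)) {
    s2bar <- mean(s2)
    v_within <- 2 * s2bar^2 / d        # E Var(s2 | sigma2) at sigma2 ~ s2bar
    v_prior <- stats::var(s2) - v_within
    if (!is.finite(v_prior) || v_prior <= 0) {
      d0 <- 1e6                        # no between-gene spread: full shrink
      s0sq <- s2bar
    } else {
      d0 <- 4 + 2 * s2bar^2 / v_prior  # inverse-gamma moment match
      s0sq <- s2bar * (d0 - 2) / d0
    }
  } else {
    d0 <- prior_df
    s0sq <- if (d0 > 0) mean(s2) else 0
  }
  s2_tilde <- (d0 * s0sq + d * s2) / (d0 + d)
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, logfc / se, ifelse(logfc == 0, 0, NA_real_))
  df_mod <- d + min(d0, 1e6)
  p <- 2 * stats::pt(-abs(t_mod), df = df_mod)
  out <- data.frame(gene = expr$genes, logfc = logfc, t_moderated = t_mod,
                    p_value = p, fdr = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  usable <- !is.na(out$t_moderated)
  pool <- usable & (if (scope == "positive") out$logfc > 0 else TRUE)
  flag <- rep(FALSE, nrow(out))
  if (any(pool)) {
    thr <- stats::quantile(out$t_moderated[pool], 1 - top_fraction,
                           names = FALSE)
    flag <- pool & out$logfc > 0 & out$t_moderated >= thr
  }
  out$top5_flag <- flag
  if (any(!usable)) {
    attr(out, "dropped_genes") <- out$gene[!usable]
    message(sum(!usable), " gene(s) with undefined t dropped from ranking")
  }
  attr(out, "prior") <- list(d0 = d0, s0sq = s0sq, df_moderated = df_mod,
                             target_tissue = target_tissue)
  out
}

#' Chi-squared enrichment of selected genes among overexpressed genes
#'
#' Pearson chi-squared test (no continuity correction) on the 2x2 table of
#' selected/overexpressed membership over a background gene universe. The
#' Bonferroni-corrected significance level used for the tissue panel
#' (default `0.05 / 22`) is recorded in the result.
#'
#' @param selected_genes Gene ids in selection regions.
#' @param overexpressed Gene ids flagged overexpressed in the tissue.
#' @param background The background gene universe (superset).
#' @param n_tests Number of tissues tested (Bonferroni divisor;
#'   default 22).
#' @param tissue Optional label.
#' @return List (`EnrichmentResult`): `tissue`, `table2x2`, `chi2_stat`,
#'   `p_value`, `bonferroni_alpha`.
#' @export
enrichment_chi2 <- function(selected_genes, overexpressed, background,
                            n_tests = 22, tissue = NA_character_) {
  background <- unique(background)
  selected_genes <- intersect(unique(selected_genes), background)
  overexpressed <- intersect(unique(overexpressed), background)
  sel <- background %in% selected_genes
  ove <- background %in% overexpressed
  tab <- matrix(c(sum(sel & ove), sum(sel & !ove),
                  sum(!sel & ove), sum(!sel & !ove)),
                nrow = 2, byrow = TRUE,
                dimnames = list(selected = c("yes", "no"),
                                overexpressed = c("yes", "no")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    stop("degenerate 2x2 table: an expected cell count is zero")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(tissue = tissue, table2x2 = tab,
       chi2_stat = unname(ct$statistic), p_value = ct$p.value,
       bonferroni_alpha = 0.05 / n_tests)
}
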