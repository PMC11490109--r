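#' Co-localise top-scoring variants with cis-eQTL
#'
#' Exact (chrom, pos) matching between the per-population top-0.01\%
#' variants and significant cis-eQTL; one hit is reported per
#' (variant, tissue, eGene, population) combination, so a shared position
#' regulating genes in several tissues yields several hits.
#'
#' @param top_variants data.frame with `population`, `chrom`, `pos` and
#'   optionally `z` (the variant's standardized iHS).
#' @param eqtl eQTL records as from [read_eqtl_table()].
#' @return data.frame of hits: `evariant_id`, `chrom`, `pos`, `tissue`,
#'   `egene`, `population`, `z`.
#' @export
colocalize <- function(top_variants, eqtl) {
  empty <- data.frame(evariant_id = character(), chrom = character(),
                      pos = numeric(), tissue = character(),
                      egene = character(), population = character(),
                      z = numeric())
  if (!nrow(top_variants) || !nrow(eqtl)) return(empty)
  tv <- top_variants
  if (!"z" %in% names(tv)) tv$z <- NA_real_
  key_e <- paste(eqtl$chrom, eqtl$pos)
  key_v <- paste(tv$chrom, tv$pos)
  m <- match(key_e, key_v) # first variant row per eQTL key
  hits <- do.call(rbind, lapply(which(!is.na(m)), function(i) {
    rows <- which(key_v == key_e[i])
    data.frame(evariant_id = eqtl$evariant_id[i], chrom = eqtl$chrom[i],
               pos = eqtl$pos[i], tissue = eqtl$tissue[i],
               egene = eqtl$egene[i], population = tv$population[rows],
               z = tv$z[rows], stringsAsFactors = FALSE)
  }))
  if (is.null(hits)) return(empty)
  hits <- unique(hits)
  rownames(hits) <- NULL
  hits
}

# intervals: df with start/stop (1-based inclusive) on one chromosome of
# length L. Apply circular shift by s bp, splitting wrapped intervals.
shift_intervals_circular <- function(start, stop, s, L) {
  ns <- ((start - 1 + s) %% L) + 1
  ne <- ns + (stop - start)
  wrap <- ne > L
  out_start <- c(ns[!wrap], ns[wrap], rep(1, sum(wrap)))
  out_stop <- c(ne[!wrap], rep(L, sum(wrap)), ne[wrap] - L)
  o <- order(out_start)
  list(start = out_start[o], stop = out_stop[o])
}

count_positions_in <- function(pos, start, stop) {
  if (!length(start)) return(0L)
  i <- findInterval(pos, start)
  sum(i >= 1 & pos <= stop[pmax(i, 1L)])
}

#' Circular-permutation test for signature / eQTL overlap
#'
#' The observed statistic is the number of eQTL positions falling inside
#' any selection-signature interval. The null distribution is built by
#' circular randomization: in each permutation the whole signature set on
#' each chromosome is shifted by one uniform random offset (wrapping
#' around the chromosome end), which preserves the number, lengths, order
#' and spacing of the intervals. The empirical p-value is
#' `(#\{perm >= observed\} + 1) / (n_perm + 1)`.
#'
#' @param signatures data.frame of intervals: `chrom`, `start`, `stop`.
#' @param eqtl_positions data.frame with `chrom`, `pos` (one tissue at a
#'   time; see [circular_permutation_by_tissue()] for a panel).
#' @param chrom_lengths Named vector of chromosome lengths (bp), covering
#'   every interval.
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Optional seed.
#' @param tissue Label carried to the result.
#' @param validate Assert conservation of interval count and total length
#'   in every permutation (used by tests).
#' @return List (`PermutationResult`): `tissue`, `observed_overlap`,
#'   `perm_mean`, `perm_sd`, `z_score`, `p_empirical`, `n_perm`, `seed`.
#' @export
circular_permutation_test <- function(signatures, eqtl_positions,
                                      chrom_lengths, n_perm = 10000,
                                      seed = NULL, tissue = NA_character_,
                                      validate = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  sig <- split(signatures, signatures$chrom)
  for (chr in names(sig)) {
    L <- chrom_lengths[[chr]]
    if (is.null(L) || is.na(L)) stop("missing chromosome length for ", chr)
    if (any(sig[[chr]]$stop > L)) {
      stop("interval beyond chromosome length on ", chr)
    }
    sig[[chr]] <- merge_intervals(sig[[chr]][order(sig[[chr]]$start), ,
                                             drop = FALSE])
  }
  pos <- split(eqtl_positions$pos, eqtl_positions$chrom)
  observed <- 0L
  for (chr in names(sig)) {
    p <- pos[[chr]]
    if (is.null(p)) next
    observed <- observed +
      count_positions_in(sort(p), sig[[chr]]$start, sig[[chr]]$stop)
  }
  perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    tot <- 0L
    for (chr in names(sig)) {
      L <- chrom_lengths[[chr]]
      s <- floor(stats::runif(1) * L)
      sh <- shift_intervals_circular(sig[[chr]]$start, sig[[chr]]$stop,
                                     s, L)
      if (validate) {
        stopifnot(
          sum(sh$stop - sh$start + 1) ==
            sum(sig[[chr]]$stop - sig[[chr]]$start + 1),
          length(sh$start) >= nrow(sig[[chr]]))
      }
      p <- pos[[chr]]
      if (!is.null(p)) {
        tot <- tot + count_positions_in(sort(p), sh$start, sh$stop)
      }
    }
    perm[b] <- tot
  }
  m <- mean(perm)
  sdv <- stats::sd(perm)
  list(tissue = tissue, observed_overlap = observed, perm_mean = m,
       perm_sd = sdv,
       z_score = if (is.na(sdv) || sdv == 0) NA_real_ else
         (observed - m) / sdv,
       p_empirical = (sum(perm >= observed) + 1) / (n_perm + 1),
       n_perm = n_perm, seed = seed)
}

#' Run the circular-permutation test for every tissue in an eQTL table
#' @inheritParams circular_permutation_test
#' @param eqtl eQTL records with `chrom`, `pos`, `tissue`.
#' @return data.frame with one row per tissue.
#' @export
circular_permutation_by_tissue <- function(signatures, eqtl, chrom_lengths,
                                           n_perm = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(split(eqtl, eqtl$tissue), function(d) {
    r <- circular_permutation_test(signatures, d, chrom_lengths,
                                   n_perm = n_perm, tissue = d$tissue[1])
    data.frame(tissue = r$tissue, observed_overlap = r$observed_overlap,
               perm_mean = r$perm_mean, perm_sd = r$perm_sd,
               z_score = r$z_score, p_empirical = r$p_empirical,
               n_perm = r$n_perm)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

join_fst_eqtl <- function(fst, eqtl) {
  key_f <- paste(fst$chrom, fst$pos)
  key_e <- paste(eqtl$chrom, eqtl$pos)
  m <- match(key_e, key_f)
  ok <- !is.na(m)
  data.frame(evariant_id = eqtl$evariant_id[ok],
             global_fst = fst$global_fst[m[ok]],
             slope = eqtl$slope[ok], stringsAsFactors = FALSE)
}

# leave-one-out 390x rule: |s_i| > factor * mean(|s_(-i)|), strict
flag_slope_outliers <- function(abs_slope, factor) {
  n <- length(abs_slope)
  if (n < 2L) return(rep(FALSE, n))
  loo_mean <- (sum(abs_slope) - abs_slope) / (n - 1)
  abs_slope > factor * loo_mean
}

#' Spearman correlation of FST with cis-eQTL effect size
#'
#' For one tissue, joins the per-variant global FST with the cis-eQTL
#' slopes on (chrom, pos), excludes extreme-effect variants whose
#' `|slope|` exceeds `outlier_factor` times the mean of all other
#' `|slope|` values in that tissue (leave-one-out, strict), and reports
#' the Spearman rank correlation (average ranks for ties) between FST and
#' `|slope|` with a two-sided p-value from the t approximation.
#'
#' @param fst FST table from [wc_fst()].
#' @param eqtl eQTL records for one tissue.
#' @param outlier_factor Exclusion multiple (default 390).
#' @param use_abs Correlate `|slope|` (default) or the signed slope.
#' @return List: `tissue`, `spearman_rho`, `rho_p`, `n_used`,
#'   `excluded_outliers` (variant ids).
#' @export
fst_slope_correlation <- function(fst, eqtl, outlier_factor = 390,
                                  use_abs = TRUE) {
  d <- join_fst_eqtl(fst, eqtl)
  if (!nrow(d)) stop("no variant shared between FST table and eQTL records")
  out_flag <- flag_slope_outliers(abs(d$slope), outlier_factor)
  excluded <- d$evariant_id[out_flag]
  d <- d[!out_flag, , drop = FALSE]
  if (nrow(d) < 3L) {
    stop("fewer than 3 variants remain after outlier exclusion")
  }
  y <- if (use_abs) abs(d$slope) else d$slope
  n <- nrow(d)
  rho <- stats::cor(rank(d$global_fst), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(tissue = eqtl$tissue[1], spearman_rho = rho, rho_p = p, n_used = n,
       excluded_outliers = excluded)
}

#' Wilcoxon comparison of adaptive vs non-adaptive cis-eQTL slopes
#'
#' Adaptive variants are those in the top `top_q` quantile of global FST
#' among the variants carrying an eQTL slope in the tissue (default top
#' 1\%); their `|slope|` distribution is compared to the remaining
#' (non-adaptive) variants by a two-sided Wilcoxon rank-sum test — exact
#' enumeration when both groups have at most 12 observations and no ties,
#' otherwise the normal approximation with tie correction.
#'
#' @param fst FST table from [wc_fst()].
#' @param eqtl eQTL records for one tissue.
#' @param top_q Upper FST quantile defining the adaptive set
#'   (default 0.01).
#' @param use_abs Compare `|slope|` (default) or signed slopes.
#' @param alternative Passed to [stats::wilcox.test()]
#'   (default `"two.sided"`).
#' @return List: `tissue`, `wilcoxon_p`, `n_adaptive`, `n_nonadaptive`,
#'   `median_abs_slope_adaptive`, `median_abs_slope_nonadaptive`,
#'   `adaptive_cutoff_fst`.
#' @export
adaptive_vs_nonadaptive <- function(fst, eqtl, top_q = 0.01,
                                    use_abs = TRUE,
                                    alternative = "two.sided") {
  d <- join_fst_eqtl(fst, eqtl)
  if (!nrow(d)) stop("no variant shared between FST table and eQTL records")
  cutoff <- top_quantile_threshold(d$global_fst, q = top_q)
  adaptive <- d$global_fst >= cutoff
  if (!any(adaptive) || all(adaptive)) {
    stop("adaptive/non-adaptive split is degenerate")
  }
  y <- if (use_abs) abs(d$slope) else d$slope
  xa <- y[adaptive]; xn <- y[!adaptive]
  exact <- length(xa) <= 12 && length(xn) <= 12 &&
    !anyDuplicated(c(xa, xn))
  wt <- suppressWarnings(stats::wilcox.test(
    xa, xn, alternative = alternative, exact = exact, correct = FALSE))
  list(tissue = eqtl$tissue[1], wilcoxon_p = wt$p.value,
       n_adaptive = length(xa), n_nonadaptive = length(xn),
       median_abs_slope_adaptive = stats::median(abs(y[adaptive])),
       median_abs_slope_nonadaptive = stats::median(abs(y[!adaptive])),
       adaptive_cutoff_fst = cutoff)
}

#' Per-tissue adaptive-eQTL statistics
#'
#' Convenience wrapper running [fst_slope_correlation()] and
#' [adaptive_vs_nonadaptive()] for each tissue present in an eQTL table.
#'
#' @inheritParams fst_slope_correlation
#' @inheritParams adaptive_vs_nonadaptive
#' @return data.frame with one row per tissue.
#' @export
adaptive_eqtl_by_tissue <- function(fst, eqtl, outlier_factor = 390,
                                    top_q = 0.01, use_abs = TRUE) {
  res <- lapply(split(eqtl, eqtl$tissue), function(d) {
    co <- fst_slope_correlation(fst, d, outlier_factor = outlier_factor,
                                use_abs = use_abs)
    wt <- adaptive_vs_nonadaptive(fst, d, top_q = top_q, use_abs = use_abs)
    data.frame(tissue = co$tissue, spearman_rho = co$spearman_rho,
               rho_p = co$rho_p, n_used = co$n_used,
               n_excluded = length(co$excluded_outliers),
               wilcoxon_p = wt$wilcoxon_p,
               median_abs_slope_adaptive = wt$median_abs_slope_adaptive,
               median_abs_slope_nonadaptive =
                 wt$median_abs_slope_nonadaptive,
               adaptive_cutoff_fst = wt$adaptive_cutoff_fst)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
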