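#' Multi-population Weir-Cockerham FST per variant
#'
#' Per-variant Weir & Cockerham (1984) variance-components estimator
#' `theta = a / (a + b + c)` across all populations jointly, from diploid
#' genotypes. Variants monomorphic across every population (zero
#' denominator) are dropped. Negative estimates are retained.
#'
#' @param genotypes List (one element per population) of integer dosage
#'   matrices, variants x individuals, values 0/1/2, all with the same
#'   variant rows.
#' @param chrom,pos Optional per-variant coordinates carried to the output.
#' @return data.frame (`FstTable`): `chrom`, `pos`, `global_fst`,
#'   `n_pops_used`.
#' @export
wc_fst <- function(genotypes, chrom = NULL, pos = NULL) {
  r <- length(genotypes)
  if (r < 2L) stop("at least two populations are required for FST")
  genotypes <- lapply(genotypes, as.matrix)
  nv <- nrow(genotypes[[1]])
  if (any(vapply(genotypes, nrow, 0L) != nv)) {
    stop("all populations must cover the same variants")
  }
  n_i <- vapply(genotypes, ncol, 0L)       # diploids per population
  if (any(n_i < 1L)) stop("every population needs at least one genotype")
  p_i <- vapply(genotypes, function(g) rowMeans(g) / 2, numeric(nv))
  h_i <- vapply(genotypes, function(g) rowMeans(g == 1L), numeric(nv))
  if (nv == 1L) { p_i <- rbind(p_i); h_i <- rbind(h_i) }

  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  w <- n_i / (r * nbar)
  pbar <- as.vector(p_i %*% w)
  s2 <- as.vector(((p_i - pbar)^2 %*% n_i)) / ((r - 1) * nbar)
  hbar <- as.vector(h_i %*% w)

  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  keep <- is.finite(denom) & denom != 0
  if (is.null(chrom)) chrom <- rep("1", nv)
  if (is.null(pos)) pos <- seq_len(nv)
  data.frame(chrom = chrom[keep], pos = pos[keep],
             global_fst = (a / denom)[keep],
             n_pops_used = r, stringsAsFactors = FALSE)
}

#' Weir-Cockerham FST from phased haplotype sets
#'
#' Convenience wrapper pairing consecutive haplotypes into diploids.
#'
#' @param hap_list List of [haplotype_set()] objects on the same variants.
#' @return See [wc_fst()].
#' @export
wc_fst_from_haplotypes <- function(hap_list) {
  stopifnot(length(hap_list) >= 2)
  pos <- hap_list[[1]]$positions
  for (hs in hap_list) {
    if (!identical(hs$positions, pos)) {
      stop("haplotype sets must share the same variant positions")
    }
  }
  genotypes <- lapply(hap_list, function(hs) t(diploid_dosages(hs)))
  wc_fst(genotypes, chrom = rep(hap_list[[1]]$chrom, length(pos)),
         pos = pos)
}

#' Windowed LD r-squared summary
#'
#' Squared Pearson correlation of diploid allele dosages for every pair of
#' polymorphic variants within `window_bp` of each other; reports the mean
#' and median over pairs. When the full pair list exceeds `max_pairs`, a
#' uniform random subsample of pairs is scored instead (seeded).
#'
#' @param haps A [haplotype_set()].
#' @param window_bp Maximum pair distance (default 1 Mb).
#' @param max_pairs Cap on scored pairs (default 2e5).
#' @param seed Seed for the pair subsample.
#' @return List (`LdSummary`): `population`, `mean_r2`, `median_r2`,
#'   `n_pairs`, `window_bp`, `subsampled`.
#' @export
ld_r2_summary <- function(haps, window_bp = 1e6, max_pairs = 2e5,
                          seed = NULL) {
  stopifnot(inherits(haps, "haplotype_set"))
  dos <- diploid_dosages(haps)
  v <- apply(dos, 2, stats::var)
  poly <- which(v > 0)
  if (length(poly) < 2L) stop("need at least two polymorphic variants")
  dos <- dos[, poly, drop = FALSE]
  pos <- haps$positions[poly]
  m <- length(poly)
  upper <- findInterval(pos + window_bp, pos)
  n_cand <- sum(upper - seq_len(m))
  if (n_cand < 1) stop("no variant pair within ", window_bp, " bp")
  subsampled <- n_cand > max_pairs
  if (subsampled) {
    if (!is.null(seed)) set.seed(seed)
    i <- sample.int(m, 2 * max_pairs, replace = TRUE,
                    prob = pmax(upper - seq_len(m), 0))
    j <- i + 1L + floor(stats::runif(length(i)) *
                          (upper[i] - i))
    ok <- j <= upper[i] & j > i
    i <- i[ok][seq_len(min(max_pairs, sum(ok)))]
    j <- j[ok][seq_len(min(max_pairs, sum(ok)))]
  } else {
    i <- rep.int(seq_len(m), upper - seq_len(m))
    j <- sequence(upper - seq_len(m)) +
      rep.int(seq_len(m), upper - seq_len(m))
  }
  r2 <- vapply(seq_along(i), function(k) {
    stats::cor(dos[, i[k]], dos[, j[k]])^2
  }, 0)
  list(population = haps$population, mean_r2 = mean(r2),
       median_r2 = stats::median(r2), n_pairs = length(r2),
       window_bp = window_bp, subsampled = subsampled)
}
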