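# Independent oracles: deliberately different algorithms/representations
# from the production code paths they check.

# EHH by brute-force pairwise haplotype identity: every ordered carrier
# pair keeps a running "still identical from the core to here" flag (the
# production paths instead use incremental partition refinement).
oracle_ehh_curve <- function(h, pos, core, allele, dir, cutoff = -1) {
  carriers <- which(h[, core] == allele)
  nc <- length(carriers)
  stopifnot(nc >= 2)
  idxs <- if (dir == "left") {
    if (core > 1) rev(seq_len(core - 1)) else integer(0)
  } else {
    if (core < ncol(h)) seq(core + 1, ncol(h)) else integer(0)
  }
  pr <- utils::combn(carriers, 2)
  same <- rep(TRUE, ncol(pr))
  npair <- ncol(pr)
  offs <- 0
  eh <- 1
  for (k in idxs) {
    same <- same & (h[pr[1, ], k] == h[pr[2, ], k])
    e <- 2 * sum(same) / (nc * (nc - 1))
    stopifnot(2 * npair == nc * (nc - 1))
    eh <- c(eh, e)
    offs <- c(offs, pos[k] - pos[core])
    if (e < cutoff) break   # optional truncation for the iHS oracle
  }
  list(offsets = offs, ehh = eh)
}

# trapezoid integral with cutoff handling, on explicit breakpoints
oracle_trapezoid_ihh <- function(offsets, ehh, cutoff = 0.05) {
  d <- abs(offsets)
  ihh <- 0
  truncated <- TRUE
  if (length(d) >= 2) {
    for (k in 2:length(d)) {
      ihh <- ihh + (d[k] - d[k - 1]) * (ehh[k] + ehh[k - 1]) / 2
      if (ehh[k] < cutoff) {
        truncated <- FALSE
        break
      }
    }
  }
  list(ihh = ihh, truncated = truncated)
}

# full unstandardized iHS per variant via the string oracle
oracle_uihs_table <- function(h, pos, maf_min = 0.01, cutoff = 0.05) {
  res <- list()
  for (j in seq_len(ncol(h))) {
    daf <- mean(h[, j])
    if (!(min(daf, 1 - daf) > maf_min)) next
    if (sum(h[, j] == 1) < 2 || sum(h[, j] == 0) < 2) next
    ihh <- c(derived = 0, ancestral = 0)
    for (al in c(1, 0)) {
      for (dir in c("left", "right")) {
        cv <- oracle_ehh_curve(h, pos, j, al, dir, cutoff = cutoff)
        nm <- if (al == 1) "derived" else "ancestral"
        ihh[nm] <- ihh[nm] + oracle_trapezoid_ihh(cv$offsets, cv$ehh,
                                                  cutoff)$ihh
      }
    }
    if (ihh["derived"] <= 0 || ihh["ancestral"] <= 0) next
    res[[length(res) + 1]] <- data.frame(
      index = j, daf = daf,
      uihs = log(ihh[["derived"]] / ihh[["ancestral"]]))
  }
  do.call(rbind, res)
}

# Weir & Cockerham (1984) a, b, c components, transcribed per variant with
# explicit scalar loops over populations
oracle_wc_fst_variant <- function(counts_per_pop) {
  # counts_per_pop: list of genotype vectors (0/1/2) for one variant
  r <- length(counts_per_pop)
  n <- vapply(counts_per_pop, length, 0)
  p <- vapply(counts_per_pop, function(g) sum(g) / (2 * length(g)), 0)
  hobs <- vapply(counts_per_pop, function(g) mean(g == 1), 0)
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * hobs) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# chi-squared from the four observed cells, closed form
oracle_chi2 <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# naive scanning peak caller: walks the track element by element
oracle_call_peaks <- function(pos, score, enter, exit) {
  peaks <- list()
  i <- 1
  n <- length(score)
  while (i <= n) {
    if (score[i] >= exit) {
      j <- i
      while (j < n && score[j + 1] >= exit) j <- j + 1
      m <- max(score[i:j])
      if (m >= enter) {
        peaks[[length(peaks) + 1]] <- data.frame(
          start = pos[i], stop = pos[j], max_z = m,
          n_variants = j - i + 1)
      }
      i <- j + 1
    } else i <- i + 1
  }
  do.call(rbind, peaks)
}

# per-bp membership oracle for interval segmentation on a small chromosome
oracle_bp_membership <- function(intervals, chrom_len) {
  # intervals: data.frame(population, start, stop); returns a list of
  # per-bp character vectors of covering population sets
  cov <- vector("list", chrom_len)
  for (i in seq_len(nrow(intervals))) {
    for (b in intervals$start[i]:intervals$stop[i]) {
      cov[[b]] <- union(cov[[b]], intervals$population[i])
    }
  }
  cov
}

# random haplotype set for property tests
rand_hapset <- function(n_hap = 20, n_var = 30, seed = NULL,
                        chrom_len = 100000) {
  if (!is.null(seed)) set.seed(seed)
  n_hap <- 2L * ceiling(n_hap / 2)   # row count must be even
  pos <- sort(sample.int(chrom_len, n_var))
  h <- matrix(rbinom(n_hap * n_var, 1, runif(n_var, 0.2, 0.8)[
    rep(seq_len(n_var), each = n_hap)]), nrow = n_hap)
  # guarantee polymorphism where possible
  haplotype_set("1", pos, h)
}

# exact one-sided rank-sum p by full enumeration of group assignments
oracle_wilcoxon_exact_greater <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v)
  m <- length(x)
  obs <- sum(rank(all_v)[seq_len(m)])
  combos <- utils::combn(n, m)
  stats <- apply(combos, 2, function(i) sum(rank(all_v)[i]))
  mean(stats >= obs)
}
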