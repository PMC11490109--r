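test_that("colocalization matches exact positions, per tissue and breed", {
  tv <- data.frame(population = c("A", "A", "B"), chrom = "1",
                   pos = c(100, 200, 100), z = c(5, 6, 4.5))
  expect_equal(nrow(colocalize(tv, data.frame(
    evariant_id = character(), chrom = character(), pos = numeric(),
    tissue = character(), egene = character(), slope = numeric()))), 0)
  eq <- data.frame(evariant_id = c("1_100", "1_100", "1_300"), chrom = "1",
                   pos = c(100, 100, 300),
                   tissue = c("liver", "blood", "liver"),
                   egene = c("G1", "G2", "G3"), slope = c(0.5, -1, 2))
  hits <- colocalize(tv, eq)
  # position 100 is top in breeds A and B, eQTL in 2 tissues -> 4 hits
  expect_equal(nrow(hits), 4)
  expect_setequal(unique(hits$tissue), c("liver", "blood"))
  expect_setequal(unique(hits$population), c("A", "B"))
})

test_that("planted exact matches are all recovered, nothing else", {
  set.seed(41)
  pos_v <- sample.int(1e6, 100)
  pos_e <- sample(setdiff(seq_len(1e6), pos_v), 43)
  planted <- sample(pos_v, 7)
  tv <- data.frame(population = "A", chrom = "1", pos = pos_v, z = 5)
  eq <- data.frame(evariant_id = sprintf("e%d", 1:50), chrom = "1",
                   pos = c(pos_e, planted), tissue = "liver",
                   egene = sprintf("G%d", 1:50), slope = 1)
  hits <- colocalize(tv, eq)
  expect_equal(nrow(hits), 7)
  expect_setequal(hits$pos, planted)
})

test_that("signatures covering a whole chromosome give p = 1", {
  sig <- data.frame(chrom = "1", start = 1, stop = 1e5)
  eq <- data.frame(chrom = "1", pos = c(10, 5000, 99999))
  r <- circular_permutation_test(sig, eq, c("1" = 1e5), n_perm = 50,
                                 seed = 1)
  expect_equal(r$observed_overlap, 3)
  expect_equal(r$p_empirical, 1)
  expect_true(is.na(r$z_score))   # zero permutation SD
})

test_that("circular shifts conserve interval count and total length", {
  set.seed(19)
  start <- sort(sample.int(9e4, 8))
  sig <- data.frame(chrom = "1", start = start,
                    stop = pmin(start + sample(500:5000, 8, TRUE), 1e5))
  eq <- data.frame(chrom = "1", pos = sample.int(1e5, 200))
  # validate = TRUE asserts conservation inside the permutation loop
  r <- circular_permutation_test(sig, eq, c("1" = 1e5), n_perm = 200,
                                 seed = 3, validate = TRUE)
  expect_true(r$p_empirical > 0 && r$p_empirical <= 1)
  expect_equal(r$n_perm, 200)
})

test_that("observed overlap equals the per-bp membership oracle", {
  set.seed(29)
  for (rep in 1:3) {
    start <- sort(sample.int(900, 5))
    sig <- data.frame(chrom = "1", population = "A", start = start,
                      stop = pmin(start + sample(20:150, 5, TRUE), 1000))
    eq <- data.frame(chrom = "1", pos = sample.int(1000, 80))
    r <- circular_permutation_test(sig, eq, c("1" = 1000), n_perm = 5,
                                   seed = 1)
    cov <- oracle_bp_membership(sig, 1000)
    want <- sum(vapply(eq$pos, function(p) !is.null(cov[[p]]), TRUE))
    expect_equal(r$observed_overlap, want)
  }
})

test_that("wrapped intervals are split into two arcs at the boundary", {
  shift <- sweepexpress:::shift_intervals_circular
  sh <- shift(start = 90, stop = 110, s = 0, L = 100)
  expect_equal(sh, list(start = c(1, 90), stop = c(10, 100)),
               ignore_attr = TRUE)
  sh2 <- shift(start = 10, stop = 30, s = 85, L = 100)
  expect_equal(sort(sh2$start), c(1, 95))
  expect_equal(sum(sh2$stop - sh2$start + 1), 21)
})

test_that("a monotone |slope|-FST relation gives Spearman rho = 1", {
  fst <- data.frame(chrom = "1", pos = 1:50, global_fst = runif(50))
  eq <- data.frame(evariant_id = sprintf("v%d", 1:50), chrom = "1",
                   pos = 1:50, tissue = "liver", egene = "G",
                   slope = (rank(fst$global_fst))^2 *
                     sample(c(-1, 1), 50, TRUE))
  r <- fst_slope_correlation(fst, eq)
  expect_equal(r$spearman_rho, 1)
  expect_equal(r$rho_p, 0)
})

test_that("Spearman rho is invariant to monotone transforms", {
  set.seed(51)
  fst <- data.frame(chrom = "1", pos = 1:200,
                    global_fst = runif(200))
  eq <- simulate_eqtl_slopes(fst, rho = 0.5, seed = 2)
  r1 <- fst_slope_correlation(fst, eq)
  fst2 <- fst
  fst2$global_fst <- exp(5 * fst2$global_fst)   # strictly monotone
  r2 <- fst_slope_correlation(fst2, eq)
  expect_equal(r1$spearman_rho, r2$spearman_rho, tolerance = 1e-12)
})

test_that("the 390x leave-one-out rule excludes exactly the extreme", {
  fst <- data.frame(chrom = "1", pos = 1:20,
                    global_fst = seq(0.01, 0.4, length.out = 20))
  slopes <- seq(0.9, 1.1, length.out = 20)
  slopes[7] <- 1000    # ~1000x the mean of the others
  eq <- data.frame(evariant_id = sprintf("v%d", 1:20), chrom = "1",
                   pos = 1:20, tissue = "liver", egene = "G",
                   slope = slopes * sample(c(-1, 1), 20, TRUE))
  r <- fst_slope_correlation(fst, eq, outlier_factor = 390)
  expect_equal(r$excluded_outliers, "v7")
  expect_equal(r$n_used, 19)
  # a 300x variant with factor 390 is kept
  eq$slope[7] <- 300
  r2 <- fst_slope_correlation(fst, eq, outlier_factor = 390)
  expect_equal(length(r2$excluded_outliers), 0)
  expect_equal(r2$n_used, 20)
})

test_that("complete 3-vs-7 separation gives the exact enumeration p", {
  fst <- data.frame(chrom = "1", pos = 1:10,
                    global_fst = c(rep(0.1, 7), 0.8, 0.85, 0.9))
  eq <- data.frame(evariant_id = sprintf("v%d", 1:10), chrom = "1",
                   pos = 1:10, tissue = "liver", egene = "G",
                   slope = c(seq(0.1, 0.7, 0.1), 2, 3, 4))
  r <- adaptive_vs_nonadaptive(fst, eq, top_q = 0.3,
                               alternative = "greater")
  expect_equal(r$n_adaptive, 3)
  expect_equal(r$wilcoxon_p, 1 / choose(10, 3), tolerance = 1e-12)
  # full-enumeration oracle agrees
  expect_equal(oracle_wilcoxon_exact_greater(c(2, 3, 4),
                                             seq(0.1, 0.7, 0.1)),
               1 / choose(10, 3))
  expect_gt(r$median_abs_slope_adaptive, r$median_abs_slope_nonadaptive)
})

test_that("adaptive top-quantile default is 1% and split must be proper", {
  expect_equal(formals(adaptive_vs_nonadaptive)$top_q, 0.01)
  fst <- data.frame(chrom = "1", pos = 1:5, global_fst = rep(0.5, 5))
  eq <- data.frame(evariant_id = sprintf("v%d", 1:5), chrom = "1",
                   pos = 1:5, tissue = "liver", egene = "G", slope = 1:5)
  expect_error(suppressWarnings(adaptive_vs_nonadaptive(fst, eq)),
               "degenerate")
})

test_that("planted copula rho is recovered and rho = 1 is exact", {
  set.seed(61)
  fst <- data.frame(chrom = "1", pos = 1:5000, global_fst = runif(5000))
  eq1 <- simulate_eqtl_slopes(fst, rho = 1, seed = 8)
  expect_equal(cor(rank(fst$global_fst), rank(abs(eq1$slope))), 1)
  for (rho in c(0, 0.3, 0.7)) {
    eq <- simulate_eqtl_slopes(fst, rho = rho, seed = 70 + rho * 10)
    est <- fst_slope_correlation(fst, eq)$spearman_rho
    expect_lt(abs(est - rho), 0.05)
  }
  expect_error(simulate_eqtl_slopes(fst, rho = 1.2), "rho")
})
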