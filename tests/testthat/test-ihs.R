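test_that("EHH is 1 everywhere when all carriers are identical", {
  h <- rbind(c(1, 1, 0, 1), c(1, 1, 0, 1), c(1, 1, 0, 1),
             c(0, 0, 1, 0), c(0, 0, 1, 0), c(0, 0, 1, 0))
  hs <- haplotype_set("1", c(100, 200, 300, 400), h)
  cv <- compute_ehh(hs, 2, "derived", "right")
  expect_equal(cv$ehh_values, c(1, 1, 1))
})

test_that("EHH collapses to 0 once two sole carriers differ", {
  h <- rbind(c(1, 0, 1), c(1, 1, 0), c(0, 0, 0), c(0, 0, 0))
  hs <- haplotype_set("1", c(10, 20, 30), h)
  cv <- compute_ehh(hs, 1, "derived", "right")
  expect_equal(cv$ehh_values, c(1, 0, 0))
})

test_that("a 2/2 carrier split gives EHH 2/6 (pairwise identity count)", {
  # 4 derived carriers split into two groups of 2 at the next variant
  h <- rbind(c(1, 0), c(1, 0), c(1, 1), c(1, 1), c(0, 0), c(0, 1))
  hs <- haplotype_set("1", c(100, 200), h)
  cv <- compute_ehh(hs, 1, "derived", "right")
  expect_equal(cv$ehh_values[2], 2 / 6)
  o <- oracle_ehh_curve(h, hs$positions, 1, 1, "right")
  expect_equal(cv$ehh_values, o$ehh)
})

test_that("EHH errors with fewer than 2 carriers", {
  h <- rbind(c(1, 0), c(0, 0), c(0, 1), c(0, 1))
  hs <- haplotype_set("1", c(1, 5), h)
  expect_error(compute_ehh(hs, 1, "derived", "right"), "carry")
})

test_that("compute_ehh matches the string-counting oracle and is monotone", {
  for (s in 1:30) {
    hs <- rand_hapset(n_hap = sample(4:30, 1), n_var = sample(5:50, 1),
                      seed = s)
    h <- hs$haplotypes
    core <- sample(ncol(h), 1)
    for (al in c("derived", "ancestral")) {
      a <- if (al == "derived") 1 else 0
      if (sum(h[, core] == a) < 2) next
      for (dir in c("left", "right")) {
        cv <- compute_ehh(hs, core, al, dir)
        o <- oracle_ehh_curve(h, hs$positions, core, a, dir)
        expect_equal(cv$ehh_values, o$ehh, tolerance = 1e-12)
        expect_true(all(diff(cv$ehh_values) <= 1e-12))
      }
    }
  }
})

test_that("iHH trapezoid integration follows the listed breakpoints", {
  cv <- structure(list(core_index = 1, core_allele = "derived",
                       direction = "right",
                       offsets = c(0, 1000, 2000, 3000),
                       ehh_values = c(1, 1, 1, 0)), class = "ehh_curve")
  r <- compute_ihh(cv, cutoff = 0.05)
  # 1000 + 1000 + 500*(1+0), stopping at the crossing variant
  expect_equal(r$ihh, 2500)
  expect_false(r$truncated)
  o <- oracle_trapezoid_ihh(cv$offsets, cv$ehh_values, 0.05)
  expect_equal(r$ihh, o$ihh)
})

test_that("a curve never crossing the cutoff is flagged truncated", {
  cv <- structure(list(core_index = 1, core_allele = "derived",
                       direction = "right", offsets = c(0, 500, 900),
                       ehh_values = c(1, 0.8, 0.6)), class = "ehh_curve")
  r <- compute_ihh(cv)
  expect_true(r$truncated)
  expect_equal(r$ihh, 500 * 0.9 + 400 * 0.7)
})

test_that("default EHH cutoff is 0.05 and MAF filter is strict", {
  expect_equal(formals(compute_ihh)$cutoff, 0.05)
  expect_equal(formals(compute_ihs_table)$maf_min, 0.01)
  set.seed(8)
  # 40 haplotypes: variant with MAF exactly 0.05 must be excluded at
  # maf_min = 0.05 (strict >) and included at a smaller threshold
  h <- matrix(rbinom(40 * 20, 1, 0.5), nrow = 40)
  h[, 10] <- c(rep(1, 2), rep(0, 38))           # MAF = 0.05
  hs <- haplotype_set("1", sort(sample.int(1e5, 20)), h)
  t_strict <- compute_ihs_table(hs, maf_min = 0.05)
  expect_false(10 %in% t_strict$index)
  t_loose <- compute_ihs_table(hs, maf_min = 0.04)
  # may still be dropped for < 2 carriers? count is 2, so it is scored
  expect_true(10 %in% t_loose$index)
})

test_that("mirror-symmetric backgrounds give uihs = 0", {
  flank <- rbind(c(0, 1), c(1, 0), c(1, 1))
  h <- cbind(rbind(flank, flank),
             c(1, 1, 1, 0, 0, 0),
             rbind(flank, flank))
  hs <- haplotype_set("1", c(100, 200, 300, 400, 500), h)
  tab <- compute_ihs_table(hs, maf_min = 0.01)
  row <- tab[tab$index == 3, ]
  expect_equal(row$uihs, 0)
})

test_that("flipping all allele labels negates uihs", {
  hs <- rand_hapset(n_hap = 24, n_var = 40, seed = 99)
  tab <- compute_ihs_table(hs, maf_min = 0.01)
  hs_flip <- haplotype_set(hs$chrom, hs$positions, 1L - hs$haplotypes)
  tab_flip <- compute_ihs_table(hs_flip, maf_min = 0.01)
  shared <- intersect(tab$index, tab_flip$index)
  expect_gt(length(shared), 0)
  expect_equal(tab_flip$uihs[match(shared, tab_flip$index)],
               -tab$uihs[match(shared, tab$index)], tolerance = 1e-12)
})

test_that("production iHS equals the oracle on a small simulation", {
  cfg <- sim_config(n_populations = 1, haplotypes_per_population = 30,
                    n_sites = 120, chrom_length_bp = 3e5, seed = 17)
  hs <- simulate_neutral_haplotypes(cfg)[[1]]
  tab <- compute_ihs_table(hs)
  o <- oracle_uihs_table(hs$haplotypes, hs$positions)
  expect_equal(tab$index, o$index)
  expect_equal(tab$uihs, o$uihs, tolerance = 1e-9)
})

test_that("bin standardization uses the sample SD and drops flat bins", {
  a <- 0.8
  tab <- data.frame(daf = c(0.11, 0.115, 0.51, 0.515, 0.52),
                    uihs = c(a, -a, 2, 2, 2))
  suppressMessages(z <- standardize_ihs(tab, n_bins = 50))
  # bin {a, -a}: mean 0, sample SD sqrt(2)*a, so z = +-1/sqrt(2)
  expect_equal(sort(z$z), c(-1, 1) / sqrt(2))
  # the constant bin (SD = 0) is dropped entirely
  expect_false(any(z$daf > 0.5))
  expect_equal(attr(z, "dropped_bins")$n_variants_dropped, 3)
})

test_that("standardization errors when every bin is degenerate", {
  tab <- data.frame(daf = c(0.3, 0.5), uihs = c(1, 1))
  expect_error(standardize_ihs(tab), "degenerate")
})
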