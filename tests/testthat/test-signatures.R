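test_that("peak runs follow the enter/exit construction on the toy track", {
  tr <- data.frame(chrom = "1", pos = 1:7 * 100,
                   z = c(0.1, 3.6, 4.2, 3.7, 3.4, 5.0, 3.2))
  p <- call_peaks(tr, enter = 4, exit = 3.5)
  expect_equal(nrow(p), 2)
  expect_equal(p$start, c(200, 600))
  expect_equal(p$stop, c(400, 600))
  expect_equal(p$max_z, c(4.2, 5.0))
  expect_equal(p$n_variants, c(3, 1))
})

test_that("runs peaking below the enter threshold are rejected", {
  tr <- data.frame(chrom = "1", pos = 1:4 * 10, z = c(3.6, 3.9, 3.7, 1))
  expect_equal(nrow(call_peaks(tr, enter = 4, exit = 3.5)), 0)
  expect_equal(nrow(call_peaks(tr, enter = 3.9, exit = 3.5)), 1)
})

test_that("all-subthreshold tracks yield no peaks; unsorted input errors", {
  tr <- data.frame(chrom = "1", pos = 1:5, z = rep(1, 5))
  expect_equal(nrow(call_peaks(tr)), 0)
  tr2 <- data.frame(chrom = "1", pos = c(3, 1, 2), z = c(5, 5, 5))
  expect_error(call_peaks(tr2), "sorted")
})

test_that("peak caller uses |z| by default, signed z on request", {
  tr <- data.frame(chrom = "1", pos = 1:3 * 10, z = c(0, -4.5, 0))
  expect_equal(nrow(call_peaks(tr)), 1)
  expect_equal(nrow(call_peaks(tr, use_abs = FALSE)), 0)
})

test_that("peak caller matches the naive scanning oracle on random tracks", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    z <- rnorm(n, 0, 2)
    # salt in threshold-straddling values, ties and boundary runs
    z[sample(n, min(n, 6))] <- sample(c(3.5, 4.0, 4.2, 3.49, 5, -4.1), 6,
                                      replace = TRUE)[seq_len(min(n, 6))]
    tr <- data.frame(chrom = "1", pos = sort(sample.int(1e5, n)), z = z)
    got <- call_peaks(tr)
    want <- oracle_call_peaks(tr$pos, abs(tr$z), 4, 3.5)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[c("start", "stop", "max_z", "n_variants")],
                   want, ignore_attr = TRUE)
    }
  }
})

test_that("top-quantile threshold is the min of the ceil(qn) largest", {
  set.seed(2)
  z <- rnorm(20000)
  expect_equal(top_quantile_threshold(z, 1e-4),
               sort(z, decreasing = TRUE)[2])
  expect_equal(suppressWarnings(top_quantile_threshold(rep(3, 50), 1e-4)),
               3)
  expect_warning(top_quantile_threshold(1:10, 1e-4), "maximum")
  expect_error(top_quantile_threshold(numeric(0)), "empty")
})

test_that("signature validation is strict by default", {
  peaks <- data.frame(chrom = "1", start = c(1, 100), stop = c(50, 150),
                      max_z = c(5, 4.2), n_variants = c(3, 2))
  ss <- validate_signatures(peaks, threshold = 4.2, population = "A")
  expect_equal(nrow(ss$peaks), 1)   # equal-to-threshold peak dropped
  expect_equal(ss$peaks$max_z, 5)
  ss2 <- validate_signatures(peaks, 4.2, "A", strict = FALSE)
  expect_equal(nrow(ss2$peaks), 2)
  empty <- validate_signatures(peaks[0, ], 4.2, "A")
  expect_equal(empty$summary$n, 0)
})

sigset <- function(pop, start, stop, chrom = "1") {
  validate_signatures(
    data.frame(chrom = chrom, start = start, stop = stop,
               max_z = rep(9, length(start)),
               n_variants = rep(2, length(start))),
    threshold = 1, population = pop)
}

test_that("two-population intersection segments match the worked example", {
  seg <- multi_population_intersections(list(sigset("A", 100, 200),
                                             sigset("B", 150, 250)))
  expect_equal(seg$start, c(100, 150, 201))
  expect_equal(seg$stop, c(149, 200, 250))
  expect_equal(seg$populations, c("A", "A,B", "B"))
})

test_that("single population and disjoint cases behave as identities", {
  one <- multi_population_intersections(list(sigset("A", c(10, 500),
                                                    c(100, 600))))
  expect_equal(one$start, c(10, 500))
  expect_equal(one$populations, c("A", "A"))
  dis <- multi_population_intersections(list(sigset("A", 10, 100),
                                             sigset("B", 500, 600)))
  expect_true(all(dis$n_pops == 1))
})

test_that("segmentation membership is exact against the per-bp oracle", {
  set.seed(31)
  for (rep in 1:5) {
    pops <- LETTERS[1:3]
    ivs <- do.call(rbind, lapply(pops, function(p) {
      n <- sample(1:4, 1)
      start <- sort(sample.int(900, n))
      data.frame(population = p, start = start,
                 stop = pmin(start + sample(10:200, n, replace = TRUE),
                             1000))
    }))
    sets <- lapply(pops, function(p) {
      d <- ivs[ivs$population == p, ]
      sigset(p, d$start, d$stop)
    })
    suppressMessages(seg <- multi_population_intersections(sets))
    cov <- oracle_bp_membership(ivs, 1000)
    # every covered bp is in exactly one segment with the exact label set
    for (b in 1:1000) {
      inseg <- which(seg$start <= b & seg$stop >= b)
      if (is.null(cov[[b]])) {
        expect_equal(length(inseg), 0)
      } else {
        expect_equal(length(inseg), 1)
        expect_equal(strsplit(seg$populations[inseg], ",")[[1]],
                     sort(cov[[b]]))
      }
    }
  }
})

test_that("region grouping respects the 50-kb gap boundary exactly", {
  seg <- function(s1, s2) data.frame(
    chrom = "1", start = c(1, s2), stop = c(s1, s2 + 10),
    populations = c("A", "B"), n_pops = 1L, n_signatures = 1L)
  # gap of 49,999 bp chains; 50,001 bp does not
  r1 <- merge_into_regions(seg(1000, 1000 + 50000), gap = 50000)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$member_populations, "A,B")
  r2 <- merge_into_regions(seg(1000, 1000 + 50002), gap = 50000)
  expect_equal(nrow(r2), 2)
  # exactly 50,000 chains too (<=)
  r3 <- merge_into_regions(seg(1000, 1000 + 50001), gap = 50000)
  expect_equal(nrow(r3), 1)
  expect_equal(formals(merge_into_regions)$gap, 50000)
})

test_that("region grouping is idempotent and input-order invariant", {
  set.seed(5)
  start <- sort(sample.int(1e6, 12))
  segs <- data.frame(chrom = "1", start = start, stop = start + 5000,
                     populations = sample(c("A", "B", "A,B"), 12, TRUE),
                     n_pops = 1L, n_signatures = 1L)
  r <- merge_into_regions(segs)
  shuffled <- segs[sample(nrow(segs)), ]
  expect_equal(merge_into_regions(shuffled), r)
  # re-merging the regions themselves changes nothing
  r2 <- merge_into_regions(data.frame(
    chrom = r$chrom, start = r$start, stop = r$stop,
    populations = r$member_populations, n_pops = r$n_pops,
    n_signatures = r$n_signatures))
  expect_equal(r2[c("chrom", "start", "stop", "member_populations")],
               r[c("chrom", "start", "stop", "member_populations")])
})

test_that("exclusive/common classification follows membership", {
  seg <- data.frame(chrom = "1", start = c(1, 2e5), stop = c(100, 2e5 + 9),
                    populations = c("A", "A,B"), n_pops = c(1L, 2L),
                    n_signatures = c(1L, 2L))
  r <- merge_into_regions(seg)
  expect_equal(r$classification, c("exclusive", "common"))
})

test_that("gene overlap is 1-based inclusive: abutting is not overlap", {
  regions <- merge_into_regions(data.frame(
    chrom = "1", start = 1000, stop = 2000, populations = "A",
    n_pops = 1L, n_signatures = 1L))
  genes <- data.frame(gene_id = c("left", "touch", "inside"),
                      chrom = "1", start = c(500, 900, 2000),
                      stop = c(999, 1000, 2500))
  ann <- annotate_genes(regions, genes)
  expect_equal(sort(strsplit(ann$genes, ",")[[1]]), c("inside", "touch"))
})

test_that("chromosome name mismatch errors name the offending labels", {
  regions <- merge_into_regions(data.frame(
    chrom = "chr1", start = 1, stop = 10, populations = "A",
    n_pops = 1L, n_signatures = 1L))
  genes <- data.frame(gene_id = "g", chrom = "1", start = 1, stop = 5)
  expect_error(annotate_genes(regions, genes), "chr1")
})

test_that("QTL overlap pairs and trait-class tallies match enumeration", {
  sets <- list(sigset("A", c(100, 5000, 9000), c(200, 5100, 9050)),
               sigset("B", c(150, 7000), c(260, 7500)))
  qtl <- data.frame(
    qtl_id = sprintf("Q%d", 1:6), chrom = "1",
    start = c(150, 190, 5050, 6000, 7400, 9051),
    stop = c(160, 400, 5600, 6500, 8000, 9500),
    trait_name = "t",
    trait_class = c("milk", "milk", "reproduction", "health",
                    "meat and carcass", "exterior"))
  res <- annotate_qtl(sets, qtl)
  # brute-force enumeration of all (signature, QTL) pairs
  sigs <- rbind(data.frame(p = "A", s = c(100, 5000, 9000),
                           e = c(200, 5100, 9050)),
                data.frame(p = "B", s = c(150, 7000), e = c(260, 7500)))
  want <- 0
  for (i in seq_len(nrow(sigs))) for (j in 1:6) {
    if (sigs$s[i] <= qtl$stop[j] && sigs$e[i] >= qtl$start[j]) {
      want <- want + 1
    }
  }
  expect_equal(nrow(res$pairs), want)
  expect_equal(sum(res$trait_class_counts), want)
  # Q6 abuts signature 9000-9050 (starts at 9051): no overlap
  expect_false("Q6" %in% res$pairs$qtl_id)
  # per-class check for population A
  a_counts <- res$trait_class_counts["A", ]
  expect_equal(a_counts[["milk"]], 2)
  expect_equal(a_counts[["reproduction"]], 1)
})
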