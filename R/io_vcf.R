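#' Read phased biallelic genotypes from a VCF file
#'
#' Parses a VCF with phased `GT` fields (separator `|`) into one
#' [haplotype_set()] per chromosome, recoding alleles so that 0 is the
#' ancestral and 1 the derived allele.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param ancestral Polarization policy: `"ref"` treats the REF allele as
#'   ancestral; `"aa"` uses the `INFO/AA` tag (an error if the tag is absent
#'   for any record).
#' @param population Population (breed) label attached to the output.
#' @param drop_missing Variants with any missing genotype are dropped with a
#'   logged count (`attr(,"n_dropped_missing")`); the iHS machinery requires
#'   complete data. If `FALSE`, missingness is an error.
#' @return Named list of `haplotype_set`, one per chromosome.
#' @export
read_phased_vcf <- function(path, ancestral = c("ref", "aa"),
                            population = NA_character_, drop_missing = TRUE) {
  ancestral <- match.arg(ancestral)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  n_var <- nrow(gt)
  if (n_var == 0L) stop("no variant records in ", path)
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) {
    bad <- which(grepl(",", alt, fixed = TRUE))[1]
    stop("multi-allelic record at ", fix[bad, "CHROM"], ":", fix[bad, "POS"],
         "; apply QC (biallelic filter) first")
  }
  miss <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  unphased <- !miss & !grepl("^[01]\\|[01]$", gt)
  if (any(unphased)) {
    bad <- which(rowSums(unphased) > 0)[1]
    stop("unphased or malformed genotype at record ", fix[bad, "CHROM"], ":",
         fix[bad, "POS"], " (GT '", gt[unphased][1],
         "'); phased input with '|' separator is required")
  }
  has_missing <- rowSums(miss) > 0
  n_dropped <- sum(has_missing)
  if (n_dropped > 0L) {
    if (!drop_missing) stop(n_dropped, " records carry missing genotypes")
    message("dropping ", n_dropped, " variants with missing genotypes")
    gt <- gt[!has_missing, , drop = FALSE]
    fix <- fix[!has_missing, , drop = FALSE]
  }
  if (nrow(gt) == 0L) stop("no complete phased records left in ", path)

  swap <- rep(FALSE, nrow(gt))
  if (ancestral == "aa") {
    aa <- vcfR::extract.info(vcf, element = "AA")
    if (n_dropped > 0L) aa <- aa[!has_missing]
    if (anyNA(aa) || any(!nzchar(aa))) {
      stop("ancestral policy 'aa' requested but INFO/AA is absent for ",
           sum(is.na(aa) | !nzchar(aa)), " records")
    }
    ref <- fix[, "REF"]; altk <- fix[, "ALT"]
    known <- toupper(aa) == toupper(ref) | toupper(aa) == toupper(altk)
    if (!all(known)) {
      stop("INFO/AA matches neither REF nor ALT for ", sum(!known), " records")
    }
    swap <- toupper(aa) == toupper(altk) # ALT is ancestral -> flip coding
  }

  a1 <- substr(gt, 1L, 1L) == "1"
  a2 <- substr(gt, 3L, 3L) == "1"
  n_hap <- 2L * ncol(gt)
  out <- list()
  for (chr in unique(fix[, "CHROM"])) {
    rows <- which(fix[, "CHROM"] == chr)
    pos <- as.numeric(fix[rows, "POS"])
    o <- order(pos)
    rows <- rows[o]; pos <- pos[o]
    if (anyDuplicated(pos)) stop("duplicated positions on ", chr)
    h <- matrix(0L, nrow = n_hap, ncol = length(rows))
    odd <- seq(1L, n_hap, by = 2L)
    h[odd, ] <- t(a1[rows, , drop = FALSE]) + 0L
    h[odd + 1L, ] <- t(a2[rows, , drop = FALSE]) + 0L
    flip <- swap[rows]
    if (any(flip)) h[, flip] <- 1L - h[, flip]
    out[[chr]] <- haplotype_set(
      chrom = chr, positions = pos, haplotypes = h,
      sample_ids = colnames(gt), population = population,
      ancestral_policy = ancestral)
  }
  attr(out, "n_dropped_missing") <- n_dropped
  out
}

#' Write a haplotype set as a phased VCF
#'
#' Emits a minimal VCF 4.2 with phased `GT` columns. Coding follows the
#' stored polarity: REF = ancestral (0), ALT = derived (1); an `INFO/AA`
#' field records the ancestral allele explicitly.
#'
#' @param haps A `haplotype_set` or list of them (one per chromosome).
#' @param path Output path (plain text).
#' @param ref,alt Allele symbols to write (defaults `A` ancestral,
#'   `G` derived).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(haps, path, ref = "A", alt = "G") {
  if (inherits(haps, "haplotype_set")) haps <- list(haps)
  con <- file(path, "w")
  on.exit(close(con))
  ids <- haps[[1]]$sample_ids
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=sweepexpress",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")), con)
  for (hs in haps) {
    h <- hs$haplotypes
    odd <- seq(1L, nrow(h), by = 2L)
    gt_mat <- matrix(paste0(t(h[odd, , drop = FALSE]), "|",
                            t(h[odd + 1L, , drop = FALSE])),
                     nrow = ncol(h))
    lines <- paste(hs$chrom, format(hs$positions, scientific = FALSE,
                                    trim = TRUE),
                   sprintf("%s_%s", hs$chrom,
                           format(hs$positions, scientific = FALSE,
                                  trim = TRUE)),
                   ref, alt, ".", "PASS", paste0("AA=", ref), "GT",
                   apply(gt_mat, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Apply variant and sample quality control to a VCF
#'
#' Filters, in this fixed order: (1) keep biallelic SNPs; (2) mask
#' genotypes failing the quality rule, then keep variants with call rate
#' >= `min_var_call_rate` (inclusive); (3) drop samples with call rate <
#' `min_sample_call_rate`. The quality rule keeps genotypes with
#' `FORMAT/GQ > min_gq` (`gq_mode = "genotype"`, the default) or records
#' with site `QUAL > min_gq` (`gq_mode = "site"`).
#'
#' @param vcf A `vcfR` object (from [vcfR::read.vcfR()]).
#' @param min_var_call_rate Minimum variant call rate (kept if `>=`).
#' @param min_gq Genotype-quality threshold (kept if strictly `>`).
#' @param min_sample_call_rate Samples below this call rate are dropped.
#' @param gq_mode `"genotype"` (per-genotype GQ) or `"site"` (QUAL).
#' @return List with the filtered `vcf` and a `report` list counting
#'   removals per filter.
#' @export
apply_qc <- function(vcf, min_var_call_rate = 0.95, min_gq = 20,
                     min_sample_call_rate = 0.75,
                     gq_mode = c("genotype", "site")) {
  gq_mode <- match.arg(gq_mode)
  stopifnot(inherits(vcf, "vcfR"))
  fix <- vcf@fix
  n_var0 <- nrow(fix)
  n_smp0 <- ncol(vcf@gt) - 1L

  base <- c("A", "C", "G", "T")
  biallelic <- !grepl(",", fix[, "ALT"], fixed = TRUE) &
    toupper(fix[, "REF"]) %in% base & toupper(fix[, "ALT"]) %in% base
  n_not_biallelic <- sum(!biallelic)
  vcf <- vcf[biallelic, ]

  gt <- vcfR::extract.gt(vcf, element = "GT")
  miss <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  n_low_qual <- 0L
  has_gq <- nrow(vcf@gt) > 0 && any(grepl("GQ", vcf@gt[, "FORMAT"]))
  if (gq_mode == "genotype" && has_gq) {
    gq <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ",
                                            as.numeric = TRUE))
    if (!is.null(gq) && !all(is.na(gq))) {
      lowq <- !is.na(gq) & gq <= min_gq
      miss <- miss | lowq
    }
  } else if (gq_mode == "site") {
    qual <- suppressWarnings(as.numeric(vcf@fix[, "QUAL"]))
    lowq_var <- !is.na(qual) & qual <= min_gq
    n_low_qual <- sum(lowq_var)
    vcf <- vcf[!lowq_var, ]
    miss <- miss[!lowq_var, , drop = FALSE]
  }
  call_rate <- 1 - rowMeans(miss)
  keep_var <- call_rate >= min_var_call_rate
  n_low_call <- sum(!keep_var)
  vcf <- vcf[keep_var, ]
  miss <- miss[keep_var, , drop = FALSE]

  sample_cr <- 1 - colMeans(miss)
  keep_smp <- sample_cr >= min_sample_call_rate
  n_smp_drop <- sum(!keep_smp)
  if (n_smp_drop > 0L) {
    vcf@gt <- vcf@gt[, c(TRUE, keep_smp), drop = FALSE]
  }

  report <- list(
    n_variants_in = n_var0, n_samples_in = n_smp0,
    removed_not_biallelic_snp = n_not_biallelic,
    removed_low_site_quality = n_low_qual,
    removed_low_variant_call_rate = n_low_call,
    removed_samples_low_call_rate = n_smp_drop,
    gq_mode = gq_mode,
    n_variants_out = nrow(vcf@fix), n_samples_out = sum(keep_smp))
  if (report$n_variants_out == 0L) {
    warning("all variants removed by QC filters")
  }
  list(vcf = vcf, report = report)
}

#' Write a QC report as JSON
#' @param report The `report` element returned by [apply_qc()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
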