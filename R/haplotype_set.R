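#' Phased haplotype matrix for one chromosome
#'
#' Container for a set of phased haplotypes: a 0/1 matrix with one row per
#' haplotype and one column per variant, where 0 codes the ancestral and 1
#' the derived allele. Consecutive row pairs (1,2), (3,4), ... belong to the
#' same diploid sample.
#'
#' @param chrom Chromosome label (single string).
#' @param positions Integer-ish vector of 1-based base-pair coordinates,
#'   strictly increasing, one per variant.
#' @param haplotypes Matrix of 0/1 with `length(positions)` columns and an
#'   even number of rows.
#' @param sample_ids Optional character vector, one id per pair of rows.
#' @param population Population (breed) label.
#' @param ancestral_policy How polarity was assigned (`"ref"` or `"aa"`);
#'   recorded as metadata.
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(chrom, positions, haplotypes, sample_ids = NULL,
                          population = NA_character_,
                          ancestral_policy = "ref") {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  positions <- as.numeric(positions)
  if (length(chrom) != 1L) stop("`chrom` must be a single label")
  if (ncol(haplotypes) != length(positions)) {
    stop("haplotype column count (", ncol(haplotypes),
         ") must equal number of positions (", length(positions), ")")
  }
  if (nrow(haplotypes) %% 2L != 0L) {
    stop("haplotype row count must be even (two haplotypes per diploid)")
  }
  if (length(positions) > 1L && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing")
  }
  if (length(positions) && any(positions < 1)) {
    stop("positions must be >= 1 (1-based coordinates)")
  }
  if (anyNA(haplotypes) || !all(haplotypes %in% c(0L, 1L))) {
    stop("haplotype entries must all be 0 or 1 (no missing data)")
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("sample%d", seq_len(nrow(haplotypes) %/% 2L))
  }
  if (length(sample_ids) != nrow(haplotypes) %/% 2L) {
    stop("need one sample id per pair of haplotype rows")
  }
  structure(
    list(chrom = as.character(chrom), positions = positions,
         haplotypes = haplotypes, sample_ids = as.character(sample_ids),
         population = as.character(population),
         ancestral_policy = ancestral_policy),
    class = "haplotype_set")
}

#' @method print haplotype_set
#' @export
print.haplotype_set <- function(x, ...) {
  cat("<haplotype_set> population:", x$population,
      " chrom:", x$chrom, "\n")
  cat("  ", nrow(x$haplotypes), "haplotypes (",
      nrow(x$haplotypes) %/% 2L, "diploids ) x",
      ncol(x$haplotypes), "variants\n")
  if (length(x$positions)) {
    cat("   span:", format(min(x$positions), big.mark = ","), "-",
        format(max(x$positions), big.mark = ","), "bp\n")
  }
  invisible(x)
}

#' Derived allele frequency per variant
#' @param haps A `haplotype_set`.
#' @return Numeric vector of derived allele frequencies.
#' @export
derived_freq <- function(haps) {
  stopifnot(inherits(haps, "haplotype_set"))
  colMeans(haps$haplotypes)
}

#' Diploid dosage matrix (0/1/2) from consecutive haplotype pairs
#' @param haps A `haplotype_set`.
#' @return Integer matrix, samples x variants.
#' @export
diploid_dosages <- function(haps) {
  stopifnot(inherits(haps, "haplotype_set"))
  h <- haps$haplotypes
  odd <- seq(1L, nrow(h), by = 2L)
  d <- h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE]
  rownames(d) <- haps$sample_ids
  d
}
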