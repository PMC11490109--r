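#' Extended haplotype homozygosity from a core variant
#'
#' EHH at a variant k (moving away from the core in one direction) is the
#' probability that two randomly drawn core-allele carriers are identical
#' at every variant from the core out to k:
#' `EHH = sum_h n_h (n_h - 1) / (n_c (n_c - 1))` over the distinct extended
#' haplotypes h among the `n_c` carriers. The curve starts at 1 at the core
#' and is evaluated at variant positions only.
#'
#' @param haps A [haplotype_set()].
#' @param core_index Column index of the core variant.
#' @param core_allele `"derived"` (1) or `"ancestral"` (0).
#' @param direction `"left"` or `"right"`.
#' @return An `ehh_curve` object: list with `core_index`, `core_allele`,
#'   `offsets` (signed bp distances from the core, starting at 0) and
#'   `ehh_values`.
#' @export
compute_ehh <- function(haps, core_index,
                        core_allele = c("derived", "ancestral"),
                        direction = c("left", "right")) {
  stopifnot(inherits(haps, "haplotype_set"))
  core_allele <- match.arg(core_allele)
  direction <- match.arg(direction)
  h <- haps$haplotypes
  pos <- haps$positions
  allele <- if (core_allele == "derived") 1L else 0L
  carriers <- which(h[, core_index] == allele)
  nc <- length(carriers)
  if (nc < 2L) {
    stop("EHH undefined: only ", nc, " haplotype(s) carry the ",
         core_allele, " allele at variant ", core_index)
  }
  step <- if (direction == "left") -1L else 1L
  idx <- core_index
  denom <- nc * (nc - 1)
  offsets <- 0
  ehh <- 1
  groups <- list(carriers)
  while (idx + step >= 1L && idx + step <= ncol(h)) {
    idx <- idx + step
    a <- h[, idx]
    nxt <- list()
    pairs <- 0
    for (g in groups) {
      ones <- g[a[g] == 1L]
      zeros <- g[a[g] == 0L]
      if (length(ones) >= 2L) {
        pairs <- pairs + length(ones) * (length(ones) - 1)
        nxt[[length(nxt) + 1L]] <- ones
      }
      if (length(zeros) >= 2L) {
        pairs <- pairs + length(zeros) * (length(zeros) - 1)
        nxt[[length(nxt) + 1L]] <- zeros
      }
    }
    groups <- nxt
    offsets <- c(offsets, pos[idx] - pos[core_index])
    ehh <- c(ehh, pairs / denom)
  }
  structure(list(core_index = core_index, core_allele = core_allele,
                 direction = direction, offsets = offsets,
                 ehh_values = ehh),
            class = "ehh_curve")
}

#' Integrated EHH of one curve
#'
#' Trapezoidal integral of EHH over physical distance from the core
#' outward, accumulated until the first variant where EHH drops below
#' `cutoff`; the segment ending at that crossing variant is included. If
#' the curve reaches the data boundary before crossing, the full integral
#' is returned with `truncated = TRUE`.
#'
#' @param curve An `ehh_curve` from [compute_ehh()].
#' @param cutoff EHH cutoff (default 0.05).
#' @return List with `ihh` (bp units) and `truncated`.
#' @export
compute_ihh <- function(curve, cutoff = 0.05) {
  stopifnot(inherits(curve, "ehh_curve"))
  d <- abs(curve$offsets)
  e <- curve$ehh_values
  ihh <- 0
  truncated <- TRUE
  if (length(d) >= 2L) {
    for (k in 2:length(d)) {
      ihh <- ihh + (d[k] - d[k - 1]) * (e[k] + e[k - 1]) / 2
      if (e[k] < cutoff) {
        truncated <- FALSE
        break
      }
    }
  }
  list(ihh = ihh, truncated = truncated)
}

#' Per-variant unstandardized iHS table
#'
#' For every variant with minor allele frequency strictly above `maf_min`,
#' integrates EHH on the derived and ancestral backgrounds (left + right,
#' cutoff `cutoff`) and reports `uihs = ln(iHH_derived / iHH_ancestral)`.
#' Variants where either background has fewer than 2 carriers or a zero
#' integral are dropped; the dropped indices and reasons are attached as
#' `attr(, "dropped")`.
#'
#' @param haps A [haplotype_set()] with complete phased data.
#' @param maf_min MAF threshold (strict `>`; default 0.01).
#' @param cutoff EHH integration cutoff (default 0.05).
#' @return data.frame with columns `chrom`, `pos`, `daf`, `ihh_derived`,
#'   `ihh_ancestral`, `uihs`, `truncated`.
#' @export
compute_ihs_table <- function(haps, maf_min = 0.01, cutoff = 0.05) {
  stopifnot(inherits(haps, "haplotype_set"))
  scan <- ihs_scan_cpp(t(haps$haplotypes), haps$positions, maf_min, cutoff)
  if (!length(scan$index)) {
    stop("no variant passed the MAF/carrier filters; nothing to score")
  }
  out <- data.frame(
    chrom = haps$chrom, pos = haps$positions[scan$index],
    index = scan$index, daf = scan$daf,
    ihh_derived = scan$ihh_derived, ihh_ancestral = scan$ihh_ancestral,
    uihs = log(scan$ihh_derived / scan$ihh_ancestral),
    truncated = as.logical(scan$truncated), stringsAsFactors = FALSE)
  if (length(scan$dropped_index)) {
    attr(out, "dropped") <- data.frame(
      index = scan$dropped_index,
      reason = c("fewer_than_2_carriers",
                 "zero_integral")[scan$dropped_code])
  }
  out
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Following the usual standardization, variants are binned by derived
#' allele frequency into `n_bins` equal-width bins on (0, 1) and
#' `z = (uihs - bin mean) / bin SD` with the sample SD. Bins with fewer
#' than 2 variants or zero SD cannot be standardized; their variants are
#' dropped and recorded in `attr(, "dropped_bins")`.
#'
#' @param table An iHS table from [compute_ihs_table()].
#' @param n_bins Number of frequency bins (default 50, width 0.02).
#' @return The table restricted to standardizable variants, with a `z`
#'   column appended.
#' @export
standardize_ihs <- function(table, n_bins = 50) {
  stopifnot(is.data.frame(table), all(c("daf", "uihs") %in% names(table)))
  bin <- pmin(pmax(ceiling(table$daf * n_bins), 1L), n_bins)
  mu <- tapply(table$uihs, bin, mean)
  sdv <- tapply(table$uihs, bin, stats::sd)
  nb <- tapply(table$uihs, bin, length)
  ok_bin <- !is.na(sdv) & sdv > 0 & nb >= 2
  if (!any(ok_bin)) stop("all frequency bins are degenerate (SD = 0 or < 2 ",
                         "variants); cannot standardize")
  key <- as.character(bin)
  keep <- ok_bin[key]
  out <- table[keep, , drop = FALSE]
  out$z <- as.numeric((out$uihs - mu[key[keep]]) / sdv[key[keep]])
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    attr(out, "dropped_bins") <- list(
      n_variants_dropped = n_drop,
      bins = as.integer(names(ok_bin)[!ok_bin]))
    message("dropped ", n_drop, " variants in ", sum(!ok_bin),
            " degenerate frequency bins")
  }
  rownames(out) <- NULL
  out
}

#' Write an iHS table as TSV
#' @param table A (standardized) iHS table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ihs_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
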