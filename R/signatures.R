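#' Call candidate peaks on a per-variant z-score track
#'
#' Two-threshold peak construction: candidate runs are maximal consecutive
#' stretches of variants whose score stays at or above `exit`; a run
#' becomes a peak iff its maximum score reaches `enter`. Peak bounds are
#' the positions of the first and last variant of the run. By default the
#' score is `|z|` (iHS is signed, but sweeps are flagged by extreme values
#' of either sign).
#'
#' @param z_track data.frame with `chrom`, `pos`, `z`, sorted by position,
#'   one chromosome at a time.
#' @param enter Peak threshold the run maximum must reach (default 4.0).
#' @param exit Run-membership threshold (default 3.5).
#' @param use_abs Score with `|z|` (default) or signed `z`.
#' @return data.frame of peaks: `chrom`, `start`, `stop`, `max_z`,
#'   `n_variants`.
#' @export
call_peaks <- function(z_track, enter = 4.0, exit = 3.5, use_abs = TRUE) {
  stopifnot(all(c("chrom", "pos", "z") %in% names(z_track)))
  if (length(unique(z_track$chrom)) > 1L) {
    stop("call_peaks works on one chromosome at a time")
  }
  if (is.unsorted(z_track$pos, strictly = TRUE)) {
    stop("z track must be sorted by position")
  }
  if (exit > enter) stop("exit threshold must not exceed enter threshold")
  score <- if (use_abs) abs(z_track$z) else z_track$z
  in_run <- score >= exit
  if (!any(in_run)) {
    return(data.frame(chrom = character(), start = numeric(),
                      stop = numeric(), max_z = numeric(),
                      n_variants = integer()))
  }
  r <- rle(in_run)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- lapply(runs, function(k) {
    i <- starts[k]:ends[k]
    m <- max(score[i])
    if (m < enter) return(NULL)
    data.frame(chrom = z_track$chrom[1], start = z_track$pos[i[1]],
               stop = z_track$pos[i[length(i)]], max_z = m,
               n_variants = length(i))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(chrom = character(),
                                      start = numeric(), stop = numeric(),
                                      max_z = numeric(),
                                      n_variants = integer())
  rownames(out) <- NULL
  out
}

#' Minimum score among the top quantile of a score vector
#'
#' The validation threshold is the minimum among the `ceiling(q * n)`
#' largest scores (the "top 0.01\%" rule at the default `q`).
#'
#' @param z_values Numeric scores (typically `|z|`).
#' @param q Upper-tail fraction (default 1e-4, i.e. 0.01\%).
#' @return The threshold value.
#' @export
top_quantile_threshold <- function(z_values, q = 1e-4) {
  if (!length(z_values)) stop("empty score vector")
  n <- length(z_values)
  k <- ceiling(q * n)
  if (n < 1 / q) {
    warning("fewer than 1/q = ", format(1 / q), " values; threshold is the ",
            "maximum score")
  }
  sort(z_values, decreasing = TRUE)[k]
}

#' Validate peaks against the top-quantile threshold
#'
#' A peak is a selection signature iff its maximum score exceeds the
#' population's top-0.01\% threshold (strict `>` by default, per the
#' two-step rule; set `strict = FALSE` for `>=`).
#'
#' @param peaks Peaks from [call_peaks()].
#' @param threshold From [top_quantile_threshold()].
#' @param population Population label recorded in the output.
#' @param strict Use strict inequality (default `TRUE`).
#' @return A `signature_set`: list with `population`, `peaks` (validated),
#'   `top_threshold` and a `summary`.
#' @export
validate_signatures <- function(peaks, threshold,
                                population = NA_character_, strict = TRUE) {
  keep <- if (strict) peaks$max_z > threshold else peaks$max_z >= threshold
  sig <- peaks[keep, , drop = FALSE]
  rownames(sig) <- NULL
  structure(list(
    population = population, peaks = sig, top_threshold = threshold,
    summary = list(
      n = nrow(sig),
      mean_length = if (nrow(sig)) mean(sig$stop - sig$start + 1) else NA,
      max_z = if (nrow(sig)) max(sig$max_z) else NA)),
    class = "signature_set")
}

#' @method print signature_set
#' @export
print.signature_set <- function(x, ...) {
  cat("<signature_set>", x$population, ":", x$summary$n,
      "validated signatures (top-quantile threshold",
      format(x$top_threshold, digits = 4), ")\n")
  invisible(x)
}

# merge overlapping/adjacent-or-closer-than-gap intervals; df sorted within
merge_intervals <- function(df, gap = 0) {
  if (nrow(df) <= 1L) return(df)
  df <- df[order(df$start, df$stop), , drop = FALSE]
  out <- df[1, , drop = FALSE]
  for (i in 2:nrow(df)) {
    j <- nrow(out)
    if (df$start[i] - out$stop[j] - 1 <= gap) {
      out$stop[j] <- max(out$stop[j], df$stop[i])
    } else {
      out <- rbind(out, df[i, , drop = FALSE])
    }
  }
  out
}

#' Segment the union of per-population signatures by membership
#'
#' bedtools-multiinter semantics: on each chromosome, the union of all
#' signature intervals is partitioned at every interval start/stop, and
#' each resulting segment carries the exact set of populations whose
#' signatures cover it. Overlapping peaks within one population are merged
#' first.
#'
#' @param signature_sets List of `signature_set` objects.
#' @return data.frame of segments: `chrom`, `start`, `stop`,
#'   `populations` (comma-separated), `n_pops`, `n_signatures`.
#' @export
multi_population_intersections <- function(signature_sets) {
  ivs <- do.call(rbind, lapply(signature_sets, function(ss) {
    if (!nrow(ss$peaks)) return(NULL)
    merged <- do.call(rbind, lapply(split(ss$peaks, ss$peaks$chrom),
                                    merge_intervals, gap = 0))
    if (nrow(merged) < nrow(ss$peaks)) {
      message("merged ", nrow(ss$peaks) - nrow(merged),
              " overlapping peaks within population ", ss$population)
    }
    data.frame(population = ss$population, chrom = merged$chrom,
               start = merged$start, stop = merged$stop)
  }))
  empty <- data.frame(chrom = character(), start = numeric(),
                      stop = numeric(), populations = character(),
                      n_pops = integer(), n_signatures = integer())
  if (is.null(ivs) || !nrow(ivs)) return(empty)
  out <- lapply(split(ivs, ivs$chrom), function(d) {
    cuts <- sort(unique(c(d$start, d$stop + 1)))
    seg_start <- cuts[-length(cuts)]
    seg_stop <- cuts[-1] - 1
    cover <- lapply(seq_along(seg_start), function(k) {
      which(d$start <= seg_start[k] & d$stop >= seg_stop[k])
    })
    keep <- lengths(cover) > 0
    data.frame(
      chrom = d$chrom[1], start = seg_start[keep], stop = seg_stop[keep],
      populations = vapply(cover[keep], function(i)
        paste(sort(unique(d$population[i])), collapse = ","), ""),
      n_pops = vapply(cover[keep], function(i)
        length(unique(d$population[i])), 0L),
      n_signatures = lengths(cover[keep]))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Group nearby segments into regions
#'
#' Segments on one chromosome whose gap (`next.start - prev.stop - 1`) is
#' at most `gap` bp are chained into one region. Region membership is the
#' union of the member populations; a region is `exclusive` iff exactly
#' one population contributes, otherwise `common`.
#'
#' @param segments Output of [multi_population_intersections()].
#' @param gap Maximum chaining gap in bp (default 50,000).
#' @return data.frame of regions: `region_id` (`Reg_k`), `chrom`, `start`,
#'   `stop`, `member_populations`, `n_pops`, `n_signatures`, `length`,
#'   `classification`.
#' @export
merge_into_regions <- function(segments, gap = 50000) {
  empty <- data.frame(region_id = character(), chrom = character(),
                      start = numeric(), stop = numeric(),
                      member_populations = character(), n_pops = integer(),
                      n_signatures = integer(), length = numeric(),
                      classification = character())
  if (!nrow(segments)) return(empty)
  res <- lapply(split(segments, segments$chrom), function(d) {
    d <- d[order(d$start, d$stop), , drop = FALSE]
    grp <- cumsum(c(1, (d$start[-1] - d$stop[-nrow(d)] - 1 > gap) + 0))
    do.call(rbind, lapply(split(d, grp), function(g) {
      pops <- sort(unique(unlist(strsplit(g$populations, ","))))
      data.frame(chrom = g$chrom[1], start = min(g$start),
                 stop = max(g$stop),
                 member_populations = paste(pops, collapse = ","),
                 n_pops = length(pops), n_signatures = max(g$n_signatures))
    }))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$region_id <- sprintf("Reg_%d", seq_len(nrow(out)))
  out$length <- out$stop - out$start + 1
  out$classification <- ifelse(out$n_pops == 1L, "exclusive", "common")
  rownames(out) <- NULL
  out[c("region_id", "chrom", "start", "stop", "member_populations",
        "n_pops", "n_signatures", "length", "classification")]
}

check_shared_chroms <- function(a_chrom, b_chrom, what) {
  if (!length(intersect(unique(a_chrom), unique(b_chrom)))) {
    stop("no shared chromosome names between inputs (", what, "); left: ",
         paste(utils::head(unique(a_chrom), 5), collapse = ","),
         " right: ", paste(utils::head(unique(b_chrom), 5), collapse = ","))
  }
}

#' Annotate regions with overlapping genes
#'
#' Overlap means any shared base pair under the 1-based inclusive
#' convention.
#'
#' @param regions Regions from [merge_into_regions()].
#' @param genes Gene models from [read_gene_annotation()].
#' @return `regions` with `genes` (comma-separated ids) and `n_genes`.
#' @export
annotate_genes <- function(regions, genes) {
  if (!nrow(regions)) {
    regions$genes <- character()
    regions$n_genes <- integer()
    return(regions)
  }
  check_shared_chroms(regions$chrom, genes$chrom, "regions vs genes")
  hits <- vapply(seq_len(nrow(regions)), function(i) {
    g <- genes[genes$chrom == regions$chrom[i] &
                 genes$start <= regions$stop[i] &
                 genes$stop >= regions$start[i], "gene_id"]
    paste(sort(g), collapse = ",")
  }, "")
  regions$genes <- hits
  regions$n_genes <- ifelse(nzchar(hits),
                            lengths(strsplit(hits, ",")), 0L)
  regions
}

#' Overlap selection signatures with QTL records
#'
#' Every (signature, QTL) pair sharing at least one base pair is reported,
#' together with per-population tallies by trait class.
#'
#' @param signature_sets List of `signature_set` objects.
#' @param qtl QTL records from [read_qtl_table()].
#' @return List with `pairs` (one row per overlapping pair) and
#'   `trait_class_counts` (population x trait_class table as data.frame).
#' @export
annotate_qtl <- function(signature_sets, qtl) {
  sigs <- do.call(rbind, lapply(signature_sets, function(ss) {
    if (!nrow(ss$peaks)) return(NULL)
    data.frame(population = ss$population, chrom = ss$peaks$chrom,
               start = ss$peaks$start, stop = ss$peaks$stop)
  }))
  if (is.null(sigs)) {
    return(list(pairs = data.frame(), trait_class_counts = data.frame()))
  }
  check_shared_chroms(sigs$chrom, qtl$chrom, "signatures vs QTL")
  pairs <- do.call(rbind, lapply(seq_len(nrow(sigs)), function(i) {
    q <- qtl[qtl$chrom == sigs$chrom[i] & qtl$start <= sigs$stop[i] &
               qtl$stop >= sigs$start[i], , drop = FALSE]
    if (!nrow(q)) return(NULL)
    data.frame(population = sigs$population[i], chrom = sigs$chrom[i],
               sig_start = sigs$start[i], sig_stop = sigs$stop[i],
               qtl_id = q$qtl_id, trait_name = q$trait_name,
               trait_class = q$trait_class)
  }))
  if (is.null(pairs)) pairs <- data.frame()
  counts <- if (nrow(pairs)) {
    as.data.frame.matrix(table(pairs$population, pairs$trait_class))
  } else data.frame()
  list(pairs = pairs, trait_class_counts = counts)
}
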