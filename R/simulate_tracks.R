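#' Simulate a gene annotation track
#'
#' Non-overlapping gene models of random length tiled over a chromosome;
#' used to give synthetic genomes a gene layer for region annotation and
#' expression linkage.
#'
#' @param n_genes Number of genes.
#' @param chrom_length_bp Chromosome length.
#' @param chrom Chromosome label.
#' @param mean_length_bp Mean gene length (exponential, floor 1 kb).
#' @param seed Optional seed.
#' @return data.frame of gene models (`gene_id`, `chrom`, `start`, `stop`).
#' @export
simulate_gene_annotation <- function(n_genes = 200, chrom_length_bp = 5e6,
                                     chrom = "1", mean_length_bp = 2e4,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  starts <- sort(sample.int(chrom_length_bp - 1e3, n_genes))
  len <- pmax(1e3, round(stats::rexp(n_genes, 1 / mean_length_bp)))
  stops <- pmin(starts + len - 1, chrom_length_bp)
  stops <- pmin(stops, c(starts[-1] - 1, chrom_length_bp)) # no overlap
  data.frame(gene_id = sprintf("gene%05d", seq_len(n_genes)),
             chrom = chrom, start = starts, stop = stops,
             stringsAsFactors = FALSE)
}

#' Simulate a QTL interval table
#'
#' Random QTL intervals with trait names drawn per trait class, emulating
#' a QTL-database extract.
#'
#' @param n_qtl Number of QTL records.
#' @param chrom_length_bp Chromosome length.
#' @param chrom Chromosome label.
#' @param mean_length_bp Mean interval length.
#' @param trait_classes Closed label set.
#' @param seed Optional seed.
#' @return data.frame of QTL records.
#' @export
simulate_qtl_table <- function(n_qtl = 100, chrom_length_bp = 5e6,
                               chrom = "1", mean_length_bp = 1e5,
                               trait_classes = qtl_trait_classes(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  starts <- sample.int(chrom_length_bp, n_qtl)
  len <- pmax(1e3, round(stats::rexp(n_qtl, 1 / mean_length_bp)))
  cls <- sample(trait_classes, n_qtl, replace = TRUE)
  data.frame(qtl_id = sprintf("QTL%05d", seq_len(n_qtl)), chrom = chrom,
             start = starts, stop = pmin(starts + len - 1, chrom_length_bp),
             trait_name = paste0(gsub(" ", "_", cls), "_trait"),
             trait_class = cls, stringsAsFactors = FALSE)
}
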