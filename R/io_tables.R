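#' Read gene annotation from GFF3 or BED
#'
#' Gene records are returned in the package-wide 1-based inclusive
#' convention; BED input (0-based half-open) is converted on ingress.
#' Parsing is delegated to \pkg{rtracklayer}.
#'
#' @param path Path to a GFF3 or BED file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `stop`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed" else "gff3"
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("package 'rtracklayer' is required to read ", format, " files")
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED"
                            else "GFF3")
  df <- as.data.frame(gr)
  if (format == "gff3") {
    if ("type" %in% names(df)) df <- df[df$type == "gene", , drop = FALSE]
    id <- if ("gene_id" %in% names(df) && !all(is.na(df$gene_id)))
      df$gene_id else df$ID
  } else {
    id <- df$name
  }
  if (is.null(id) || anyNA(id)) stop("gene records without identifiers in ",
                                     path)
  out <- data.frame(gene_id = as.character(id),
                    chrom = as.character(df$seqnames),
                    start = df$start, stop = df$end,
                    stringsAsFactors = FALSE)
  validate_gene_models(out)
}

validate_gene_models <- function(df) {
  if (anyDuplicated(df$gene_id)) {
    stop("duplicated gene ids: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)])[1:3],
               collapse = ", "))
  }
  if (any(df$start > df$stop)) stop("gene with start > stop")
  if (any(df$start < 1)) stop("gene coordinates must be 1-based (start >= 1)")
  df
}

#' Read a cis-eQTL table
#'
#' Expects a TSV with header columns (case-insensitive) eVariant, Chr, Pos,
#' Tissue, eGene, Slope — the layout of CattleGTEx-style significant
#' cis-eQTL files.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `evariant_id`, `chrom`, `pos`, `tissue`,
#'   `egene`, `slope`.
#' @export
read_eqtl_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  names(df) <- tolower(names(df))
  ren <- c(evariant = "evariant_id", evariant_id = "evariant_id",
           chr = "chrom", chrom = "chrom", pos = "pos", tissue = "tissue",
           egene = "egene", slope = "slope")
  keep <- names(df) %in% names(ren)
  df <- df[keep]
  names(df) <- unname(ren[names(df)])
  need <- c("evariant_id", "chrom", "pos", "tissue", "egene", "slope")
  if (!all(need %in% names(df))) {
    stop("eQTL table must provide columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df <- df[need]
  df$chrom <- as.character(df$chrom)
  df$pos <- as.numeric(df$pos)
  df$slope <- as.numeric(df$slope)
  if (any(df$pos < 1)) stop("eQTL positions must be >= 1")
  if (any(!nzchar(df$tissue) | is.na(df$tissue))) {
    stop("every eQTL record needs a non-empty tissue label")
  }
  df
}

#' Write a cis-eQTL table as TSV
#' @param eqtl data.frame as returned by [read_eqtl_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eqtl_table <- function(eqtl, path) {
  utils::write.table(eqtl, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default closed set of QTL trait classes
#' @export
qtl_trait_classes <- function() {
  c("meat and carcass", "milk", "reproduction", "exterior", "health",
    "production")
}

#' Read a QTL interval table
#'
#' Expects a TSV with header columns qtl_id, chrom, start, stop,
#' trait_name, trait_class (1-based inclusive coordinates).
#'
#' @param path Path to the TSV.
#' @param trait_classes Allowed trait-class labels.
#' @return data.frame of QTL records.
#' @export
read_qtl_table <- function(path, trait_classes = qtl_trait_classes()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("qtl_id", "chrom", "start", "stop", "trait_name", "trait_class")
  if (!all(need %in% names(df))) {
    stop("QTL table must provide columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df <- df[need]
  df$chrom <- as.character(df$chrom)
  if (any(df$start > df$stop)) stop("QTL with start > stop")
  if (anyDuplicated(df$qtl_id)) stop("duplicated QTL ids")
  bad <- setdiff(unique(df$trait_class), trait_classes)
  if (length(bad)) {
    stop("unknown trait_class label(s): ", paste(bad, collapse = ", "))
  }
  df
}

#' Read a genes-by-samples expression matrix
#'
#' Expects a TSV whose first column is the gene id and whose remaining
#' columns are samples, plus a two-column sample sheet mapping sample id to
#' tissue. Values are log-scale expression.
#'
#' @param path Path to the expression TSV.
#' @param sample_sheet Path to a TSV with columns `sample`, `tissue`.
#' @return An `expression_matrix` object (list with `genes`, `samples`,
#'   `tissue_of_sample`, `values`).
#' @export
read_expression_matrix <- function(path, sample_sheet) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  genes <- as.character(df[[1]])
  values <- as.matrix(df[-1])
  rownames(values) <- genes
  sheet <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  if (!all(c("sample", "tissue") %in% names(sheet))) {
    stop("sample sheet must have columns 'sample' and 'tissue'")
  }
  tissue <- sheet$tissue[match(colnames(values), sheet$sample)]
  expression_matrix(genes, colnames(values), tissue, values)
}

#' Construct/validate an expression matrix object
#' @param genes,samples Identifier vectors.
#' @param tissue_of_sample Tissue label per sample.
#' @param values Numeric matrix, genes x samples, log scale.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(genes, samples, tissue_of_sample, values) {
  values <- as.matrix(values)
  if (nrow(values) != length(genes) || ncol(values) != length(samples)) {
    stop("expression matrix dimensions do not match gene/sample lists")
  }
  if (length(tissue_of_sample) != length(samples) ||
      anyNA(tissue_of_sample) || any(!nzchar(tissue_of_sample))) {
    stop("every sample needs a tissue label")
  }
  if (anyDuplicated(genes)) stop("duplicated gene ids")
  dimnames(values) <- list(genes, samples)
  structure(list(genes = as.character(genes),
                 samples = as.character(samples),
                 tissue_of_sample = as.character(tissue_of_sample),
                 values = values),
            class = "expression_matrix")
}

#' @method print expression_matrix
#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix>", length(x$genes), "genes x",
      length(x$samples), "samples,",
      length(unique(x$tissue_of_sample)), "tissues\n")
  invisible(x)
}

#' Write intervals as BED (0-based half-open on egress)
#' @param df data.frame with `chrom`, `start`, `stop` (1-based inclusive)
#'   and optionally a `name` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  name <- if ("name" %in% names(df)) df$name else
    if ("region_id" %in% names(df)) df$region_id else "."
  out <- data.frame(df$chrom, format(df$start - 1, scientific = FALSE,
                                     trim = TRUE),
                    format(df$stop, scientific = FALSE, trim = TRUE), name)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
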