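#' Gene family annotation from gene names
#'
#' Assigns each gene to exactly one family by standard human nomenclature
#' prefixes: `MT-` for mitochondrial genes, `RPS`/`RPL` for
#' ribosomal-protein genes, everything else `other`. The sex and macrophage
#' marker genes (XIST, RPS4Y1, CD68, MARCO) are always annotated `other`:
#' RPS4Y1 is nominally a ribosomal-protein gene but is the male-specific
#' transcript the whole analysis rests on, so it must never be swept up by
#' the ribosomal-family discard.
#'
#' @param genes character vector of gene identifiers.
#' @param protected genes forced to family `other`.
#' @return character vector (same length) with values `"mitochondrial"`,
#'   `"ribosomal_protein"` or `"other"`.
#' @export
gene_family <- function(genes,
                        protected = c("XIST", "RPS4Y1", "CD68", "MARCO")) {
  fam <- rep("other", length(genes))
  fam[startsWith(genes, "MT-")] <- "mitochondrial"
  fam[grepl("^RP[SL]", genes)] <- "ribosomal_protein"
  fam[genes %in% protected] <- "other"
  fam
}

.check_annotation <- function(m, annotation) {
  stopifnot(all(c("gene", "family") %in% names(annotation)))
  missing <- setdiff(rownames(m), annotation$gene)
  if (length(missing)) {
    stop("annotation does not cover genes: ", paste(head(missing, 5), collapse = ", "))
  }
  annotation$family[match(rownames(m), annotation$gene)]
}

#' Per-barcode quality-control metrics
#'
#' Computes, for each column of the count matrix: library size (total
#' counts), number of genes detected (count > 0), percentage of counts from
#' mitochondrial genes and percentage from ribosomal-protein genes (0 when
#' the library size is 0).
#'
#' @param m sparse genes x barcodes count matrix with rownames/colnames.
#' @param annotation data.frame with columns `gene`, `family` covering every
#'   gene in `m` (see [gene_family()]).
#' @return data.frame with columns `barcode`, `library_size`, `n_genes`,
#'   `pct_mito`, `pct_ribo`.
#' @export
compute_qc <- function(m, annotation) {
  stopifnot(ncol(m) >= 1L)
  fam <- .check_annotation(m, annotation)
  lib <- Matrix::colSums(m)
  ngene <- Matrix::colSums(m > 0)
  mito <- Matrix::colSums(m[fam == "mitochondrial", , drop = FALSE])
  ribo <- Matrix::colSums(m[fam == "ribosomal_protein", , drop = FALSE])
  pct <- function(x) ifelse(lib > 0, 100 * x / lib, 0)
  data.frame(
    barcode = colnames(m),
    library_size = as.numeric(lib),
    n_genes = as.numeric(ngene),
    pct_mito = pct(mito),
    pct_ribo = pct(ribo),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Flag cells as outliers by the k x MAD rule
#'
#' For each of the four QC metrics the median and the raw (unscaled) median
#' absolute deviation are computed over all cells; a cell is flagged iff
#' `|value - median| > k * MAD` for ANY metric. The default is the literal
#' two-sided reading of the rule; `two_sided = FALSE` flags only cells above
#' `median + k * MAD`. A metric with MAD 0 flags every cell not equal to its
#' median.
#'
#' @param metrics a [compute_qc()] table (>= 2 cells).
#' @param k multiplier (default 3).
#' @param two_sided flag deviations in both directions (default) or only
#'   high values.
#' @return data.frame with per-metric logical flags and an `outlier` column
#'   (any metric flagged).
#' @export
mad_outliers <- function(metrics, k = 3, two_sided = TRUE) {
  if (nrow(metrics) < 2L) stop("mad_outliers requires at least 2 cells")
  stopifnot(k > 0)
  cols <- c("library_size", "n_genes", "pct_mito", "pct_ribo")
  flags <- lapply(cols, function(cn) {
    v <- metrics[[cn]]
    med <- median(v)
    mad_raw <- median(abs(v - med))
    if (two_sided) abs(v - med) > k * mad_raw else (v - med) > k * mad_raw
  })
  names(flags) <- paste0("flag_", cols)
  out <- as.data.frame(flags)
  out <- cbind(barcode = metrics$barcode, out, stringsAsFactors = FALSE)
  out$outlier <- Reduce(`|`, flags)
  out
}

#' Hard mitochondrial / ribosomal caps
#'
#' Flags cells with pct_mito strictly greater than `mito_cap` (default 20)
#' or pct_ribo strictly greater than `ribo_cap` (default 50). Cells exactly
#' at a cap are kept.
#'
#' @param metrics a [compute_qc()] table.
#' @param mito_cap,ribo_cap percentage caps.
#' @return data.frame with `barcode`, `flag_mito`, `flag_ribo`, `outlier`.
#' @export
hard_filters <- function(metrics, mito_cap = 20, ribo_cap = 50) {
  fm <- metrics$pct_mito > mito_cap
  fr <- metrics$pct_ribo > ribo_cap
  data.frame(barcode = metrics$barcode, flag_mito = fm, flag_ribo = fr,
             outlier = fm | fr, stringsAsFactors = FALSE)
}

#' Remove genes detected in too few cells
#'
#' Drops genes whose detection fraction (cells with count > 0) is strictly
#' below `min_cell_fraction`; the default removes genes detected in <1% of
#' all cells.
#'
#' @param m count matrix (>= 1 cell).
#' @param min_cell_fraction prevalence cutoff in \[0, 1\].
#' @return the filtered matrix.
#' @export
filter_genes <- function(m, min_cell_fraction = 0.01) {
  stopifnot(ncol(m) >= 1L)
  frac <- Matrix::rowSums(m > 0) / ncol(m)
  m[frac >= min_cell_fraction, , drop = FALSE]
}

#' Discard mitochondrial and ribosomal-protein gene families
#'
#' Removes every gene annotated `mitochondrial` or `ribosomal_protein`
#' before normalization, so these abundant families cannot drive clustering.
#' The protected markers (XIST, RPS4Y1, CD68, MARCO) carry family `other`
#' and are never removed.
#'
#' @param m count matrix.
#' @param annotation gene annotation covering all genes of `m`.
#' @return the filtered matrix.
#' @export
drop_gene_families <- function(m, annotation) {
  fam <- .check_annotation(m, annotation)
  m[fam == "other", , drop = FALSE]
}

#' Run the full cell- and gene-level QC stage
#'
#' Fixed order: QC metrics are computed once over all cells, then the
#' k x MAD outlier rule and the hard mito/ribo caps remove cells, then the
#' prevalence filter and the gene-family discard remove genes from the
#' surviving cells. Each stage logs items in/out.
#'
#' @param m count matrix of called cells.
#' @param annotation gene annotation.
#' @param mad_k MAD multiplier.
#' @param mad_two_sided see [mad_outliers()].
#' @param mito_cap,ribo_cap see [hard_filters()].
#' @param min_cell_fraction see [filter_genes()].
#' @return list with `matrix` (filtered), `sex_counts_matrix` (cells
#'   filtered, genes untouched — the raw-count source for sex assignment),
#'   `metrics`, and `log` (data.frame of per-stage item counts).
#' @export
qc_pipeline <- function(m, annotation, mad_k = 3, mad_two_sided = TRUE,
                        mito_cap = 20, ribo_cap = 50,
                        min_cell_fraction = 0.01) {
  metrics <- compute_qc(m, annotation)
  mad_f <- mad_outliers(metrics, k = mad_k, two_sided = mad_two_sided)
  m1 <- m[, !mad_f$outlier, drop = FALSE]
  hard_f <- hard_filters(metrics[!mad_f$outlier, , drop = FALSE],
                         mito_cap = mito_cap, ribo_cap = ribo_cap)
  m2 <- m1[, !hard_f$outlier, drop = FALSE]
  m3 <- filter_genes(m2, min_cell_fraction = min_cell_fraction)
  m4 <- drop_gene_families(m3, annotation)
  log <- data.frame(
    stage = c("mad_outliers", "hard_filters", "filter_genes",
              "drop_gene_families"),
    unit = c("cells", "cells", "genes", "genes"),
    n_in = c(ncol(m), ncol(m1), nrow(m2), nrow(m3)),
    n_out = c(ncol(m1), ncol(m2), nrow(m3), nrow(m4)),
    stringsAsFactors = FALSE
  )
  list(matrix = m4, sex_counts_matrix = m2, metrics = metrics, log = log)
}
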