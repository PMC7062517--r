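# Deterministic fixtures built in code (no files, no RNG unless seeded).

# 200-cell QC metrics table with implanted outliers.
#
# All 200 cells carry cyclic baseline metrics, then:
#   cells 191-192: library_size 5000   -> 3xMAD outliers (library)
#   cells 193-194: n_genes 300         -> 3xMAD outliers (genes)
#   cells 195-196: pct_mito 21         -> survive MAD, fail the >20% cap
#   cells 197-198: pct_ribo 52         -> survive MAD, fail the >50% cap
#
# Hand verification of the MAD stage (two-sided, raw MAD, k = 3):
#   library: median 1001, MAD 1  -> cutoff |v-1001| > 3   -> flags the 5000s
#   n_genes: median 101,  MAD 1  -> cutoff |v-101|  > 3   -> flags the 300s
#   pct_mito: median 10,  MAD 4  -> cutoff |v-10|   > 12  -> 21 NOT flagged
#   pct_ribo: median 25,  MAD 10 -> cutoff |v-25|   > 30  -> 52 NOT flagged
# so the MAD stage removes exactly 4 cells and the hard stage exactly 4 more.
make_qc_fixture <- function() {
  i <- 0:199
  metrics <- data.frame(
    barcode = sprintf("BC%03d", i + 1),
    library_size = 1000 + (i %% 3),
    n_genes = 100 + (i %% 3),
    pct_mito = 2 + 4 * (i %% 5),
    pct_ribo = 5 + 10 * (i %% 5),
    stringsAsFactors = FALSE
  )
  metrics$library_size[191:192] <- 5000
  metrics$n_genes[193:194] <- 300
  metrics$pct_mito[195:196] <- 21
  metrics$pct_ribo[197:198] <- 52
  metrics
}

# 50-gene x 200-cell count matrix where gene j (j = 0..49) is detected in
# exactly j cells: j = 0 and j = 1 (0.5%) fall below the 1% prevalence
# cutoff, j = 2 (exactly 1%) is kept, so 48 genes survive.
make_prevalence_fixture <- function() {
  genes <- sprintf("G%02d", 0:49)
  i <- integer(0)
  j <- integer(0)
  for (g in 1:49) {
    i <- c(i, rep(g + 1L, g))
    j <- c(j, seq_len(g))
  }
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(50, 200),
                            dimnames = list(genes, sprintf("C%03d", 1:200)))
  methods::as(m, "generalMatrix")
}

# tiny read-record table for hand-checked demultiplexing fixtures
make_read <- function(barcode, umi, gene, bq = 37L, uq = 37L) {
  data.frame(
    barcode = barcode,
    barcode_quals = vapply(nchar(barcode), function(n)
      intToUtf8(rep(bq + 33L, n)), character(1)),
    umi = umi,
    umi_quals = vapply(nchar(umi), function(n)
      intToUtf8(rep(uq + 33L, n)), character(1)),
    gene = gene,
    stringsAsFactors = FALSE
  )
}
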