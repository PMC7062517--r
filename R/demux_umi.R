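#' Build a barcode whitelist
#'
#' @param barcodes character vector of equal-length barcode sequences.
#' @param abundance observed read support per barcode (>= 0); defaults to 1.
#' @return data.frame of class `barcode_whitelist` with columns `barcode`,
#'   `abundance`.
#' @export
whitelist <- function(barcodes, abundance = rep(1, length(barcodes))) {
  stopifnot(length(barcodes) >= 1L, length(abundance) == length(barcodes),
            all(abundance >= 0), !anyDuplicated(barcodes),
            length(unique(nchar(barcodes))) == 1L)
  out <- data.frame(barcode = as.character(barcodes),
                    abundance = as.numeric(abundance),
                    stringsAsFactors = FALSE)
  class(out) <- c("barcode_whitelist", "data.frame")
  out
}

.as_whitelist <- function(wl) {
  if (inherits(wl, "barcode_whitelist")) return(wl)
  whitelist(wl$barcode, wl$abundance)
}

## all sequences at Hamming distance exactly 1, with the substituted position
.hamming1_variants <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(ch)
  seqs <- character(3L * L)
  pos <- integer(3L * L)
  k <- 0L
  for (p in seq_len(L)) {
    for (b in DNA_BASES[DNA_BASES != ch[p]]) {
      k <- k + 1L
      tmp <- ch
      tmp[p] <- b
      seqs[k] <- paste(tmp, collapse = "")
      pos[k] <- p
    }
  }
  list(seqs = seqs, pos = pos)
}

#' Correct a cell barcode against a whitelist
#'
#' A barcode already in the whitelist is returned unchanged. Otherwise every
#' whitelist member at Hamming distance exactly 1 is scored by posterior
#' probability proportional to `abundance(candidate) * P(error | Phred)` at
#' the mismatched base, with `P(error | q) = 10^(-q/10)`. The best candidate
#' is returned if its normalized posterior reaches the acceptance threshold
#' (0.975, the convention of the upstream droplet pipeline); otherwise the
#' read is unassignable and `NA` is returned.
#'
#' @param observed barcode sequence as read.
#' @param quals integer Phred scores, one per base.
#' @param wl a [whitelist()] (or data.frame with `barcode`, `abundance`).
#' @param threshold posterior acceptance threshold.
#' @return corrected barcode, or `NA_character_` if uncorrectable.
#' @export
#' @examples
#' wl <- whitelist(c("AAAA", "CCCC"), c(100, 100))
#' correct_barcode("AAAT", rep(30L, 4), wl)
correct_barcode <- function(observed, quals, wl, threshold = 0.975) {
  wl <- .as_whitelist(wl)
  if (nchar(observed) != nchar(wl$barcode[1])) {
    stop("observed barcode length does not match whitelist length")
  }
  if (length(quals) != nchar(observed)) {
    stop("quality vector length does not match barcode length")
  }
  if (observed %in% wl$barcode) return(observed)
  var <- .hamming1_variants(observed)
  hit <- match(var$seqs, wl$barcode)
  ok <- which(!is.na(hit))
  if (!length(ok)) return(NA_character_)
  perr <- 10^(-quals[var$pos[ok]] / 10)
  post <- wl$abundance[hit[ok]] * perr
  tot <- sum(post)
  if (tot <= 0) return(NA_character_)
  best <- which.max(post)
  if (post[best] / tot >= threshold) var$seqs[ok][best] else NA_character_
}

#' UMI retention rule
#'
#' A UMI is kept iff it is not a homopolymer (a single repeated base) and
#' every base has Phred quality strictly greater than 10.
#'
#' @param umi UMI sequence.
#' @param quals integer Phred scores, one per base.
#' @return `TRUE` to keep the read, `FALSE` to discard it.
#' @export
filter_umi <- function(umi, quals) {
  stopifnot(nchar(umi) >= 1L, length(quals) == nchar(umi))
  if (grepl("^(.)\\1*$", umi)) return(FALSE)
  min(quals) > 10
}

## directional single-group UMI merge; umis/reads for ONE (barcode, gene)
.correct_umis_group <- function(umis, reads) {
  n <- length(umis)
  if (n == 1L || max(reads) == min(reads)) {
    return(list(umi = umis, reads = reads))
  }
  o <- order(-reads, umis)
  umis <- umis[o]
  orig <- reads[o]
  acc <- orig
  alive <- rep(TRUE, n)
  chm <- do.call(rbind, strsplit(umis, "", fixed = TRUE))
  for (i in seq_len(n - 1L)) {
    if (!alive[i]) next
    for (j in (i + 1L):n) {
      if (!alive[j] || orig[j] >= orig[i]) next
      if (sum(chm[i, ] != chm[j, ]) == 1L) {
        acc[i] <- acc[i] + acc[j]
        alive[j] <- FALSE
      }
    }
  }
  list(umi = umis[alive], reads = acc[alive])
}

#' Merge sequencing-error UMIs within one cell barcode
#'
#' Within each gene, a UMI is corrected to another UMI at Hamming distance 1
#' with strictly greater read support (read counts are summed into the more
#' prolific UMI). UMIs are processed in descending read-support order, ties
#' broken lexicographically, in a single pass, so merge chains are
#' deterministic. UMIs never merge across genes.
#'
#' @param molecules data.frame with columns `umi`, `gene`, `reads`, all
#'   sharing one corrected cell barcode.
#' @return data.frame with the same columns after merging; total `reads` is
#'   conserved and the number of distinct UMIs never increases.
#' @export
correct_umis <- function(molecules) {
  stopifnot(all(c("umi", "gene", "reads") %in% names(molecules)),
            all(molecules$reads >= 1))
  parts <- split(molecules, molecules$gene)
  out <- lapply(names(parts), function(g) {
    p <- parts[[g]]
    r <- .correct_umis_group(p$umi, p$reads)
    data.frame(umi = r$umi, gene = g, reads = r$reads,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a deduplicated count matrix from read records
#'
#' Applies, in order: barcode correction against the whitelist
#' ([correct_barcode()]), the UMI retention rule ([filter_umi()]),
#' within-barcode UMI merging ([correct_umis()]), and multi-gene collision
#' resolution: a (barcode, UMI) pair observed with several genes is assigned
#' to the gene with the most reads and dropped entirely on a tie. Each
#' surviving distinct (barcode, UMI, gene) contributes exactly one count.
#'
#' @param records data.frame of read records (`barcode`, `barcode_quals`,
#'   `umi`, `umi_quals`, `gene`; qualities as offset-33 strings).
#' @param wl a [whitelist()].
#' @param genes optional character vector fixing matrix row order; defaults
#'   to the sorted genes observed.
#' @return sparse genes x barcodes `dgCMatrix` of UMI counts.
#' @export
build_count_matrix <- function(records, wl, genes = NULL) {
  stopifnot(nrow(records) >= 1L)
  wl <- .as_whitelist(wl)
  dt <- as.data.table(records)

  ## barcode correction: fast path for exact whitelist hits
  bc <- dt$barcode
  miss <- which(!(bc %chin% wl$barcode))
  for (i in miss) {
    bc[i] <- correct_barcode(dt$barcode[i], phred_decode(dt$barcode_quals[i]), wl)
  }
  dt[, bc := bc]
  dt <- dt[!is.na(bc)]

  if (nrow(dt)) {
    keep <- !grepl("^(.)\\1*$", dt$umi) & min_phred(dt$umi_quals) > 10L
    dt <- dt[keep]
  }
  if (!nrow(dt)) {
    warning("all reads rejected; returning empty count matrix")
    g <- if (is.null(genes)) character(0) else genes
    return(Matrix::Matrix(0, nrow = length(g), ncol = 0, sparse = TRUE,
                          dimnames = list(g, character(0))))
  }

  mol <- dt[, .(reads = .N), by = .(bc, gene, umi)]

  ## UMI correction within (barcode, gene); only groups that can merge
  mol[, grp_n := .N, by = .(bc, gene)]
  simple <- mol[grp_n == 1L, .(bc, gene, umi, reads)]
  multi <- mol[grp_n > 1L]
  if (nrow(multi)) {
    merged <- multi[, .correct_umis_group(umi, reads), by = .(bc, gene)]
    setnames(merged, c("bc", "gene", "umi", "reads"))
    mol <- rbind(simple, merged)
  } else {
    mol <- simple
  }

  ## multi-gene (barcode, UMI) collisions: max read support wins, ties drop
  mol[, grp_n := .N, by = .(bc, umi)]
  uniq <- mol[grp_n == 1L]
  coll <- mol[grp_n > 1L]
  if (nrow(coll)) {
    coll <- coll[, {
      m <- max(reads)
      w <- which(reads == m)
      if (length(w) == 1L) .SD[w] else .SD[0L]
    }, by = .(bc, umi)]
    mol <- rbind(uniq[, .(bc, umi, gene, reads)],
                 coll[, .(bc, umi, gene, reads)])
  } else {
    mol <- uniq
  }

  if (!nrow(mol)) {
    warning("all reads rejected; returning empty count matrix")
    g <- if (is.null(genes)) character(0) else genes
    return(Matrix::Matrix(0, nrow = length(g), ncol = 0, sparse = TRUE,
                          dimnames = list(g, character(0))))
  }
  if (is.null(genes)) genes <- sort(unique(mol$gene))
  stopifnot(all(mol$gene %in% genes))
  bcs <- sort(unique(mol$bc))
  m <- Matrix::sparseMatrix(
    i = match(mol$gene, genes),
    j = match(mol$bc, bcs),
    x = 1,
    dims = c(length(genes), length(bcs)),
    dimnames = list(genes, bcs)
  )
  as(as(m, "CsparseMatrix"), "generalMatrix")
}
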