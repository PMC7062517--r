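# Independent brute-force oracles. These deliberately share no code with the
# package: plain loops, no data.table, no shortcuts.

oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sum(ca != cb)
}

# barcode correction: scan every whitelist member, score Hamming-1 candidates
oracle_correct_barcode <- function(observed, quals, wl, threshold = 0.975) {
  if (observed %in% wl$barcode) return(observed)
  post <- numeric(0)
  cand <- character(0)
  for (i in seq_len(nrow(wl))) {
    b <- wl$barcode[i]
    if (oracle_hamming(observed, b) == 1L) {
      pos <- which(strsplit(observed, "")[[1]] != strsplit(b, "")[[1]])
      post <- c(post, wl$abundance[i] * 10^(-quals[pos] / 10))
      cand <- c(cand, b)
    }
  }
  if (!length(cand) || sum(post) <= 0) return(NA_character_)
  best <- which.max(post)
  if (post[best] / sum(post) >= threshold) cand[best] else NA_character_
}

# directional UMI merge, one (barcode, gene) group at a time
oracle_correct_umis <- function(mols) {
  out <- NULL
  for (g in sort(unique(mols$gene))) {
    p <- mols[mols$gene == g, , drop = FALSE]
    p <- p[order(-p$reads, p$umi), , drop = FALSE]
    orig <- p$reads
    acc <- p$reads
    alive <- rep(TRUE, nrow(p))
    for (i in seq_len(nrow(p))) {
      if (!alive[i]) next
      for (j in seq_len(nrow(p))) {
        if (i == j || !alive[j]) next
        if (orig[j] < orig[i] && oracle_hamming(p$umi[i], p$umi[j]) == 1L) {
          acc[i] <- acc[i] + acc[j]
          alive[j] <- FALSE
        }
      }
    }
    out <- rbind(out, data.frame(umi = p$umi[alive], gene = g,
                                 reads = acc[alive],
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

# full read-to-count reconstruction on a small fixture
oracle_build_counts <- function(records, wl) {
  bc <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    bc[i] <- oracle_correct_barcode(records$barcode[i],
                                    utf8ToInt(records$barcode_quals[i]) - 33L,
                                    wl)
  }
  keep <- !is.na(bc)
  for (i in which(keep)) {
    u <- records$umi[i]
    q <- utf8ToInt(records$umi_quals[i]) - 33L
    ch <- strsplit(u, "")[[1]]
    if (length(unique(ch)) == 1L || min(q) <= 10) keep[i] <- FALSE
  }
  df <- data.frame(bc = bc[keep], umi = records$umi[keep],
                   gene = records$gene[keep], stringsAsFactors = FALSE)
  if (!nrow(df)) return(list())
  key <- paste(df$bc, df$gene, df$umi, sep = "|")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), "|", fixed = TRUE))
  mol <- data.frame(bc = parts[, 1], gene = parts[, 2], umi = parts[, 3],
                    reads = as.integer(tab), stringsAsFactors = FALSE)
  merged <- NULL
  for (b in sort(unique(mol$bc))) {
    sub <- mol[mol$bc == b, c("umi", "gene", "reads")]
    mg <- oracle_correct_umis(sub)
    mg$bc <- b
    merged <- rbind(merged, mg)
  }
  # multi-gene (barcode, UMI) collisions: max reads wins, ties dropped
  res <- NULL
  for (k in unique(paste(merged$bc, merged$umi, sep = "|"))) {
    sub <- merged[paste(merged$bc, merged$umi, sep = "|") == k, , drop = FALSE]
    mx <- max(sub$reads)
    w <- which(sub$reads == mx)
    if (length(w) == 1L) res <- rbind(res, sub[w, , drop = FALSE])
  }
  counts <- list()
  for (i in seq_len(nrow(res))) {
    k <- paste(res$bc[i], res$gene[i], sep = "|")
    counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
  }
  counts
}

oracle_call_cells <- function(totals, expected_cells) {
  v <- sort(unname(totals), decreasing = TRUE)
  m <- min(expected_cells, length(v))
  top <- sort(v[1:m])
  robust_max <- top[max(1, ceiling(0.99 * m))]
  names(totals)[totals >= robust_max / 10]
}

oracle_mad_flags <- function(metrics, k = 3) {
  flag <- rep(FALSE, nrow(metrics))
  for (cn in c("library_size", "n_genes", "pct_mito", "pct_ribo")) {
    v <- metrics[[cn]]
    med <- median(v)
    mad0 <- median(abs(v - med))
    flag <- flag | (abs(v - med) > k * mad0)
  }
  flag
}

oracle_hard_flags <- function(metrics) {
  metrics$pct_mito > 20 | metrics$pct_ribo > 50
}

oracle_gene_keep <- function(m, min_frac = 0.01) {
  dense <- as.matrix(m)
  keep <- logical(nrow(dense))
  for (i in seq_len(nrow(dense))) {
    keep[i] <- mean(dense[i, ] > 0) >= min_frac
  }
  rownames(dense)[keep]
}

# exact Mann-Whitney by complete enumeration with double-loop U
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi < yj) + 0.5 * (xi == yj)
  }
  u
}

oracle_mwu_p <- function(x, y) {
  pool <- c(x, y)
  m <- length(x)
  idx <- combn(length(pool), m)
  us <- numeric(ncol(idx))
  for (c in seq_len(ncol(idx))) {
    us[c] <- oracle_u(pool[idx[, c]], pool[-idx[, c]])
  }
  u <- oracle_u(x, y)
  eps <- 1e-9
  min(1, 2 * min(mean(us >= u - eps), mean(us <= u + eps)))
}

# exact Spearman permutation p with its own permutation generator
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

oracle_spearman_p <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  eps <- 1e-9
  hits <- 0L
  perms <- oracle_perms(length(x))
  for (p in perms) {
    if (abs(cor(rx, ry[unlist(p)])) >= abs(rho) - eps) hits <- hits + 1L
  }
  hits / length(perms)
}
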