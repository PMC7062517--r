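test_that("barcode correction follows the posterior rule on hand cases", {
  q30 <- rep(30L, 4)
  wl1 <- whitelist(c("AAAA", "CCCC"), c(100, 100))
  expect_identical(correct_barcode("AAAA", q30, wl1), "AAAA")   # identity
  expect_identical(correct_barcode("AAAT", q30, wl1), "AAAA")   # one candidate
  # two symmetric Hamming-1 candidates: posterior 0.5 < 0.975
  wl2 <- whitelist(c("AAAA", "AAAC"), c(50, 50))
  expect_true(is.na(correct_barcode("AAAG", q30, wl2)))
  # abundance skew breaks the symmetry
  wl3 <- whitelist(c("AAAA", "AAAC"), c(1000, 1))
  expect_identical(correct_barcode("AAAG", q30, wl3), "AAAA")
  # no Hamming-1 candidate at all
  expect_true(is.na(correct_barcode("GGGG", q30, wl1)))
  expect_error(correct_barcode("AAA", rep(30L, 3), wl1), "length")
})

test_that("barcode correction matches the brute-force oracle on random cases", {
  set.seed(101)
  for (rep in 1:40) {
    bcs <- unique(replicate(8, paste(sample(c("A", "C", "G", "T"), 6, TRUE),
                                     collapse = "")))
    wl <- whitelist(bcs, sample(0:200, length(bcs), replace = TRUE))
    obs <- paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = "")
    quals <- sample(2:40, 6, replace = TRUE)
    expect_identical(correct_barcode(obs, quals, wl),
                     oracle_correct_barcode(obs, quals, wl),
                     info = paste("rep", rep))
  }
  # corrected output is always a whitelist member or NA (idempotence)
  set.seed(102)
  wl <- whitelist(replicate(20, paste(sample(c("A", "C", "G", "T"), 5, TRUE),
                                      collapse = "")) |> unique())
  for (b in wl$barcode) {
    expect_identical(correct_barcode(b, rep(30L, 5), wl), b)
  }
})

test_that("UMI retention rejects homopolymers and low quality", {
  expect_false(filter_umi("AAAAAAAAAA", rep(40L, 10)))
  q <- rep(30L, 10); q[4] <- 10L                    # strict > 10
  expect_false(filter_umi("ACGTACGTAC", q))
  q[4] <- 11L
  expect_true(filter_umi("ACGTACGTAC", q))
  expect_true(filter_umi("ACGTACGTAC", rep(30L, 10)))
})

test_that("UMI merging follows the prolific-neighbor rule", {
  m <- data.frame(umi = c("AAAA", "AAAT"), gene = "G1", reads = c(5L, 1L))
  out <- correct_umis(m)
  expect_equal(nrow(out), 1)
  expect_equal(out$umi, "AAAA")
  expect_equal(out$reads, 6L)
  # equal support: neither is more prolific, no merge
  m2 <- data.frame(umi = c("AAAA", "AAAT"), gene = "G1", reads = c(3L, 3L))
  expect_equal(nrow(correct_umis(m2)), 2)
  # same UMIs in different genes never merge
  m3 <- data.frame(umi = c("AAAA", "AAAT"), gene = c("G1", "G2"),
                   reads = c(5L, 1L))
  expect_equal(nrow(correct_umis(m3)), 2)
})

test_that("UMI merging matches the oracle and conserves reads", {
  set.seed(103)
  for (rep in 1:40) {
    n <- sample(2:12, 1)
    mols <- data.frame(
      umi = replicate(n, paste(sample(c("A", "C"), 4, TRUE), collapse = "")),
      gene = sample(c("G1", "G2"), n, replace = TRUE),
      reads = sample(1:6, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    mols <- unique(mols[, c("umi", "gene")]) |>
      (\(u) cbind(u, reads = sample(1:6, nrow(u), replace = TRUE)))()
    got <- correct_umis(mols)
    want <- oracle_correct_umis(mols)
    key <- function(d) d[order(d$gene, d$umi), c("umi", "gene", "reads")]
    expect_equal(unname(as.matrix(key(got))), unname(as.matrix(key(want))),
                 info = paste("rep", rep))
    expect_equal(sum(got$reads), sum(mols$reads))       # conservation
    expect_lte(nrow(got), nrow(mols))
  }
})

test_that("duplicate reads of one molecule yield a single count", {
  wl <- whitelist("ACGTAC")
  reads <- make_read(rep("ACGTAC", 10), rep("ACGTACGTAC", 10), rep("G1", 10))
  m <- build_count_matrix(reads, wl)
  expect_equal(as.numeric(m["G1", "ACGTAC"]), 1)
})

test_that("multi-gene (barcode, UMI) collisions resolve by read support", {
  wl <- whitelist("ACGTAC")
  # 3 reads say G1, 1 read says G2: G1 wins, one count
  reads <- make_read(rep("ACGTAC", 4), rep("ACGTACGTAC", 4),
                     c("G1", "G1", "G1", "G2"))
  m <- build_count_matrix(reads, wl)
  expect_equal(as.numeric(m["G1", "ACGTAC"]), 1)
  expect_false("G2" %in% rownames(m)[Matrix::rowSums(m) > 0])
  # 2 vs 2: tie, molecule dropped entirely
  reads2 <- make_read(rep("ACGTAC", 4), rep("ACGTACGTAC", 4),
                      c("G1", "G1", "G2", "G2"))
  expect_warning(m2 <- build_count_matrix(reads2, wl), "all reads rejected")
  expect_equal(ncol(m2), 0)
})

test_that("a mixed error fixture matches the brute-force reconstruction", {
  set.seed(104)
  wl <- whitelist(c("AAAAAA", "CCCCCC", "GGGGGG", "TTTTTT", "ACGTAC"),
                  c(40, 30, 20, 10, 25))
  bcs <- sample(wl$barcode, 50, replace = TRUE)
  umis <- replicate(50, paste(sample(c("A", "C", "G", "T"), 5, TRUE),
                              collapse = ""))
  genes <- sample(c("G1", "G2", "G3"), 50, replace = TRUE)
  reads <- make_read(bcs, umis, genes)
  # implant 2 correctable barcode errors and 1 correctable UMI error
  sub1 <- sub("^A", "T", reads$barcode[1])
  reads$barcode[1] <- sub1
  reads$barcode[2] <- sub("C$", "G", reads$barcode[2])
  reads$umi[3] <- reads$umi[4]                  # duplicate a umi then perturb
  reads$gene[3] <- reads$gene[4]
  reads$barcode[3] <- reads$barcode[4]
  got <- build_count_matrix(reads, wl)
  want <- oracle_build_counts(reads, wl)
  for (k in names(want)) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    expect_equal(as.numeric(got[parts[2], parts[1]]), want[[k]], info = k)
  }
  expect_equal(sum(got), sum(unlist(want)))
})

test_that("oracle equivalence holds on random read fixtures of <= 100 reads", {
  for (seed in c(21, 22, 23)) {
    set.seed(seed)
    wl <- whitelist(c("AAAAAA", "CCCCCC", "GGGGGG", "ACGTAC"),
                    sample(5:50, 4))
    n <- sample(40:100, 1)
    reads <- make_read(
      sample(wl$barcode, n, replace = TRUE),
      replicate(n, paste(sample(c("A", "C", "G"), 4, TRUE), collapse = "")),
      sample(c("G1", "G2"), n, replace = TRUE)
    )
    # random substitution errors in ~10% of barcodes
    err <- sample(n, ceiling(n / 10))
    for (i in err) {
      ch <- strsplit(reads$barcode[i], "")[[1]]
      p <- sample(6, 1)
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      reads$barcode[i] <- paste(ch, collapse = "")
      q <- utf8ToInt(reads$barcode_quals[i]) - 33L
      q[p] <- 5L
      reads$barcode_quals[i] <- intToUtf8(q + 33L)
    }
    got <- build_count_matrix(reads, wl)
    want <- oracle_build_counts(reads, wl)
    expect_equal(sum(got), sum(unlist(want)), info = paste("seed", seed))
    for (k in names(want)) {
      parts <- strsplit(k, "|", fixed = TRUE)[[1]]
      expect_equal(as.numeric(got[parts[2], parts[1]]), want[[k]],
                   info = paste("seed", seed, k))
    }
  }
})
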