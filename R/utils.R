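#' @importFrom data.table data.table as.data.table setDT rbindlist setorder
#'   setorderv := .N .SD %chin% setnames fread fwrite copy
#' @importFrom methods as is new
#' @importFrom stats median rnorm rpois rbinom rlnorm rmultinom runif sd cor
#'   pnorm pt setNames quantile
#' @importFrom utils combn head tail read.delim write.table
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  ".", "barcode", "barcode_quals", "umi", "umi_quals", "gene", "bc", "reads",
  "grp_n", "n_genes_hit", "J", "N", "i.abundance", "abundance", "V1"
))

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the random seed, evaluates `code`, and restores the caller's RNG
#' state afterwards, so package functions never clobber the session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-stream seed from a root seed
#'
#' Deterministic arithmetic (no RNG use) keeping the result a valid 32-bit
#' integer, so each pipeline stage and sample gets an independent named
#' stream from one root seed.
#'
#' @param seed root integer seed.
#' @param offset nonnegative integer stream index.
#' @return integer seed.
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483587L) + 1L
}

#' Decode a Phred quality string (Sanger, offset 33)
#'
#' @param qstring character scalar, ASCII-encoded qualities.
#' @return integer vector of Phred scores.
#' @export
#' @examples
#' phred_decode("IIII")  # four bases at Q40
phred_decode <- function(qstring) {
  stopifnot(is.character(qstring), length(qstring) == 1L)
  utf8ToInt(qstring) - 33L
}

#' Encode integer Phred scores as a Sanger quality string
#'
#' @param q integer vector of Phred scores (0-60).
#' @return character scalar.
#' @export
phred_encode <- function(q) {
  stopifnot(all(q >= 0), all(q <= 60))
  intToUtf8(as.integer(q) + 33L)
}

## minimum Phred per quality string, vectorized over strings
min_phred <- function(qstrings) {
  vapply(qstrings, function(s) min(utf8ToInt(s)), integer(1), USE.NAMES = FALSE) - 33L
}

## n distinct random nucleotide sequences of given length
random_sequences <- function(n, len) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out) + 16L
    m <- matrix(sample(DNA_BASES, need * len, replace = TRUE), ncol = len)
    out <- unique(c(out, apply(m, 1L, paste, collapse = "")))
  }
  out[seq_len(n)]
}

## map integers in [0, 4^len) to sequences, vectorized
int_to_seq <- function(ints, len) {
  digits <- matrix(0L, nrow = length(ints), ncol = len)
  x <- ints
  for (p in len:1) {
    digits[, p] <- x %% 4L
    x <- x %/% 4L
  }
  m <- matrix(DNA_BASES[digits + 1L], nrow = length(ints))
  apply(m, 1L, paste, collapse = "")
}

## Hamming distance between two equal-length strings
hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

## encode an integer matrix of Phred scores (rows = reads) as strings
encode_qual_rows <- function(qm) {
  if (is.null(dim(qm))) qm <- matrix(qm, nrow = 1L)
  offs <- qm + 33L
  vapply(seq_len(nrow(offs)), function(i) intToUtf8(offs[i, ]), character(1))
}
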