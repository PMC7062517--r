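#' Call cell-containing barcodes from total UMI counts
#'
#' Implements the expected-cell-count percentile rule: barcodes are sorted
#' by total UMI count descending; the robust maximum is the nearest-rank
#' 99th percentile of the top `min(expected_cells, n)` totals; every barcode
#' whose total is within an order of magnitude of it (total >=
#' robust_max / 10, inclusive) is called a cell.
#'
#' @param barcode_totals named numeric vector, total UMIs per barcode.
#' @param expected_cells expected number of cells (>= 1); 10,000 is the
#'   full-scale default used in the original experiment, desk-scale runs
#'   use hundreds.
#' @return object of class `cell_call`: list with `called` (character
#'   vector of called barcodes), `robust_max`, `threshold`
#'   (= robust_max / 10) and `n_barcodes`.
#' @export
#' @examples
#' tot <- c(a = 500, b = 450, c = 400, d = 5, e = 4, f = 3)
#' call_cells(tot, expected_cells = 3)
call_cells <- function(barcode_totals, expected_cells) {
  stopifnot(length(barcode_totals) >= 1L, expected_cells >= 1)
  if (is.null(names(barcode_totals)) ||
      anyDuplicated(names(barcode_totals))) {
    stop("barcode_totals must be named with unique barcodes")
  }
  if (all(barcode_totals <= 0)) stop("no candidate cells: all totals are zero")
  totals <- sort(barcode_totals, decreasing = TRUE)
  m <- min(as.integer(expected_cells), length(totals))
  top <- sort(totals[seq_len(m)])           # ascending for nearest-rank
  rank99 <- max(1L, ceiling(0.99 * m))
  robust_max <- as.numeric(top[rank99])
  threshold <- robust_max / 10
  called <- names(barcode_totals)[barcode_totals >= threshold]
  structure(
    list(called = called, robust_max = robust_max, threshold = threshold,
         n_barcodes = length(barcode_totals)),
    class = "cell_call"
  )
}

#' @export
print.cell_call <- function(x, ...) {
  cat(sprintf(
    "cell_call: %d of %d barcodes called (robust max %.1f, threshold %.1f)\n",
    length(x$called), x$n_barcodes, x$robust_max, x$threshold))
  invisible(x)
}
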