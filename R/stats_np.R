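## U statistic: number of (x_i, y_j) pairs with x_i < y_j, plus half ties
.u_stat <- function(x, y) {
  r <- rank(c(x, y))                        # midranks
  m <- length(x)
  n <- length(y)
  ry <- sum(r[(m + 1):(m + n)])
  ry - n * (n + 1) / 2
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a difference between two independent groups. The
#' statistic `U` counts pairs with `x_i < y_j` (plus half the tied pairs,
#' midrank convention); the mirrored convention `m*n - U` gives identical
#' p-values. When the pooled size `m + n` is at most `exact_cap` the p-value
#' is exact, by complete enumeration of all `choose(m+n, m)` group
#' assignments (ties handled exactly); otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used. Two-sided
#' p-values are `min(1, 2 * one-sided)`.
#'
#' @param x,y numeric samples (each >= 1 observation).
#' @param alternative `"two_sided"` (default), `"less"` (x stochastically
#'   smaller than y) or `"greater"`.
#' @param exact_cap maximum pooled size for exact enumeration (default 12;
#'   `choose(12, 6) = 924` assignments).
#' @return object of class `np_test`: list with `statistic` (U), `p_value`,
#'   `method` (`"exact"` or `"normal_approximation"`), `alternative`, `m`,
#'   `n`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
mann_whitney_u <- function(x, y, alternative = "two_sided", exact_cap = 12L) {
  alternative <- match.arg(alternative, c("two_sided", "less", "greater"))
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  stopifnot(is.numeric(x), is.numeric(y), !anyNA(x), !anyNA(y))
  m <- length(x)
  n <- length(y)
  u <- .u_stat(x, y)
  if (m + n <= exact_cap) {
    pool <- c(x, y)
    idx <- combn(m + n, m)
    us <- apply(idx, 2L, function(ix) .u_stat(pool[ix], pool[-ix]))
    eps <- 1e-9
    p_ge <- mean(us >= u - eps)             # evidence for x < y (large U)
    p_le <- mean(us <= u + eps)
    method <- "exact"
  } else {
    N <- m + n
    r <- rank(c(x, y))
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- m * n / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p_ge <- p_le <- 1
    } else {
      mu <- m * n / 2
      s <- sqrt(sigma2)
      p_ge <- pnorm((u - mu - 0.5) / s, lower.tail = FALSE)
      p_le <- pnorm((u - mu + 0.5) / s)
    }
    method <- "normal_approximation"
  }
  p <- switch(alternative,
    less = p_ge,
    greater = p_le,
    two_sided = min(1, 2 * min(p_ge, p_le))
  )
  structure(
    list(statistic = u, p_value = p, method = method,
         alternative = alternative, m = m, n = n),
    class = "np_test"
  )
}

## all permutations of 1..n as an n! x n matrix, lexicographic order
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    block <- cbind(first, matrix(rest[sub], nrow(sub)))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks. For `n <= exact_cap` (default 8) the
#' p-value is exact, from the permutation distribution of the rank
#' correlation under the null (all `n!` orderings); otherwise the
#' t-distribution approximation `t = rho * sqrt((n-2)/(1-rho^2))` with
#' `n - 2` degrees of freedom is used. Two-sided.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact_cap maximum n for exact permutation p.
#' @return object of class `np_test`: list with `statistic` (rho),
#'   `p_value`, `method`, `n`. A constant input yields `NA` statistic and
#'   p-value with a warning.
#' @export
spearman_rho <- function(x, y, exact_cap = 8L) {
  stopifnot(length(x) == length(y), length(x) >= 3L, !anyNA(x), !anyNA(y))
  n <- length(x)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant input: Spearman's rho undefined")
    return(structure(
      list(statistic = NA_real_, p_value = NA_real_, method = "undefined",
           alternative = "two_sided", n = n),
      class = "np_test"
    ))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  eps <- 1e-9
  if (n <= exact_cap) {
    perms <- .all_perms(n)
    rhos <- apply(perms, 1L, function(p) cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - eps)
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(eps, 1 - rho^2))
    p <- min(1, 2 * pt(-abs(tt), df = n - 2))
    method <- "t_approximation"
  }
  structure(
    list(statistic = rho, p_value = p, method = method,
         alternative = "two_sided", n = n),
    class = "np_test"
  )
}

#' @export
print.np_test <- function(x, ...) {
  cat(sprintf("np_test (%s, %s): statistic %.4g, p = %.4g\n",
              x$method, x$alternative, x$statistic, x$p_value))
  invisible(x)
}
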