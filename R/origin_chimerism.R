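#' Per-sample transplant metadata
#'
#' @param sample_id sample identifier.
#' @param recipient_sex,donor_sex `"female"` or `"male"`; must differ for
#'   origin mapping to be identifiable.
#' @param months_post_transplant optional annotation (nonnegative).
#' @return object of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, recipient_sex, donor_sex,
                        months_post_transplant = NA_real_) {
  recipient_sex <- match.arg(recipient_sex, c("female", "male"))
  donor_sex <- match.arg(donor_sex, c("female", "male"))
  if (!is.na(months_post_transplant)) stopifnot(months_post_transplant >= 0)
  structure(
    list(sample_id = as.character(sample_id), recipient_sex = recipient_sex,
         donor_sex = donor_sex,
         months_post_transplant = months_post_transplant),
    class = "sample_meta"
  )
}

#' Per-cell sex call from sex-specific transcript counts
#'
#' Expression greater than zero determines sex: XIST for female cells,
#' RPS4Y1 for male cells, applied to raw (pre-normalization) counts of
#' QC-passing cells. Cells positive for both are `"both"` (candidate
#' doublets or ambient contamination), cells positive for neither are
#' `"neither"` (dropout).
#'
#' @param xist_count,rps4y1_count nonnegative integer vectors (recycled to
#'   common length).
#' @return character vector: `"female"`, `"male"`, `"both"` or `"neither"`.
#' @export
#' @examples
#' assign_sex(c(3, 0, 1, 0), c(0, 2, 2, 0))
assign_sex <- function(xist_count, rps4y1_count) {
  if (any(xist_count < 0) || any(rps4y1_count < 0)) {
    stop("counts must be nonnegative")
  }
  n <- max(length(xist_count), length(rps4y1_count))
  x <- rep_len(xist_count > 0, n)
  y <- rep_len(rps4y1_count > 0, n)
  out <- rep("neither", n)
  out[x & !y] <- "female"
  out[!x & y] <- "male"
  out[x & y] <- "both"
  out
}

#' Map per-cell sex calls to donor/recipient origin
#'
#' In a sex-mismatched transplant, a cell whose sex call equals the
#' recipient's sex is recipient-derived and one matching the donor's sex is
#' donor-derived; `"both"` becomes `"ambiguous"` and `"neither"` becomes
#' `"unassigned"`.
#'
#' @param sex_calls output of [assign_sex()].
#' @param meta a [sample_meta()]; recipient and donor sex must differ.
#' @return data.frame with columns `sex_call` and `origin`
#'   (`"recipient"`, `"donor"`, `"ambiguous"`, `"unassigned"`).
#' @export
map_origin <- function(sex_calls, meta) {
  stopifnot(inherits(meta, "sample_meta"))
  if (meta$recipient_sex == meta$donor_sex) {
    stop("origin not identifiable: recipient and donor are sex-matched")
  }
  origin <- rep("unassigned", length(sex_calls))
  origin[sex_calls == meta$recipient_sex] <- "recipient"
  origin[sex_calls == meta$donor_sex] <- "donor"
  origin[sex_calls == "both"] <- "ambiguous"
  data.frame(sex_call = sex_calls, origin = origin, stringsAsFactors = FALSE)
}

#' Macrophage gate from marker expression
#'
#' @param m raw count matrix.
#' @param markers marker genes; all must be present in the matrix.
#' @param mode `"off"` (all cells pass; the default, since markers confirm
#'   identity rather than subset the quantification), `"any_positive"`
#'   (count > 0 for at least one marker) or `"all_positive"`.
#' @return logical mask over columns of `m`.
#' @export
gate_macrophages <- function(m, markers = c("CD68", "MARCO"), mode = "off") {
  mode <- match.arg(mode, c("off", "any_positive", "all_positive"))
  if (mode == "off") return(rep(TRUE, ncol(m)))
  missing <- setdiff(markers, rownames(m))
  if (length(missing)) {
    stop("marker genes absent from matrix: ", paste(missing, collapse = ", "))
  }
  pos <- m[markers, , drop = FALSE] > 0
  if (mode == "any_positive") Matrix::colSums(pos) >= 1 else
    Matrix::colSums(pos) == length(markers)
}

#' Per-sample chimerism summary
#'
#' Percentages of female-only (XIST+RPS4Y1-), male-only (XIST-RPS4Y1+),
#' ambiguous (double-positive) and unassigned (double-negative) cells over
#' all QC-passing cells, plus the donor/recipient split among assignable
#' cells. The four category percentages always total 100; the
#' donor/recipient split is `NA` (undefined, not 0/0) when no cell is
#' assignable. Percentages are kept at full precision; rendering rounds to
#' 2 decimals.
#'
#' @param calls a [map_origin()] data.frame (columns `sex_call`, `origin`).
#' @param meta a [sample_meta()].
#' @return object of class `chimerism_summary`.
#' @export
summarize_chimerism <- function(calls, meta) {
  stopifnot(inherits(meta, "sample_meta"), nrow(calls) >= 1L)
  n <- nrow(calls)
  n_female <- sum(calls$sex_call == "female")
  n_male <- sum(calls$sex_call == "male")
  n_amb <- sum(calls$sex_call == "both")
  n_un <- sum(calls$sex_call == "neither")
  n_rec <- sum(calls$origin == "recipient")
  n_don <- sum(calls$origin == "donor")
  n_assign <- n_rec + n_don
  structure(
    list(
      sample_id = meta$sample_id,
      recipient_sex = meta$recipient_sex,
      donor_sex = meta$donor_sex,
      n_cells = n,
      n_recipient = n_rec,
      n_donor = n_don,
      n_ambiguous = n_amb,
      n_unassigned = n_un,
      pct_xist_pos = 100 * n_female / n,
      pct_rps4y1_pos = 100 * n_male / n,
      pct_ambiguous = 100 * n_amb / n,
      pct_unassigned = 100 * n_un / n,
      pct_recipient = if (n_assign > 0) 100 * n_rec / n_assign else NA_real_,
      pct_donor = if (n_assign > 0) 100 * n_don / n_assign else NA_real_
    ),
    class = "chimerism_summary"
  )
}

#' @export
print.chimerism_summary <- function(x, ...) {
  cat(sprintf(
    paste0("chimerism_summary [%s] recipient %s / donor %s, %d cells\n",
           "  %% XIST+ only %.2f | %% RPS4Y1+ only %.2f | ambiguous %.2f",
           " | unassigned %.2f\n",
           "  among assignable: recipient %s | donor %s\n"),
    x$sample_id, x$recipient_sex, x$donor_sex, x$n_cells,
    x$pct_xist_pos, x$pct_rps4y1_pos, x$pct_ambiguous, x$pct_unassigned,
    if (is.na(x$pct_recipient)) "undefined" else sprintf("%.2f%%", x$pct_recipient),
    if (is.na(x$pct_donor)) "undefined" else sprintf("%.2f%%", x$pct_donor)))
  invisible(x)
}

#' Dropout-corrected chimerism fraction estimate
#'
#' The raw exclusive-positive fractions understate each population by its
#' transcript dropout. With detection probabilities
#' `d = 1 - exp(-lambda)` per population, the recipient fraction is
#' estimated as `f = (p_R/d_R) / (p_R/d_R + p_D/d_D)` where `p_R`, `p_D`
#' are the observed exclusive-positive fractions. The confidence interval
#' is a Wilson score interval on the recipient share among assignable
#' cells, mapped through the (monotone) dropout correction.
#'
#' @param summary a [summarize_chimerism()] result.
#' @param lambda_recipient,lambda_donor Poisson rates of the recipient-sex
#'   and donor-sex transcript (> 0).
#' @param conf_level confidence level (default 0.95).
#' @return list with `estimate`, `lower`, `upper`, `n_assignable`.
#' @export
estimate_chimerism_fraction <- function(summary, lambda_recipient,
                                        lambda_donor, conf_level = 0.95) {
  stopifnot(inherits(summary, "chimerism_summary"),
            lambda_recipient > 0, lambda_donor > 0)
  d_r <- 1 - exp(-lambda_recipient)
  d_d <- 1 - exp(-lambda_donor)
  n_assign <- summary$n_recipient + summary$n_donor
  if (n_assign == 0) {
    stop("chimerism fraction undefined: no assignable cells")
  }
  q <- summary$n_recipient / n_assign
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  denom <- 1 + z^2 / n_assign
  center <- (q + z^2 / (2 * n_assign)) / denom
  half <- z * sqrt(q * (1 - q) / n_assign + z^2 / (4 * n_assign^2)) / denom
  correct <- function(qq) (qq / d_r) / (qq / d_r + (1 - qq) / d_d)
  list(
    estimate = correct(q),
    lower = correct(max(0, center - half)),
    upper = correct(min(1, center + half)),
    n_assignable = n_assign
  )
}
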