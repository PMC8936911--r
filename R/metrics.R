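# Raw score functions on a plain probability matrix. No validation and no
# renormalization: the finite-difference variance engine perturbs single cells
# and relies on these treating the matrix coordinates as free.

mi_f1_raw <- function(p) sum(diag(p))

ma_f1_raw <- function(p) {
  s <- rowSums(p) + colSums(p)
  mean(2 * diag(p) / s)
}

ma_pr_raw <- function(p) {
  c(maP = mean(diag(p) / rowSums(p)), maR = mean(diag(p) / colSums(p)))
}

ma_f1_star_raw <- function(p) {
  pr <- ma_pr_raw(p)
  if (pr[["maP"]] == 0 && pr[["maR"]] == 0) return(0)
  2 * pr[["maP"]] * pr[["maR"]] / (pr[["maP"]] + pr[["maR"]])
}

check_no_empty_class <- function(p, drop_empty = FALSE) {
  s <- rowSums(p) + colSums(p)
  empty <- which(s == 0)
  if (length(empty) == 0) return(p)
  labels <- rownames(p)[empty] %||% as.character(empty)
  if (!drop_empty) {
    stop_degenerate(sprintf(
      "class(es) %s absent from both margins (p_i. + p_.i = 0); per-class F1 is 0/0. Use drop_empty = TRUE to score the remaining classes.",
      paste(labels, collapse = ", ")))
  }
  warn(sprintf("dropping %d empty class(es): %s; scores computed over %d classes.",
               length(empty), paste(labels, collapse = ", "),
               nrow(p) - length(empty)))
  keep <- setdiff(seq_len(nrow(p)), empty)
  p[keep, keep, drop = FALSE]
}

check_margins_positive <- function(p) {
  zr <- which(rowSums(p) == 0)
  zc <- which(colSums(p) == 0)
  if (length(zr) == 0 && length(zc) == 0) return(invisible(p))
  stop_degenerate(sprintf(
    "maF1star is undefined: zero margin for %s. All row and column margins must be positive.",
    paste(c(if (length(zr)) sprintf("predicted class(es) %s",
                                    paste(rownames(p)[zr] %||% zr, collapse = ", ")),
            if (length(zc)) sprintf("true class(es) %s",
                                    paste(colnames(p)[zc] %||% zc, collapse = ", "))),
          collapse = " and ")))
}

#' Per-class rates, precision, recall and F1
#'
#' For each class i, the true-positive rate `tp` is the diagonal cell p_ii,
#' the false-positive rate `fp` the off-diagonal row sum, and the
#' false-negative rate `fn` the off-diagonal column sum, so that
#' `tp + fp` = p_i. (predicted margin) and `tp + fn` = p_.i (true margin).
#' Precision is p_ii / p_i., recall p_ii / p_.i, and F1 their harmonic mean
#' 2 p_ii / (p_i. + p_.i). A rate whose denominator is zero is `NA`.
#'
#' @param x a `confusion_matrix`, `prop_table`, or square count matrix.
#' @return a tibble with one row per class: `class`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @examples
#' cm <- confusion_matrix(rbind(c(2, 2, 2), c(5, 70, 2), c(0, 2, 15)))
#' class_metrics(cm)
#' @export
class_metrics <- function(x) {
  p <- as_f1_table(x)
  d <- diag(p)
  rs <- rowSums(p)
  cs <- colSums(p)
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tibble::tibble(
    class = rownames(p) %||% paste0("class_", seq_along(d)),
    tp = unname(d),
    fp = unname(rs - d),
    fn = unname(cs - d),
    precision = unname(safe_div(d, rs)),
    recall = unname(safe_div(d, cs)),
    f1 = unname(safe_div(2 * d, rs + cs))
  )
}

#' Micro-averaged F1 score
#'
#' Micro-averaging pools every per-sample decision before forming precision
#' and recall; in a single-label multi-class problem both denominators are 1,
#' so miP = miR = miF1 = the trace of the probability table (overall
#' accuracy).
#'
#' @inheritParams class_metrics
#' @return a single number in \[0, 1\].
#' @export
micro_f1 <- function(x) {
  mi_f1_raw(as_f1_table(x))
}

#' Macro-averaged F1 score (arithmetic mean of per-class F1)
#'
#' `maF1` weights every class equally: the simple mean over classes of the
#' per-class F1 score 2 p_ii / (p_i. + p_.i).
#'
#' @inheritParams class_metrics
#' @param drop_empty if `TRUE`, classes absent from both margins are dropped
#'   (with a warning) and the mean runs over the remaining classes; if `FALSE`
#'   (default) such a class is an error, since 0/0 has no agreed convention
#'   and silently changing r changes the score.
#' @return a single number in \[0, 1\].
#' @export
macro_f1 <- function(x, drop_empty = FALSE) {
  p <- check_no_empty_class(as_f1_table(x), drop_empty)
  ma_f1_raw(p)
}

#' Alternative macro-averaged F1 score (harmonic mean of maP and maR)
#'
#' Averages precision and recall over classes first (macro precision `maP`,
#' macro recall `maR`), then takes their harmonic mean. Requires every row
#' and column margin to be positive; otherwise some per-class precision or
#' recall is undefined and so is the estimator.
#'
#' @inheritParams class_metrics
#' @return a single number in \[0, 1\], with attribute `components` holding
#'   `maP` and `maR`. If maP = maR = 0 the harmonic mean is returned as 0.
#' @export
macro_f1_star <- function(x) {
  p <- as_f1_table(x)
  check_margins_positive(p)
  structure(ma_f1_star_raw(p), components = ma_pr_raw(p))
}

#' All aggregate F1-type scores as a tibble
#'
#' @inheritParams macro_f1
#' @return a tibble with columns `measure` and `estimate`, for measures
#'   `miP`, `miR`, `miF1`, `maP`, `maR`, `maF1`, `maF1star`. A measure whose
#'   estimator is undefined on `x` (zero margins) is reported as `NA`.
#' @examples
#' cm <- confusion_matrix(rbind(c(2, 2, 2), c(5, 70, 2), c(0, 2, 15)))
#' f1_scores(cm)
#' @export
f1_scores <- function(x, drop_empty = FALSE) {
  p <- as_f1_table(x)
  mi <- mi_f1_raw(p)
  ma <- tryCatch(macro_f1(p, drop_empty = drop_empty),
                 f1ci_error_degenerate = function(e) NA_real_)
  star <- tryCatch(macro_f1_star(p),
                   f1ci_error_degenerate = function(e) NA_real_)
  pr <- if (is.na(star[1])) c(maP = NA_real_, maR = NA_real_) else attr(star, "components")
  tibble::tibble(
    measure = c("miP", "miR", "miF1", "maP", "maR", "maF1", "maF1star"),
    estimate = c(mi, mi, mi, pr[["maP"]], pr[["maR"]], ma, as.numeric(star))
  )
}
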