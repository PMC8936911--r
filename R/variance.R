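# Multinomial delta method. With p the r^2-vector of cell probabilities, the
# MLE p-hat satisfies sqrt(n)(p-hat - p) -> Normal(0, Sigma),
# Sigma = diag(p) - p p^T. For a smooth score g(p), Var(g(p-hat)) is
# approximately grad^T Sigma grad / n. Because Sigma annihilates the
# sum-to-one direction, gradients are taken in the r^2 unconstrained cell
# coordinates (perturb one cell, never renormalize). The quadratic form
# simplifies to (sum_kl p_kl g_kl^2 - (sum_kl p_kl g_kl)^2) / n.

quad_form_multinomial <- function(g, p) {
  sum(p * g^2) - sum(p * g)^2
}

resolve_n <- function(x, n) {
  n <- n %||% attr(x, "n")
  if (is.null(n) || is.na(n) || n < 1) {
    stop_input("`n` (total sample size) must be supplied and >= 1.")
  }
  n
}

#' Delta-method variance of the micro-averaged F1 estimator
#'
#' `miF1` is the trace of the probability table, a linear functional of the
#' multinomial cell probabilities, so its large-sample variance has the
#' binomial form `miF1 (1 - miF1) / n`.
#'
#' @param x a `confusion_matrix`, `prop_table`, or square matrix (counts or
#'   probabilities).
#' @param n total sample size; taken from `x` when it carries one.
#' @return the estimated variance of the miF1 estimator (a single number).
#' @export
var_micro_f1 <- function(x, n = NULL) {
  p <- as_f1_table(x)
  n <- resolve_n(p, n)
  mi <- mi_f1_raw(p)
  mi * (1 - mi) / n
}

# Analytic gradient of maF1 w.r.t. cell p_kl, with s_i = p_i. + p_.i and
# A_i = p_ii / s_i^2:  g_kl = (2/r) (1[k==l]/s_k - A_k - A_l).
ma_f1_gradient <- function(p) {
  r <- nrow(p)
  s <- rowSums(p) + colSums(p)
  a <- diag(p) / s^2
  (2 / r) * (diag(1 / s, r) - outer(a, rep(1, r)) - outer(rep(1, r), a))
}

#' Delta-method variance of the macro-averaged F1 estimator
#'
#' Computes grad^T (diag(p) - p p^T) grad / n with the analytic gradient of
#' `maF1 = (2/r) sum_i p_ii / (p_i. + p_.i)`. The cell (k, l) gradient is
#' `(2/r) (1[k=l]/s_k - p_kk/s_k^2 - p_ll/s_l^2)` where `s_i = p_i. + p_.i`;
#' [delta_var_numeric()] certifies this closed form.
#'
#' @inheritParams var_micro_f1
#' @param drop_empty see [macro_f1()].
#' @return the estimated variance of the maF1 estimator.
#' @export
var_macro_f1 <- function(x, n = NULL, drop_empty = FALSE) {
  p <- as_f1_table(x)
  n <- resolve_n(p, n)
  p <- check_no_empty_class(p, drop_empty)
  quad_form_multinomial(ma_f1_gradient(p), p) / n
}

#' Delta-method variance of the alternative macro-averaged F1 estimator
#'
#' Propagates the multinomial covariance through (maP, maR) and then through
#' the harmonic-mean map `(maP, maR) -> 2 maP maR / (maP + maR)`:
#' with partial derivatives `dP = 2 maR^2/(maP+maR)^2` and
#' `dR = 2 maP^2/(maP+maR)^2`,
#' `Var(maF1star) = dP^2 Var(maP) + 2 dP dR Cov(maP, maR) + dR^2 Var(maR)`.
#' The component moments come from the cell gradients of maP and maR; in
#' scalar form `Var(maP) = (1/r^2) sum_i p_ii FP_i / p_i.^3 / n`,
#' `Var(maR) = (1/r^2) sum_i p_ii FN_i / p_.i^3 / n`, and
#' `Cov = (1/r^2) [ sum_i p_ii FP_i FN_i / (p_i.^2 p_.i^2)
#'                + sum_{i != j} p_ij p_ii p_jj / (p_i.^2 p_.j^2) ] / n`.
#' All are certified against [delta_var_numeric()].
#'
#' @inheritParams var_micro_f1
#' @return the estimated variance, with attribute `components`: a named vector
#'   holding `var_maP`, `var_maR`, `cov_maP_maR`.
#' @export
var_macro_f1_star <- function(x, n = NULL) {
  p <- as_f1_table(x)
  n <- resolve_n(p, n)
  check_margins_positive(p)
  r <- nrow(p)
  rs <- rowSums(p)
  cs <- colSums(p)
  d <- diag(p)
  # cell gradients of maP and maR
  gp <- (1 / r) * (diag(1 / rs, r) - outer(d / rs^2, rep(1, r)))
  gr <- (1 / r) * (diag(1 / cs, r) - outer(rep(1, r), d / cs^2))
  var_p <- quad_form_multinomial(gp, p) / n
  var_r <- quad_form_multinomial(gr, p) / n
  cov_pr <- (sum(p * gp * gr) - sum(p * gp) * sum(p * gr)) / n
  pr <- ma_pr_raw(p)
  map <- pr[["maP"]]
  mar <- pr[["maR"]]
  if (map + mar == 0) {
    v <- 0
  } else {
    dp <- 2 * mar^2 / (map + mar)^2
    dr <- 2 * map^2 / (map + mar)^2
    v <- dp^2 * var_p + 2 * dp * dr * cov_pr + dr^2 * var_r
  }
  structure(v, components = c(var_maP = var_p, var_maR = var_r,
                              cov_maP_maR = cov_pr))
}

#' Numerical delta-method variance (finite-difference engine)
#'
#' Independent oracle for the closed-form variances: estimates the gradient of
#' an arbitrary scalar score by central finite differences in the r^2
#' unconstrained cell coordinates (each cell perturbed alone, no
#' renormalization — the multinomial covariance already encodes the sum-to-one
#' constraint) and returns the quadratic form
#' `grad^T (diag(p) - p p^T) grad / n`.
#'
#' @param score_fn function taking a plain r x r numeric matrix (which may not
#'   sum exactly to 1) and returning a finite scalar.
#' @inheritParams var_micro_f1
#' @param step central-difference step; default 1e-6.
#' @return the estimated variance of `score_fn` at the plug-in probabilities.
#' @examples
#' p <- prop_table(confusion_matrix(rbind(c(2, 2, 2), c(5, 70, 2), c(0, 2, 15))))
#' delta_var_numeric(micro_f1, p, n = 100)
#' var_micro_f1(p, n = 100)
#' @export
delta_var_numeric <- function(score_fn, x, n = NULL, step = 1e-6) {
  p <- as_f1_table(x)
  n <- resolve_n(p, n)
  if (!is.function(score_fn)) stop_input("`score_fn` must be a function.")
  if (!is.numeric(step) || length(step) != 1 || step <= 0) {
    stop_input("`step` must be a single positive number.")
  }
  r <- nrow(p)
  pv <- as.vector(unclass(p))
  eval_at <- function(v) {
    out <- tryCatch(score_fn(matrix(v, r, r, dimnames = dimnames(p))),
                    error = function(e) NaN)
    if (length(out) != 1 || !is.finite(out)) {
      stop_oracle(
        "score undefined or non-finite at a perturbed table; try a smaller `step`.")
    }
    as.numeric(out)
  }
  g <- vapply(seq_along(pv), function(k) {
    up <- pv; up[k] <- up[k] + step
    dn <- pv; dn[k] <- dn[k] - step
    (eval_at(up) - eval_at(dn)) / (2 * step)
  }, numeric(1))
  gm <- matrix(g, r, r)
  quad_form_multinomial(gm, unclass(p)) / n
}

#' Wald confidence interval from an estimate and a variance
#'
#' `estimate +/- z_(1 - alpha/2) * sqrt(variance)` with the exact normal
#' quantile (1.959964 at alpha = 0.05). Bounds are not restricted to \[0, 1\]
#' unless `clip = TRUE`.
#'
#' @param estimate point estimate.
#' @param variance nonnegative variance estimate.
#' @param alpha miscoverage level in (0, 1); default 0.05 for a 95% interval.
#' @param clip truncate the bounds to \[0, 1\]?
#' @return a one-row tibble: `estimate`, `variance`, `se`, `ci_lower`,
#'   `ci_upper`, `alpha`, `z`, `clipped`.
#' @export
wald_interval <- function(estimate, variance, alpha = 0.05, clip = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop_input("`alpha` must be a single number in (0, 1).")
  }
  if (any(variance < 0)) stop_input("`variance` must be nonnegative.")
  z <- qnorm(1 - alpha / 2)
  se <- sqrt(variance)
  lo <- estimate - z * se
  hi <- estimate + z * se
  clipped <- clip & (lo < 0 | hi > 1)
  if (clip) {
    lo <- pmax(lo, 0)
    hi <- pmin(hi, 1)
  }
  tibble::tibble(estimate = estimate, variance = variance, se = se,
                 ci_lower = lo, ci_upper = hi, alpha = alpha, z = z,
                 clipped = clipped)
}

#' Estimates, delta-method variances and Wald intervals for the F1 measures
#'
#' The package's main workhorse: computes the requested aggregate F1 scores
#' from a confusion matrix, their delta-method variances, and
#' (1 - alpha) x 100% Wald confidence intervals.
#'
#' A boundary estimate (e.g. a perfect classifier, miF1 = 1) has estimated
#' variance 0 and a degenerate interval; a warning notes that the large-sample
#' interval carries no information there. A measure whose estimator is
#' undefined on the data (zero margin for `maF1star`; a class missing from
#' both margins for `maF1`) raises a degenerate-estimator error; use
#' `drop_empty = TRUE` to rescore `maF1` over the non-empty classes.
#'
#' @param x a `confusion_matrix`, `prop_table`, or square matrix of counts.
#' @param n total sample size; taken from `x` when it carries one.
#' @param alpha miscoverage level in (0, 1).
#' @param measures subset of `c("miF1", "maF1", "maF1star")`.
#' @param clip truncate interval bounds to \[0, 1\]? Off by default.
#' @param drop_empty see [macro_f1()].
#' @return an object of class `f1_ci`: a list with `estimates` (a tibble with
#'   one row per measure: `measure`, `estimate`, `variance`, `se`, `ci_lower`,
#'   `ci_upper`, `alpha`, `z`, `clipped`), `components` (maF1star variance
#'   diagnostics, when computed), and `n`, `r`, `alpha`, `clip`.
#' @examples
#' cm <- confusion_matrix(rbind(c(2, 2, 2), c(5, 70, 2), c(0, 2, 15)))
#' f1_ci(cm)
#' @export
f1_ci <- function(x, n = NULL, alpha = 0.05,
                  measures = c("miF1", "maF1", "maF1star"),
                  clip = FALSE, drop_empty = FALSE) {
  measures <- match.arg(measures, c("miF1", "maF1", "maF1star"),
                        several.ok = TRUE)
  p <- as_f1_table(x)
  n <- resolve_n(p, n)
  components <- NULL
  rows <- lapply(measures, function(m) {
    if (m == "miF1") {
      est <- mi_f1_raw(p)
      v <- var_micro_f1(p, n)
      if (est %in% c(0, 1)) {
        warn("miF1 estimate is on the boundary; variance 0, degenerate Wald interval.")
      }
    } else if (m == "maF1") {
      pd <- check_no_empty_class(p, drop_empty)  # warn/err once, not per call
      est <- ma_f1_raw(pd)
      v <- quad_form_multinomial(ma_f1_gradient(pd), pd) / n
    } else {
      est_full <- macro_f1_star(p)
      est <- as.numeric(est_full)
      v_full <- var_macro_f1_star(p, n)
      v <- as.numeric(v_full)
      components <<- c(attr(est_full, "components"), attr(v_full, "components"))
    }
    dplyr::bind_cols(tibble::tibble(measure = m),
                     wald_interval(est, v, alpha = alpha, clip = clip))
  })
  structure(
    list(estimates = dplyr::bind_rows(rows),
         components = components,
         n = n, r = nrow(p), alpha = alpha, clip = clip),
    class = "f1_ci")
}

#' @export
print.f1_ci <- function(x, digits = 3, ...) {
  cat(sprintf("Wald confidence intervals for F1 measures (n = %d, r = %d, %g%% CI)\n",
              x$n, x$r, 100 * (1 - x$alpha)))
  est <- x$estimates
  out <- data.frame(measure = est$measure,
                    estimate = round(est$estimate, digits),
                    se = round(est$se, 4),
                    ci_lower = round(est$ci_lower, digits),
                    ci_upper = round(est$ci_upper, digits))
  print(out, row.names = FALSE)
  invisible(x)
}
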