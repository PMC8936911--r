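#' Built-in simulation scenarios
#'
#' Three 3-class probability tables spanning qualitatively different regimes:
#'
#' * scenario 1 — balanced classes, uniformly good classifier: diagonal cells
#'   8/30, off-diagonal cells 1/30; all three F1 measures equal 0.80.
#' * scenario 2 — one dominant class (true-class probability 0.80) that is
#'   also classified best; micro-averaging is dominated by it
#'   (miF1 = 0.72, maF1 = 0.50, maF1star = 0.51).
#' * scenario 3 — one dominant class with high precision but low recall, and
#'   small diagonal mass overall (miF1 = 0.48, maF1 = 0.44, maF1star = 0.55).
#'
#' @return a named list of three [f1_scenario()] objects.
#' @export
f1_scenarios <- function() {
  s1 <- matrix(1 / 30, 3, 3)
  diag(s1) <- 8 / 30
  s2 <- rbind(c(64, 3, 3), c(8, 4, 3), c(8, 3, 4)) / 100
  s3 <- rbind(c(32, 1, 1), c(24, 8, 1), c(24, 1, 8)) / 100
  list(scenario1 = f1_scenario(s1, "scenario1"),
       scenario2 = f1_scenario(s2, "scenario2"),
       scenario3 = f1_scenario(s3, "scenario3"))
}

#' Define a simulation scenario from a probability table
#'
#' @param p square matrix of true cell probabilities (rows = predicted,
#'   columns = true) summing to 1 within 1e-9.
#' @param name scenario label used in outputs.
#' @return an object of class `f1_scenario`: a list with `name`, `p` (a
#'   `prop_table`), and `true_scores`, the analytic miF1 / maF1 / maF1star
#'   implied by `p` (`NA` where undefined).
#' @export
f1_scenario <- function(p, name = "custom") {
  pt <- as_prop_table(p, tol = 1e-9)
  scores <- f1_scores(pt)
  true_scores <- stats::setNames(scores$estimate, scores$measure)[
    c("miF1", "maF1", "maF1star")]
  structure(list(name = name, p = pt, true_scores = true_scores),
            class = "f1_scenario")
}

#' @export
print.f1_scenario <- function(x, ...) {
  cat(sprintf("<f1_scenario '%s': r = %d; true miF1 = %.4f, maF1 = %.4f, maF1star = %.4f>\n",
              x$name, nrow(x$p), x$true_scores[["miF1"]],
              x$true_scores[["maF1"]], x$true_scores[["maF1star"]]))
  invisible(x)
}

#' Draw confusion matrices from a multinomial model
#'
#' Samples `reps` independent tables `(n_11, ..., n_rr) ~ Multinomial(n; p)`.
#'
#' @param p square matrix of cell probabilities (or `f1_scenario`).
#' @param n total sample size per table.
#' @param reps number of tables.
#' @param seed optional integer seed; identical seeds give identical draws.
#' @return an `r x r x reps` integer array of counts; each slice sums to `n`.
#' @export
simulate_confusion <- function(p, n, reps = 1, seed = NULL) {
  if (inherits(p, "f1_scenario")) p <- p$p
  pt <- as_prop_table(p, tol = 1e-9)
  if (!is.numeric(n) || n < 1) stop_input("`n` must be a positive integer.")
  if (!is.numeric(reps) || reps < 1) stop_input("`reps` must be >= 1.")
  if (!is.null(seed)) set.seed(as.integer(seed))
  r <- nrow(pt)
  draws <- rmultinom(reps, size = n, prob = as.vector(unclass(pt)))
  array(draws, dim = c(r, r, reps),
        dimnames = c(dimnames(pt), list(NULL)))
}

# Vectorized estimator engine. `P` is an r^2 x reps matrix of plug-in cell
# probabilities, column-major within each column (cell (i, j) at row
# i + (j-1) r). Returns per-replicate estimates, delta-method variances and
# defined flags for all three measures. Mirrors the scalar closed forms in
# variance.R; the agreement of the two code paths is itself under test.
f1_stats_vectorized <- function(P, r, n) {
  reps <- ncol(P)
  rowidx <- rep(seq_len(r), times = r)
  colidx <- rep(seq_len(r), each = r)
  diag_idx <- seq(1, r * r, by = r + 1)
  ind_diag <- as.numeric(rowidx == colidx)

  D <- P[diag_idx, , drop = FALSE]                   # p_ii      (r x reps)
  RS <- rowsum(P, rowidx)                            # p_i.      (r x reps)
  CS <- rowsum(P, colidx)                            # p_.i      (r x reps)

  mi <- colSums(D)
  var_mi <- mi * (1 - mi) / n

  S <- RS + CS
  ok_ma <- colSums(S == 0) == 0
  F1 <- 2 * D / S
  ma <- colMeans(F1)
  A <- D / S^2
  G <- (2 / r) * (ind_diag / S[rowidx, , drop = FALSE]
                  - A[rowidx, , drop = FALSE] - A[colidx, , drop = FALSE])
  var_ma <- (colSums(P * G^2) - colSums(P * G)^2) / n
  ma[!ok_ma] <- NA_real_
  var_ma[!ok_ma] <- NA_real_

  ok_star <- colSums(RS == 0) == 0 & colSums(CS == 0) == 0
  maP <- colMeans(D / RS)
  maR <- colMeans(D / CS)
  star <- ifelse(maP + maR > 0, 2 * maP * maR / (maP + maR), 0)
  GP <- (1 / r) * (ind_diag / RS[rowidx, , drop = FALSE]
                   - (D / RS^2)[rowidx, , drop = FALSE])
  GR <- (1 / r) * (ind_diag / CS[colidx, , drop = FALSE]
                   - (D / CS^2)[colidx, , drop = FALSE])
  var_p <- (colSums(P * GP^2) - colSums(P * GP)^2) / n
  var_r <- (colSums(P * GR^2) - colSums(P * GR)^2) / n
  cov_pr <- (colSums(P * GP * GR) - colSums(P * GP) * colSums(P * GR)) / n
  dp <- 2 * maR^2 / (maP + maR)^2
  dr <- 2 * maP^2 / (maP + maR)^2
  var_star <- dp^2 * var_p + 2 * dp * dr * cov_pr + dr^2 * var_r
  var_star[maP + maR == 0] <- 0
  star[!ok_star] <- NA_real_
  var_star[!ok_star] <- NA_real_

  list(miF1 = list(estimate = mi, variance = var_mi, defined = rep(TRUE, reps)),
       maF1 = list(estimate = ma, variance = var_ma, defined = ok_ma),
       maF1star = list(estimate = star, variance = var_star, defined = ok_star))
}

# Derive a per-(scenario, n) substream seed from the master seed so each grid
# cell is reproducible in isolation. Kept strictly below 2^31.
cell_seed <- function(seed, scenario_name, n) {
  h <- sum(utf8ToInt(scenario_name) * seq_along(utf8ToInt(scenario_name)))
  as.integer((abs(as.numeric(seed)) %% 65011 * 20011 + h * 7919 + n) %% 2147483629)
}

#' Empirical coverage of the Wald F1 intervals under a multinomial model
#'
#' Draws `reps` confusion matrices from a scenario's true probability table,
#' builds the (1 - alpha) Wald interval for each requested measure in each
#' replicate, and reports the fraction of intervals containing the scenario's
#' true score (closed-interval containment).
#'
#' Replicates where an estimator is undefined — a zero margin for `maF1star`,
#' or a class absent from both margins for `maF1` — are data, not errors:
#' under `undefined_policy = "drop"` (default) they leave the denominator;
#' under `"noncover"` they count as non-covering. All tallies are reported so
#' either rate can be reconstructed.
#'
#' @param scenario an [f1_scenario()] (or a probability matrix).
#' @param n total sample size per simulated table.
#' @param reps number of simulated tables; default 1e5.
#' @param alpha miscoverage level of the intervals.
#' @param measures subset of `c("miF1", "maF1", "maF1star")`.
#' @param undefined_policy `"drop"` or `"noncover"` (see above).
#' @param seed master integer seed; the draw for a given (scenario, n) pair is
#'   reproducible independently of other cells.
#' @return a tibble of class `f1_coverage`, one row per measure: `scenario`,
#'   `n`, `measure`, `reps_requested`, `reps_evaluable`, `reps_covering`,
#'   `coverage`, `mc_se` (binomial Monte-Carlo standard error of `coverage`),
#'   `undefined_policy`, `alpha`, `seed`, `true_score`.
#' @examples
#' sc <- f1_scenarios()$scenario1
#' coverage_study(sc, n = 100, reps = 2000, seed = 1)
#' @export
coverage_study <- function(scenario, n, reps = 1e5, alpha = 0.05,
                           measures = c("miF1", "maF1", "maF1star"),
                           undefined_policy = c("drop", "noncover"),
                           seed = 1) {
  undefined_policy <- match.arg(undefined_policy)
  measures <- match.arg(measures, c("miF1", "maF1", "maF1star"),
                        several.ok = TRUE)
  if (!inherits(scenario, "f1_scenario")) scenario <- f1_scenario(scenario)
  if (!is.numeric(reps) || reps < 1) stop_input("`reps` must be >= 1.")
  r <- nrow(scenario$p)
  sub_seed <- cell_seed(seed, scenario$name, n)
  set.seed(sub_seed)
  counts <- rmultinom(reps, size = n, prob = as.vector(unclass(scenario$p)))
  stats <- f1_stats_vectorized(counts / n, r, n)
  z <- qnorm(1 - alpha / 2)
  rows <- purrr::map(measures, function(m) {
    st <- stats[[m]]
    truth <- scenario$true_scores[[m]]
    ok <- st$defined
    lo <- st$estimate - z * sqrt(st$variance)
    hi <- st$estimate + z * sqrt(st$variance)
    covering <- sum(lo[ok] <= truth & truth <= hi[ok])
    evaluable <- sum(ok)
    denom <- if (undefined_policy == "drop") evaluable else reps
    coverage <- if (denom > 0) covering / denom else NA_real_
    tibble::tibble(
      scenario = scenario$name, n = as.integer(n), measure = m,
      reps_requested = as.integer(reps), reps_evaluable = as.integer(evaluable),
      reps_covering = as.integer(covering), coverage = coverage,
      mc_se = if (denom > 0) sqrt(coverage * (1 - coverage) / denom) else NA_real_,
      undefined_policy = undefined_policy, alpha = alpha,
      seed = as.integer(sub_seed), true_score = truth)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("f1_coverage", class(out))
  out
}

#' Coverage grid over scenarios and sample sizes
#'
#' Runs [coverage_study()] for every (scenario, n) combination and returns the
#' results both long and as a wide grid (one row per n, one column per
#' scenario x measure), the layout conventional for reporting coverage
#' studies.
#'
#' @param scenarios list of [f1_scenario()] objects; defaults to the built-in
#'   three.
#' @param n_grid sample sizes; default `c(25, 50, 100, 500, 1000, 5000)`.
#' @inheritParams coverage_study
#' @param wide return the wide grid (default) or the long tibble.
#' @return a tibble; wide form has column `n` plus one coverage column per
#'   `scenario.measure`. The long form (`wide = FALSE`) is an `f1_coverage`
#'   tibble with full replicate bookkeeping.
#' @export
coverage_table <- function(scenarios = f1_scenarios(),
                           n_grid = c(25, 50, 100, 500, 1000, 5000),
                           reps = 1e5, alpha = 0.05,
                           measures = c("miF1", "maF1", "maF1star"),
                           undefined_policy = c("drop", "noncover"),
                           seed = 1, wide = TRUE) {
  undefined_policy <- match.arg(undefined_policy)
  grid <- tidyr::expand_grid(scenario = scenarios, n = n_grid)
  long <- purrr::pmap(grid, function(scenario, n) {
    coverage_study(scenario, n = n, reps = reps, alpha = alpha,
                   measures = measures, undefined_policy = undefined_policy,
                   seed = seed)
  })
  long <- dplyr::bind_rows(long)
  class(long) <- c("f1_coverage", class(tibble::tibble()))
  if (!wide) return(long)
  long |>
    dplyr::mutate(cell = paste(.data$scenario, .data$measure, sep = ".")) |>
    dplyr::select("n", "cell", "coverage") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "coverage") |>
    dplyr::arrange(.data$n)
}
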