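# Shared fixtures, built in code.

# 3-class example used throughout the documentation: n = 100, rows = predicted.
example_counts <- function() {
  confusion_matrix(rbind(c(2, 2, 2), c(5, 70, 2), c(0, 2, 15)))
}

# Random probability table with all cells strictly positive (bounded away
# from zero so finite-difference steps stay inside the simplex).
random_prop_table <- function(r) {
  x <- matrix(stats::rgamma(r * r, shape = 2) + 0.1, r, r)
  as_prop_table(x / sum(x))
}

# Random count table with strictly positive cells.
random_counts <- function(r, lambda = 8) {
  confusion_matrix(matrix(stats::rpois(r * r, lambda) + 1L, r, r))
}

# Independent per-class oracle: precision/recall/F1 via explicit loops,
# kept deliberately naive.
naive_class_metrics <- function(p) {
  r <- nrow(p)
  out <- data.frame(tp = numeric(r), fp = numeric(r), fn = numeric(r),
                    precision = numeric(r), recall = numeric(r),
                    f1 = numeric(r))
  for (i in seq_len(r)) {
    tp <- p[i, i]
    fp <- 0
    fn <- 0
    for (j in seq_len(r)) {
      if (j != i) {
        fp <- fp + p[i, j]
        fn <- fn + p[j, i]
      }
    }
    out$tp[i] <- tp
    out$fp[i] <- fp
    out$fn[i] <- fn
    out$precision[i] <- tp / (tp + fp)
    out$recall[i] <- tp / (tp + fn)
    out$f1[i] <- 2 * tp / (2 * tp + fp + fn)
  }
  out
}
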