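#' Construct a confusion matrix of counts
#'
#' Validates and canonicalizes an r x r table of classification counts. The
#' canonical orientation is rows = predicted class, columns = true class; a
#' table recorded the other way round is transposed on construction.
#'
#' @param x a square numeric matrix (or data frame) of nonnegative integer
#'   counts, with at least two classes and at least one observation in total.
#' @param labels optional character vector of r distinct class labels; defaults
#'   to existing dimnames, else `"class_1" ... "class_r"`.
#' @param orientation `"rows-predicted"` (default) if rows of `x` hold the
#'   predicted class, `"rows-true"` if they hold the true class (then `x` is
#'   transposed so the result is always rows-predicted).
#' @return an object of class `confusion_matrix`: an integer matrix with class
#'   labels as dimnames and attribute `n` (the total count).
#' @examples
#' cm <- confusion_matrix(rbind(c(2, 2, 2), c(5, 70, 2), c(0, 2, 15)))
#' n_obs(cm)
#' @export
confusion_matrix <- function(x, labels = NULL,
                             orientation = c("rows-predicted", "rows-true")) {
  orientation <- match.arg(orientation)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_input("`x` must be a numeric matrix of counts.")
  }
  if (nrow(x) != ncol(x)) {
    stop_format(sprintf("confusion matrix must be square; got %d x %d.",
                        nrow(x), ncol(x)))
  }
  r <- nrow(x)
  if (r < 2) {
    stop_input("a confusion matrix needs at least 2 classes (r >= 2).")
  }
  bad <- which(is.na(x) | x < 0 | x != round(x), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_format(sprintf(
      "cell (%d, %d) is not a nonnegative integer (value: %s).",
      bad[1, 1], bad[1, 2], format(x[bad[1, 1], bad[1, 2]])))
  }
  if (sum(x) < 1) stop_input("total count must be at least 1.")
  if (orientation == "rows-true") x <- t(x)
  if (is.null(labels)) {
    labels <- rownames(x) %||% colnames(x) %||% paste0("class_", seq_len(r))
  }
  labels <- as.character(labels)
  if (length(labels) != r || anyDuplicated(labels)) {
    stop_input(sprintf("`labels` must be %d distinct class identifiers.", r))
  }
  out <- matrix(as.integer(round(x)), r, r,
                dimnames = list(predicted = labels, true = labels))
  structure(out, n = sum(out), class = c("confusion_matrix", class(out)))
}

#' Tally a confusion matrix from true and predicted labels
#'
#' Cross-tabulates paired class labels into a [confusion_matrix()], with
#' rows = predicted and columns = true class. Accepts either a data frame plus
#' two column names (tidyverse style) or two bare vectors.
#'
#' @param data a data frame containing the label columns, or `NULL` to pass
#'   vectors directly via `truth` and `estimate`.
#' @param truth column (or vector) of true class labels.
#' @param estimate column (or vector) of predicted class labels.
#' @param levels optional class order; must contain every observed label.
#'   Defaults to the sorted union of observed labels.
#' @return a `confusion_matrix`; entry (i, j) counts samples predicted as
#'   class i whose true class is j.
#' @examples
#' confusion_from_labels(truth = c("A", "A", "B"), estimate = c("A", "B", "B"))
#' @export
confusion_from_labels <- function(data = NULL, truth, estimate, levels = NULL) {
  truth_v <- eval_tidy(enquo(truth), data)
  est_v <- eval_tidy(enquo(estimate), data)
  if (length(truth_v) != length(est_v)) {
    stop_input(sprintf("`truth` (%d) and `estimate` (%d) differ in length.",
                       length(truth_v), length(est_v)))
  }
  if (length(truth_v) < 1) stop_input("need at least one labelled sample.")
  truth_v <- as.character(truth_v)
  est_v <- as.character(est_v)
  observed <- sort(unique(c(truth_v, est_v)))
  if (is.null(levels)) {
    levels <- observed
  } else {
    levels <- as.character(levels)
    missing <- setdiff(observed, levels)
    if (length(missing) > 0) {
      stop_input(sprintf("label(s) not in `levels`: %s.",
                         paste(missing, collapse = ", ")))
    }
  }
  if (length(levels) < 2) {
    stop_input("fewer than 2 classes observed; supply `levels` with >= 2 classes.")
  }
  counts <- table(factor(est_v, levels = levels),
                  factor(truth_v, levels = levels))
  confusion_matrix(matrix(as.integer(counts), length(levels), length(levels)),
                   labels = levels)
}

#' Read a confusion matrix from a delimited text file
#'
#' @param path file containing a square numeric matrix.
#' @param delim `"auto"` (tab if the first line contains one, else comma),
#'   `"comma"`, or `"tab"`. No sniffing beyond the delimiter: headers and
#'   label columns are used only when flagged explicitly.
#' @param header logical; does the first row hold class labels?
#' @param label_column logical; does the first column hold class labels?
#' @param orientation see [confusion_matrix()].
#' @return a `confusion_matrix` in canonical rows-predicted orientation.
#' @export
read_confusion <- function(path, delim = c("auto", "comma", "tab"),
                           header = FALSE, label_column = FALSE,
                           orientation = c("rows-predicted", "rows-true")) {
  orientation <- match.arg(orientation)
  parsed <- parse_matrix_file(path, match.arg(delim), header, label_column)
  confusion_matrix(parsed$body, labels = parsed$labels,
                   orientation = orientation)
}

#' Read a probability table from a delimited text file
#'
#' Like [read_confusion()] but for a square table of cell probabilities
#' (entries must sum to 1 within 1e-9), e.g. a custom simulation scenario.
#'
#' @inheritParams read_confusion
#' @param n optional total sample size to attach.
#' @return a `prop_table`.
#' @export
read_prop_table <- function(path, delim = c("auto", "comma", "tab"),
                            header = FALSE, label_column = FALSE, n = NULL) {
  parsed <- parse_matrix_file(path, match.arg(delim), header, label_column)
  body <- parsed$body
  if (!is.null(parsed$labels) && length(parsed$labels) == nrow(body)) {
    dimnames(body) <- rep(list(parsed$labels), 2)
  }
  as_prop_table(body, n = n, tol = 1e-9)
}

parse_matrix_file <- function(path, delim, header, label_column) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_format(sprintf("empty file: %s", path))
  sep <- switch(delim,
                auto = if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ",",
                comma = ",",
                tab = "\t")
  cells <- strsplit(lines, sep, fixed = TRUE)
  cells <- lapply(cells, trimws)
  hdr <- NULL
  if (header) {
    hdr <- cells[[1]]
    cells <- cells[-1]
  }
  if (label_column) {
    row_labels <- vapply(cells, `[[`, character(1), 1)
    cells <- lapply(cells, `[`, -1)
    # header may or may not carry a leading cell above the label column
    if (header && length(hdr) == length(cells[[1]]) + 1) hdr <- hdr[-1]
  } else {
    row_labels <- NULL
  }
  widths <- lengths(cells)
  if (length(unique(widths)) != 1 || widths[1] != length(cells)) {
    stop_format(sprintf(
      "matrix body is not square: %d row(s) with width(s) %s.",
      length(cells), paste(unique(widths), collapse = "/")))
  }
  body <- suppressWarnings(
    matrix(as.numeric(unlist(cells)), nrow = length(cells), byrow = TRUE))
  na_cell <- which(is.na(body), arr.ind = TRUE)
  if (nrow(na_cell) > 0) {
    stop_format(sprintf("cell (%d, %d) is not numeric.",
                        na_cell[1, 1], na_cell[1, 2]))
  }
  list(body = body, labels = hdr %||% row_labels)
}

#' Write a confusion matrix to a delimited text file
#'
#' Inverse of [read_confusion()]: integer counts, one row per line, no header
#' or label column, so a written matrix reads back bit-exactly.
#'
#' @param cm a `confusion_matrix`.
#' @param path destination file.
#' @param delim `"comma"` (default) or `"tab"`.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(cm, path, delim = c("comma", "tab")) {
  delim <- match.arg(delim)
  cm <- as_counts(cm)
  sep <- if (delim == "comma") "," else "\t"
  ok <- tryCatch(suppressWarnings({
    writeLines(apply(unclass(cm), 1, paste, collapse = sep), path)
    TRUE
  }), error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write to %s", path))
  invisible(path)
}

#' Total number of classified samples
#' @param cm a `confusion_matrix`.
#' @return integer total count n.
#' @export
n_obs <- function(cm) {
  attr(as_counts(cm), "n")
}

#' Normalize counts to a table of cell probabilities
#'
#' Divides each cell by the total count n, giving the maximum-likelihood
#' estimate of the multinomial cell probabilities p_ij; all downstream scores
#' and variances plug these in.
#'
#' @param cm a `confusion_matrix` (or square count matrix).
#' @return an object of class `prop_table`: an r x r numeric matrix summing to
#'   1, with attribute `n` carrying the total count it came from.
#' @examples
#' prop_table(confusion_matrix(rbind(c(2, 2, 2), c(5, 70, 2), c(0, 2, 15))))
#' @export
prop_table <- function(cm) {
  cm <- as_counts(cm)
  n <- attr(cm, "n")
  p <- unclass(cm) / n
  structure(p, n = n, class = c("prop_table", "matrix"))
}

#' Coerce a probability matrix to a `prop_table`
#'
#' @param p a square numeric matrix of cell probabilities.
#' @param n optional total sample size to attach (needed later for variances).
#' @param tol tolerance on `abs(sum(p) - 1)`; default 1e-9.
#' @return a `prop_table`.
#' @export
as_prop_table <- function(p, n = NULL, tol = 1e-9) {
  if (inherits(p, "prop_table")) {
    if (!is.null(n)) attr(p, "n") <- n
    return(p)
  }
  if (is.data.frame(p)) p <- as.matrix(p)
  if (!is.matrix(p) || !is.numeric(p) || nrow(p) != ncol(p)) {
    stop_input("`p` must be a square numeric matrix.")
  }
  if (nrow(p) < 2) stop_input("a probability table needs r >= 2 classes.")
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop_input("all cell probabilities must lie in [0, 1].")
  }
  if (abs(sum(p) - 1) > tol) {
    stop_input(sprintf("cell probabilities sum to %.12f, not 1.", sum(p)))
  }
  if (is.null(dimnames(p))) {
    dimnames(p) <- rep(list(paste0("class_", seq_len(nrow(p)))), 2)
  }
  structure(unclass(p), n = n, class = c("prop_table", "matrix"))
}

# --- internal coercion helpers -----------------------------------------------

as_counts <- function(x) {
  if (inherits(x, "confusion_matrix")) return(x)
  if (inherits(x, "prop_table")) {
    stop_input("expected a matrix of counts, got a probability table.")
  }
  confusion_matrix(x)
}

# Accept a confusion_matrix, a prop_table, or a bare matrix (counts if it does
# not sum to ~1, probabilities otherwise; a perturbed near-sum-1 matrix from
# the finite-difference engine is deliberately NOT renormalized).
as_f1_table <- function(x) {
  if (inherits(x, "prop_table")) return(x)
  if (inherits(x, "confusion_matrix")) return(prop_table(x))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x) || nrow(x) != ncol(x)) {
    stop_input("`x` must be a square numeric matrix, confusion_matrix, or prop_table.")
  }
  if (abs(sum(x) - 1) < 0.01) {
    structure(unclass(x), n = NULL, class = c("prop_table", "matrix"))
  } else {
    prop_table(confusion_matrix(x))
  }
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix: %d classes, n = %d; rows = predicted, columns = true>\n",
              nrow(x), attr(x, "n")))
  print(matrix(x, nrow(x), ncol(x), dimnames = dimnames(x)))
  invisible(x)
}

#' @export
print.prop_table <- function(x, ...) {
  n <- attr(x, "n")
  cat(sprintf("<prop_table: %d classes%s>\n", nrow(x),
              if (is.null(n)) "" else sprintf(", n = %d", n)))
  print(matrix(x, nrow(x), ncol(x), dimnames = dimnames(x)))
  invisible(x)
}
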