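report_columns <- c("measure", "estimate", "variance", "se",
                    "ci_lower", "ci_upper", "alpha", "n", "r")

report_tibble <- function(x) {
  if (inherits(x, "f1_ci")) {
    est <- x$estimates
    est$n <- x$n
    est$r <- x$r
    return(est[report_columns])
  }
  if (is.data.frame(x)) {
    missing <- setdiff(c("measure", "estimate"), names(x))
    if (length(missing) > 0) {
      stop_input(sprintf("report is missing column(s): %s.",
                         paste(missing, collapse = ", ")))
    }
    for (col in setdiff(report_columns, names(x))) x[[col]] <- NA
    return(tibble::as_tibble(x)[report_columns])
  }
  stop_input("`x` must be an f1_ci object or a data frame of estimates.")
}

#' Write an estimate report to JSON or TSV
#'
#' Serializes a set of F1 estimates (point estimate, variance, standard error,
#' interval bounds, alpha, n, r per measure) so that reading the file back
#' reproduces every number to full stored precision. The JSON document is an
#' object with fields `package`, `version`, `seed` (optional provenance) and
#' `estimates`, an array with one record per measure; the TSV has one header
#' line and one row per measure.
#'
#' @param x an [f1_ci()] object, or a data frame with at least `measure` and
#'   `estimate` columns.
#' @param path destination file, or `""` for standard output.
#' @param format `"json"` or `"tsv"`.
#' @param seed optional master seed recorded in the JSON header.
#' @return `path`, invisibly.
#' @export
write_f1_report <- function(x, path, format = c("json", "tsv"), seed = NULL) {
  format <- match.arg(format)
  est <- report_tibble(x)
  if (nrow(est) == 0) stop_input("no estimates to report.")
  text <- if (format == "json") {
    doc <- list(package = "f1ci",
                version = as.character(packageVersion("f1ci")),
                estimates = est)
    if (!is.null(seed)) doc$seed <- as.integer(seed)
    jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), na = "null",
                     dataframe = "rows", pretty = TRUE)
  } else {
    header <- paste(names(est), collapse = "\t")
    body <- vapply(seq_len(nrow(est)), function(i) {
      paste(vapply(as.list(est[i, ]), format_report_value, character(1)),
            collapse = "\t")
    }, character(1))
    paste(c(header, body), collapse = "\n")
  }
  ok <- tryCatch(suppressWarnings({
    if (identical(path, "")) cat(text, "\n", sep = "") else
      writeLines(text, path)
    TRUE
  }), error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write report to %s", path))
  invisible(path)
}

format_report_value <- function(v) {
  if (is.character(v) || is.factor(v)) return(as.character(v))
  num <- suppressWarnings(as.numeric(v))
  if (is.na(num)) return(as.character(v))
  sprintf("%.17g", num)
}

#' Read back an estimate report written by [write_f1_report()]
#'
#' @param path report file (JSON or TSV; detected from content).
#' @return a tibble with the report columns.
#' @export
read_f1_report <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  first <- substr(trimws(readLines(path, n = 1, warn = FALSE)), 1, 1)
  if (identical(first, "{")) {
    doc <- jsonlite::fromJSON(path)
    est <- tibble::as_tibble(doc$estimates)
  } else {
    # parse numerics via strtod (exact) rather than the reader's fast path
    est <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  }
  for (col in intersect(report_columns[-1], names(est))) {
    est[[col]] <- as.numeric(est[[col]])
  }
  est
}
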