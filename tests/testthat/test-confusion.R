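test_that("confusion_from_labels tallies predicted x true correctly", {
  cm <- confusion_from_labels(truth = c("A", "A", "B"),
                              estimate = c("A", "B", "B"))
  expect_equal(unclass(cm)[, ], matrix(c(1L, 1L, 0L, 1L), 2, 2,
               dimnames = list(predicted = c("A", "B"), true = c("A", "B"))),
               ignore_attr = "n")
  expect_equal(n_obs(cm), 3L)

  # data-frame interface is equivalent
  df <- data.frame(y = c("A", "A", "B"), yhat = c("A", "B", "B"))
  expect_identical(unclass(confusion_from_labels(df, y, yhat)), unclass(cm))

  # tallied counts always sum to the number of samples
  set.seed(11)
  for (k in 1:10) {
    lab <- sample(letters[1:4], 50, replace = TRUE)
    pred <- sample(letters[1:4], 50, replace = TRUE)
    expect_equal(sum(confusion_from_labels(truth = lab, estimate = pred)), 50)
  }
})

test_that("confusion_from_labels reconstructs a known 3x3 table from 100 labels", {
  target <- unclass(example_counts())
  truth <- character(0)
  pred <- character(0)
  classes <- c("class_1", "class_2", "class_3")
  for (i in 1:3) for (j in 1:3) {
    k <- target[i, j]
    truth <- c(truth, rep(classes[j], k))
    pred <- c(pred, rep(classes[i], k))
  }
  cm <- confusion_from_labels(truth = truth, estimate = pred)
  expect_equal(unclass(cm)[, ], target[, ])
  expect_equal(n_obs(cm), 100L)
})

test_that("degenerate and malformed label input is rejected", {
  expect_error(confusion_from_labels(truth = "A", estimate = "A"),
               class = "f1ci_error_input")
  # a second class supplied through `levels` rescues the 1-label case
  cm <- confusion_from_labels(truth = "A", estimate = "A",
                              levels = c("A", "B"))
  expect_equal(dim(cm), c(2L, 2L))
  expect_error(confusion_from_labels(truth = c("A", "B"), estimate = "A"),
               class = "f1ci_error_input")
  expect_error(
    confusion_from_labels(truth = c("A", "Z"), estimate = c("A", "A"),
                          levels = c("A", "B")),
    "Z", class = "f1ci_error_input")
})

test_that("read_confusion parses delimited matrices and honors orientation", {
  f <- withr::local_tempfile(lines = c("2,2,2", "5,70,2", "0,2,15"),
                             fileext = ".csv")
  cm <- read_confusion(f)
  expect_equal(unclass(cm)[, ], unclass(example_counts())[, ])
  expect_equal(n_obs(cm), 100L)

  # rows-true input is transposed into canonical rows-predicted form
  cm_t <- read_confusion(f, orientation = "rows-true")
  expect_equal(unclass(cm_t)[, ], t(unclass(example_counts())[, ]),
               ignore_attr = TRUE)

  # tab-delimited with header row and label column
  f2 <- withr::local_tempfile(
    lines = c("a\tb", "x\t1\t2", "y\t3\t4"), fileext = ".tsv")
  cm2 <- read_confusion(f2, header = TRUE, label_column = TRUE)
  expect_equal(rownames(cm2), c("a", "b"))
  expect_equal(as.vector(cm2), c(1L, 3L, 2L, 4L))
})

test_that("read_confusion reports malformed input precisely", {
  f <- withr::local_tempfile(lines = c("1,2", "3"), fileext = ".csv")
  expect_error(read_confusion(f), "square", class = "f1ci_error_format")
  f2 <- withr::local_tempfile(lines = c("1,-2", "3,4"), fileext = ".csv")
  expect_error(read_confusion(f2), "\\(1, 2\\)", class = "f1ci_error_format")
  f3 <- withr::local_tempfile(lines = c("1,x", "3,4"), fileext = ".csv")
  expect_error(read_confusion(f3), class = "f1ci_error_format")
  expect_error(read_confusion(file.path(tempdir(), "nope.csv")),
               class = "f1ci_error_io")
})

test_that("write_confusion / read_confusion round-trip is bit-exact", {
  set.seed(21)
  for (r in c(2, 4, 6)) {
    cm <- random_counts(r)
    f <- withr::local_tempfile(fileext = ".csv")
    write_confusion(cm, f)
    expect_identical(unclass(read_confusion(f))[, ], unclass(cm)[, ])
  }
})

test_that("prop_table is the MLE plug-in and always sums to one", {
  pt <- prop_table(example_counts())
  expect_equal(pt[2, 2], 0.7)
  expect_equal(rowSums(pt)[[1]], 0.06)
  expect_equal(colSums(pt)[[1]], 0.07)
  expect_equal(attr(pt, "n"), 100L)

  expect_equal(unclass(prop_table(confusion_matrix(diag(10, 3)))),
               diag(1 / 3, 3), ignore_attr = TRUE)
  u <- prop_table(confusion_matrix(matrix(1, 3, 3)))
  expect_true(all(u == 1 / 9))
  expect_equal(unname(rowSums(u)), rep(1 / 3, 3))

  set.seed(31)
  for (k in 1:20) {
    pt <- prop_table(random_counts(sample(2:6, 1)))
    expect_lt(abs(sum(pt) - 1), 1e-12)
  }
})

test_that("constructors validate shape, values and labels", {
  expect_error(confusion_matrix(matrix(1, 2, 3)), "2 x 3",
               class = "f1ci_error_format")
  expect_error(confusion_matrix(matrix(1, 1, 1)), class = "f1ci_error_input")
  expect_error(confusion_matrix(matrix(c(1, 2, 3, 4.5), 2, 2)),
               class = "f1ci_error_format")
  expect_error(confusion_matrix(matrix(0L, 2, 2)), class = "f1ci_error_input")
  expect_error(confusion_matrix(matrix(1L, 2, 2), labels = c("a", "a")),
               class = "f1ci_error_input")
  expect_error(as_prop_table(matrix(0.3, 2, 2)), class = "f1ci_error_input")
  expect_silent(as_prop_table(matrix(0.25, 2, 2)))
})

test_that("estimate reports round-trip through JSON and TSV at full precision", {
  res <- f1_ci(example_counts())
  for (fmt in c("json", "tsv")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_f1_report(res, f, format = fmt)
    back <- read_f1_report(f)
    expect_equal(nrow(back), 3)
    expect_identical(back$measure, res$estimates$measure)
    expect_identical(back$estimate, res$estimates$estimate)
    expect_identical(back$variance, res$estimates$variance)
    expect_identical(back$ci_lower, res$estimates$ci_lower)
    expect_identical(back$ci_upper, res$estimates$ci_upper)
    expect_true(all(back$n == 100), info = fmt)
  }
  f <- withr::local_tempfile(fileext = ".json")
  write_f1_report(res, f, format = "json")
  doc <- jsonlite::fromJSON(f)
  expect_named(doc, c("package", "version", "estimates"))
  expect_setequal(names(doc$estimates),
                  c("measure", "estimate", "variance", "se", "ci_lower",
                    "ci_upper", "alpha", "n", "r"))
  expect_error(write_f1_report(res, "/nonexistent-dir/x.json"),
               class = "f1ci_error_io")
})
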