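#' Node test families
#'
#' Three families of binary node tests are supported, and a tree may mix
#' them freely:
#'
#' * **C4.5-style univariate tests.** Continuous: `attribute >= threshold`.
#'   Nominal: `attribute == category` (a binary equality test, keeping the
#'   tree binary while examining each distinct category as a candidate).
#' * **Top-Scoring-Pair (TSP):** `attribute1 < attribute2` — a rank
#'   comparison of two features within the same sample, robust to
#'   monotone normalisation differences.
#' * **Weighted TSP (WTSP):** `attribute1 < weight * attribute2` with
#'   `weight > 0`, detecting proportional (not just ordinal) shifts.
#'
#' An instance satisfying the test is routed to the **left** child;
#' otherwise right. Ties under TSP/WTSP (`v1 == w * v2`) fail the strict
#' inequality and go right. A nominal value outside the recorded category
#' set fails the equality and goes right.
#'
#' @param attribute,attribute1,attribute2 Attribute names.
#' @param threshold Numeric threshold (continuous C4.5 test).
#' @param category Category label (nominal C4.5 test).
#' @param weight Positive multiplier for the WTSP comparison.
#' @return A `split_test` object.
#' @examples
#' c45_test("g1", threshold = 3.5)
#' tsp_test("PPARGC1B", "SLC25A21_AS1")
#' wtsp_test("g1", "g2", weight = 1.25)
#' @name split_test
NULL

#' @rdname split_test
#' @export
c45_test <- function(attribute, threshold = NULL, category = NULL) {
  if (is.null(threshold) == is.null(category))
    stop_structural("c45_test needs exactly one of threshold or category")
  if (!is.null(threshold) && (!is.numeric(threshold) || !is.finite(threshold)))
    stop_structural("threshold must be a finite number")
  structure(
    list(family = "c45", attribute = as.character(attribute),
         mode = if (is.null(threshold)) "category" else "threshold",
         threshold = if (is.null(threshold)) NULL else as.numeric(threshold),
         category = if (is.null(category)) NULL else as.character(category)),
    class = c("c45_test", "split_test")
  )
}

#' @rdname split_test
#' @export
tsp_test <- function(attribute1, attribute2) {
  if (identical(as.character(attribute1), as.character(attribute2)))
    stop_structural("TSP test requires two distinct attributes")
  structure(
    list(family = "tsp", attribute1 = as.character(attribute1),
         attribute2 = as.character(attribute2)),
    class = c("tsp_test", "split_test")
  )
}

#' @rdname split_test
#' @export
wtsp_test <- function(attribute1, attribute2, weight) {
  if (identical(as.character(attribute1), as.character(attribute2)))
    stop_structural("WTSP test requires two distinct attributes")
  if (!is.numeric(weight) || !is.finite(weight) || weight <= 0)
    stop_structural("WTSP weight must be a positive finite number")
  structure(
    list(family = "wtsp", attribute1 = as.character(attribute1),
         attribute2 = as.character(attribute2), weight = as.numeric(weight)),
    class = c("wtsp_test", "split_test")
  )
}

# Check a test against a dataset's attribute schema.
validate_test <- function(test, dataset) {
  if (!inherits(test, "split_test")) stop_structural("not a split_test")
  if (test$family == "c45") {
    m <- attr_meta(dataset, test$attribute)
    if (test$mode == "threshold" && m$kind != "continuous")
      stop_structural(sprintf("threshold test requires continuous attribute; '%s' is nominal",
                              test$attribute))
    if (test$mode == "category" && m$kind != "nominal")
      stop_structural(sprintf("category test requires nominal attribute; '%s' is continuous",
                              test$attribute))
  } else {
    m1 <- attr_meta(dataset, test$attribute1)
    m2 <- attr_meta(dataset, test$attribute2)
    if (m1$kind != "continuous" || m2$kind != "continuous")
      stop_structural(sprintf("%s tests require two continuous attributes",
                              toupper(test$family)))
  }
  invisible(test)
}

# Vectorised routing: logical mask, TRUE = left, over `rows` of `dataset`.
route_rows <- function(test, dataset, rows = seq_len(n_samples(dataset))) {
  switch(test$family,
    c45 = {
      v <- dataset$data[[test$attribute]]
      if (is.null(v)) stop_structural(sprintf("unknown attribute '%s'", test$attribute))
      if (test$mode == "threshold") {
        if (!is.numeric(v))
          stop_structural(sprintf("threshold test on nominal attribute '%s'", test$attribute))
        v[rows] >= test$threshold
      } else {
        as.character(v[rows]) == test$category
      }
    },
    tsp = {
      v1 <- dataset$data[[test$attribute1]]
      v2 <- dataset$data[[test$attribute2]]
      if (is.null(v1) || is.null(v2))
        stop_structural("TSP test references an unknown attribute")
      v1[rows] < v2[rows]
    },
    wtsp = {
      v1 <- dataset$data[[test$attribute1]]
      v2 <- dataset$data[[test$attribute2]]
      if (is.null(v1) || is.null(v2))
        stop_structural("WTSP test references an unknown attribute")
      v1[rows] < test$weight * v2[rows]
    },
    stop_structural("unknown test family")
  )
}

#' Route one instance through a test
#'
#' @param test A `split_test`.
#' @param dataset A `retree_dataset` holding the instance.
#' @param row Row index of the instance.
#' @return `"left"` if the test's predicate holds, else `"right"`.
#' @export
route <- function(test, dataset, row) {
  if (route_rows(test, dataset, row)) "left" else "right"
}

#' Render a test as its canonical one-line string
#'
#' The canonical grammar (parseable back by [parse_test()]):
#' `"g1 >= 3.5"`, `"g1 == red"`, `"g1 < g2"`, `"g1 < 1.25 * g2"`.
#' Numbers are written in shortest round-trip decimal form.
#'
#' @param test A `split_test`.
#' @return A single string.
#' @export
render_test <- function(test) {
  switch(test$family,
    c45 = if (test$mode == "threshold")
            sprintf("%s >= %s", test$attribute, fmt_num(test$threshold))
          else sprintf("%s == %s", test$attribute, test$category),
    tsp = sprintf("%s < %s", test$attribute1, test$attribute2),
    wtsp = sprintf("%s < %s * %s", test$attribute1, fmt_num(test$weight),
                   test$attribute2)
  )
}

#' Parse a canonical test string
#'
#' Inverse of [render_test()] up to numeric formatting. Attribute names
#' are resolved (and type-checked) against `dataset`.
#'
#' @param text A string in the canonical test grammar.
#' @param dataset A `retree_dataset` providing the attribute schema.
#' @return A `split_test`.
#' @export
parse_test <- function(text, dataset) {
  s <- trimws(text)
  num_re <- "[-+]?(?:[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?)"
  name_re <- "[^<>=*[:space:]]+"

  m <- regmatches(s, regexec(sprintf("^(%s)\\s*>=\\s*(%s)$", name_re, num_re), s))[[1]]
  if (length(m)) {
    test <- c45_test(m[2], threshold = as.numeric(m[3]))
    return(validate_test(test, dataset))
  }
  m <- regmatches(s, regexec(sprintf("^(%s)\\s*==\\s*(.+)$", name_re), s))[[1]]
  if (length(m)) {
    test <- c45_test(m[2], category = trimws(m[3]))
    return(validate_test(test, dataset))
  }
  m <- regmatches(s, regexec(sprintf("^(%s)\\s*<\\s*(%s)\\s*\\*\\s*(%s)$",
                                     name_re, num_re, name_re), s))[[1]]
  if (length(m)) {
    test <- wtsp_test(m[2], m[4], weight = as.numeric(m[3]))
    return(validate_test(test, dataset))
  }
  m <- regmatches(s, regexec(sprintf("^(%s)\\s*<\\s*(%s)$", name_re, name_re), s))[[1]]
  if (length(m)) {
    test <- tsp_test(m[2], m[3])
    return(validate_test(test, dataset))
  }
  stop_parse(sprintf("cannot parse test expression: '%s'", text))
}

#' @export
print.split_test <- function(x, ...) {
  cat(sprintf("<%s test> %s\n", toupper(x$family), render_test(x)))
  invisible(x)
}

# Identity of two tests (used to de-duplicate suggestions).
same_test <- function(a, b) {
  identical(a[setdiff(names(a), "")], b[setdiff(names(b), "")])
}
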