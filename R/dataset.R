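#' Typed sample-by-attribute datasets
#'
#' A `retree_dataset` is a samples x attributes table with a designated
#' class column, per-attribute typing (continuous or nominal), and an
#' ignore list. Continuous attributes hold finite reals; nominal
#' attributes hold categories from a finite set recorded when the data
#' are loaded. The class-level ordering (first appearance in the
#' training file) fixes confusion-matrix layout and tie-breaking
#' everywhere downstream.
#'
#' @name retree_dataset
#' @keywords internal
NULL

new_retree_dataset <- function(data, attributes, class_name, class_levels,
                               labels, sample_ids, oov_levels = list()) {
  stopifnot(nrow(data) == length(labels), length(labels) == length(sample_ids))
  if (anyDuplicated(attributes$name))
    stop_format("duplicate attribute names in dataset")
  if (anyDuplicated(sample_ids)) stop_format("sample_ids must be unique")
  if (length(labels) < 1L) stop_input("dataset must contain at least one sample")
  if (any(labels < 1L | labels > length(class_levels)))
    stop_input("class label index out of range")
  if (class_name %in% attributes$name)
    stop_format(sprintf("class column '%s' may not also be an attribute", class_name))
  structure(
    list(data = data, attributes = attributes, class_name = class_name,
         class_levels = class_levels, labels = as.integer(labels),
         sample_ids = as.character(sample_ids), oov_levels = oov_levels),
    class = "retree_dataset"
  )
}

parse_finite <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  v[!is.finite(v)] <- NA_real_
  v
}

check_no_missing <- function(col, name) {
  bad <- which(is.na(col) | !nzchar(trimws(col)))
  if (length(bad))
    stop_data(sprintf("empty or missing value in column '%s', row %d", name, bad[1]))
}

# Shared typing core: `raw` is an all-character tibble (header already
# validated). Inference: a column is continuous iff every cell parses as a
# finite real; type_overrides win; forcing continuous onto unparseable
# cells is a data error naming row and column.
build_dataset <- function(raw, class_column, ignore = character(),
                          type_overrides = NULL, class_levels = NULL,
                          sample_ids = NULL) {
  nms <- names(raw)
  if (!class_column %in% nms)
    stop_config(sprintf("class column '%s' not found in header", class_column))
  missing_ign <- setdiff(ignore, nms)
  if (length(missing_ign))
    stop_config(sprintf("ignored attribute '%s' not found in header", missing_ign[1]))
  if (!is.null(type_overrides)) {
    type_overrides <- unlist(type_overrides)
    bad <- setdiff(names(type_overrides), nms)
    if (length(bad))
      stop_config(sprintf("type override names unknown attribute '%s'", bad[1]))
    if (!all(type_overrides %in% c("continuous", "nominal")))
      stop_config("type overrides must be 'continuous' or 'nominal'")
  }

  attr_names <- setdiff(nms, class_column)
  cls_raw <- as.character(raw[[class_column]])
  check_no_missing(cls_raw, class_column)
  lev <- if (is.null(class_levels)) unique(cls_raw) else class_levels
  if (!all(cls_raw %in% lev))
    stop_data(sprintf("class value '%s' not among the declared class levels",
                      setdiff(cls_raw, lev)[1]))
  labels <- match(cls_raw, lev)

  cols <- list()
  kinds <- character(length(attr_names))
  levels_list <- vector("list", length(attr_names))
  for (k in seq_along(attr_names)) {
    nm <- attr_names[k]
    x <- as.character(raw[[nm]])
    check_no_missing(x, nm)
    num <- parse_finite(x)
    forced <- type_overrides[nm]
    kind <- if (!is.null(forced) && !is.na(forced)) unname(forced)
            else if (!anyNA(num)) "continuous" else "nominal"
    if (kind == "continuous") {
      if (anyNA(num))
        stop_data(sprintf("value '%s' in column '%s', row %d is not a finite number",
                          x[which(is.na(num))[1]], nm, which(is.na(num))[1]))
      cols[[nm]] <- num
    } else {
      cols[[nm]] <- x
      levels_list[[k]] <- unique(x)
    }
    kinds[k] <- kind
  }

  attributes <- tibble::tibble(
    name = attr_names, kind = kinds, index = seq_along(attr_names),
    ignored = attr_names %in% ignore, levels = levels_list
  )
  new_retree_dataset(
    data = tibble::as_tibble(cols), attributes = attributes,
    class_name = class_column, class_levels = lev, labels = labels,
    sample_ids = sample_ids %||% as.character(seq_along(labels))
  )
}

#' Read a CSV file into a typed dataset
#'
#' Loads an RFC 4180 CSV with a header row. A column whose every cell
#' parses as a finite real becomes continuous; all other columns become
#' nominal, with their category set recorded in order of first
#' appearance. `type_overrides` wins over inference (use it to force
#' integer-coded categories to nominal). Ignored attributes are retained
#' in the dataset but excluded from every split search. Empty or
#' unparseable cells are a hard error: silent imputation would change
#' split statistics invisibly.
#'
#' @param path Path to a CSV file with a header row.
#' @param class_column Name of the class (decision) column.
#' @param ignore Character vector of attribute names to flag as ignored.
#' @param type_overrides Named character vector or list mapping attribute
#'   names to `"continuous"` or `"nominal"`.
#' @return A `retree_dataset`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("g1,g2,class", "1,5,A", "2,6,A", "5,1,B", "6,2,B"), f)
#' d <- read_csv_dataset(f, class_column = "class")
#' d$attributes
#' @export
read_csv_dataset <- function(path, class_column, ignore = character(),
                             type_overrides = NULL) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               name_repair = "minimal"))
  if (anyDuplicated(hdr))
    stop_format(sprintf("duplicate column name '%s' in header", hdr[duplicated(hdr)][1]))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         show_col_types = FALSE, name_repair = "minimal")
  if (nrow(raw) < 1L) stop_input("dataset has no rows")
  build_dataset(raw, class_column, ignore, type_overrides)
}

#' Build a dataset from an in-memory data frame
#'
#' Applies the same typing rules as [read_csv_dataset()] to a data frame:
#' cells are rendered to character and a column is continuous iff every
#' cell parses as a finite real, with `type_overrides` winning. Factor
#' columns are treated as nominal.
#'
#' @inheritParams read_csv_dataset
#' @param df A data frame containing the class column and the attributes.
#' @param class_levels Optional explicit class-level ordering (defaults to
#'   first appearance).
#' @param sample_ids Optional stable sample identifiers (default: row number).
#' @return A `retree_dataset`.
#' @export
as_retree_dataset <- function(df, class_column, ignore = character(),
                              type_overrides = NULL, class_levels = NULL,
                              sample_ids = NULL) {
  df <- tibble::as_tibble(df)
  if (anyDuplicated(names(df)))
    stop_format("duplicate column names in data frame")
  fct <- names(df)[vapply(df, is.factor, logical(1))]
  for (nm in setdiff(fct, names(type_overrides %||% character())))
    type_overrides <- c(type_overrides, stats::setNames("nominal", nm))
  raw <- tibble::as_tibble(lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  }))
  build_dataset(raw, class_column, ignore, type_overrides,
                class_levels = class_levels, sample_ids = sample_ids)
}

#' Write a dataset back to CSV
#'
#' Continuous values are written in shortest round-trip decimal form so
#' that re-reading reproduces them exactly.
#'
#' @param dataset A `retree_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_csv_dataset <- function(dataset, path) {
  out <- lapply(seq_len(nrow(dataset$attributes)), function(k) {
    col <- dataset$data[[k]]
    if (dataset$attributes$kind[k] == "continuous") fmt_num(col) else col
  })
  names(out) <- dataset$attributes$name
  out[[dataset$class_name]] <- dataset$class_levels[dataset$labels]
  readr::write_csv(tibble::as_tibble(out), path)
  invisible(path)
}

#' Align a test CSV to a training dataset's schema
#'
#' Reads a test CSV and coerces it to the training attribute types and
#' category sets. Columns are realigned to the training order; a missing
#' attribute or class column is a format error. A nominal test value
#' unseen in training is kept as a distinct out-of-vocabulary category
#' (recorded in the returned dataset's `oov_levels`); category tests
#' route such values to the right child. Test rows never influence tree
#' structure, labels, or split choice.
#'
#' @param train The training `retree_dataset` whose schema to match.
#' @param path Path to the test CSV.
#' @return A `retree_dataset` with the training attribute metadata.
#' @export
align_test_set <- function(train, path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               name_repair = "minimal"))
  if (anyDuplicated(hdr))
    stop_format(sprintf("duplicate column name '%s' in test header", hdr[duplicated(hdr)][1]))
  needed <- c(train$attributes$name, train$class_name)
  missing <- setdiff(needed, hdr)
  if (length(missing))
    stop_format(sprintf("test set is missing column '%s'", missing[1]))
  extra <- setdiff(hdr, needed)
  if (length(extra))
    message(sprintf("dropping %d test column(s) not in the training schema: %s",
                    length(extra), paste(extra, collapse = ", ")))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         show_col_types = FALSE, name_repair = "minimal")
  if (nrow(raw) < 1L) stop_input("test dataset has no rows")

  cls_raw <- as.character(raw[[train$class_name]])
  check_no_missing(cls_raw, train$class_name)
  unseen_cls <- setdiff(cls_raw, train$class_levels)
  if (length(unseen_cls))
    stop_data(sprintf("test class value '%s' was not seen in training", unseen_cls[1]))

  cols <- list()
  oov <- list()
  for (k in seq_len(nrow(train$attributes))) {
    nm <- train$attributes$name[k]
    x <- as.character(raw[[nm]])
    check_no_missing(x, nm)
    if (train$attributes$kind[k] == "continuous") {
      num <- parse_finite(x)
      if (anyNA(num))
        stop_data(sprintf("value '%s' in column '%s', row %d is not a finite number",
                          x[which(is.na(num))[1]], nm, which(is.na(num))[1]))
      cols[[nm]] <- num
    } else {
      cols[[nm]] <- x
      unseen <- setdiff(unique(x), train$attributes$levels[[k]])
      if (length(unseen)) oov[[nm]] <- unseen
    }
  }

  new_retree_dataset(
    data = tibble::as_tibble(cols), attributes = train$attributes,
    class_name = train$class_name, class_levels = train$class_levels,
    labels = match(cls_raw, train$class_levels),
    sample_ids = as.character(seq_along(cls_raw)), oov_levels = oov
  )
}

#' @export
print.retree_dataset <- function(x, ...) {
  cat(sprintf("<retree_dataset> %d samples x %d attributes (class '%s': %s)\n",
              length(x$labels), nrow(x$attributes), x$class_name,
              paste(x$class_levels, collapse = ", ")))
  kinds <- table(x$attributes$kind)
  cat(sprintf("  %s; %d ignored\n",
              paste(sprintf("%d %s", kinds, names(kinds)), collapse = ", "),
              sum(x$attributes$ignored)))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Flatten a dataset back to a tibble (attributes plus class column)
#' @param x A `retree_dataset`.
#' @param ... Unused.
#' @return A tibble.
#' @export
as_tibble.retree_dataset <- function(x, ...) {
  out <- x$data
  out[[x$class_name]] <- x$class_levels[x$labels]
  out
}

n_samples <- function(dataset) length(dataset$labels)

# Class counts (one per class level) of a row subset.
class_counts <- function(dataset, rows) {
  tabulate(dataset$labels[rows], nbins = length(dataset$class_levels))
}

attr_meta <- function(dataset, name) {
  i <- match(name, dataset$attributes$name)
  if (is.na(i)) stop_structural(sprintf("unknown attribute '%s'", name))
  dataset$attributes[i, ]
}
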