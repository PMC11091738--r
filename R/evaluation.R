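#' Evaluate a tree on a dataset
#'
#' Routes every row of `data` from the root to a unique leaf and reports
#' overall accuracy, the confusion matrix (rows = actual, columns =
#' predicted, in class-level order), per-node instance assignments (a
#' sample appears in its leaf's assignment and in every ancestor's), and
#' per-leaf accuracy (the fraction of the leaf's rows whose actual class
#' equals the leaf's predicted class).
#'
#' @param tree A `retree`.
#' @param data A `retree_dataset` conforming to the tree's schema.
#' @return A `retree_report`: list with `n`, `accuracy`, `confusion`,
#'   `node_assignments`, `leaf_accuracy`, and per-sample `predictions`.
#' @export
evaluate <- function(tree, data) {
  if (!inherits(data, "retree_dataset")) stop_input("data must be a retree_dataset")
  if (n_samples(data) < 1) stop_input("cannot evaluate on an empty dataset")
  check_schema(tree, data)
  K <- length(tree$class_levels)
  pred <- integer(n_samples(data))
  assignments <- list()
  leaf_acc <- numeric(0)

  recurse <- function(node, rows) {
    assignments[[node$id]] <<- sort(data$sample_ids[rows])
    if (node$kind == "leaf") {
      pred[rows] <<- node$predicted_class_index
      leaf_acc[[node$id]] <<- if (length(rows))
        mean(data$labels[rows] == node$predicted_class_index) else NA_real_
      return(invisible(NULL))
    }
    left <- route_rows(node$test, data, rows)
    recurse(node$left, rows[left])
    recurse(node$right, rows[!left])
  }
  recurse(tree$root, seq_len(n_samples(data)))

  conf <- matrix(0L, K, K, dimnames = list(actual = tree$class_levels,
                                           predicted = tree$class_levels))
  for (i in seq_len(K)) conf[i, ] <- tabulate(pred[data$labels == i], K)
  structure(
    list(n = n_samples(data),
         accuracy = sum(diag(conf)) / n_samples(data),
         confusion = conf,
         node_assignments = assignments,
         leaf_accuracy = leaf_acc,
         predictions = tree$class_levels[pred]),
    class = "retree_report"
  )
}

check_schema <- function(tree, data) {
  walk_nodes(tree$root, function(nd) {
    if (nd$kind == "internal") validate_test(nd$test, data)
  })
  if (!identical(data$class_levels, tree$class_levels))
    stop_structural("dataset class levels do not match the tree's")
  invisible(NULL)
}

#' Predict classes for a dataset
#'
#' @param object A `retree`.
#' @param data A `retree_dataset` conforming to the tree's schema.
#' @param ... Unused.
#' @return Character vector of predicted class levels, one per row.
#' @export
predict.retree <- function(object, data, ...) {
  if (n_samples(data) < 1) stop_input("cannot predict on an empty dataset")
  pred <- integer(n_samples(data))
  recurse <- function(node, rows) {
    if (!length(rows)) return(invisible(NULL))
    if (node$kind == "leaf") {
      pred[rows] <<- node$predicted_class_index
      return(invisible(NULL))
    }
    left <- route_rows(node$test, data, rows)
    recurse(node$left, rows[left])
    recurse(node$right, rows[!left])
  }
  recurse(object$root, seq_len(n_samples(data)))
  object$class_levels[pred]
}

#' @export
print.retree_report <- function(x, ...) {
  cat(sprintf("<retree_report> n=%d accuracy=%.4f\n", x$n, x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Tidy an evaluation report into confusion-matrix rows
#'
#' @param x A `retree_report`.
#' @param ... Unused.
#' @return A tibble with `actual`, `predicted`, `n` — one row per
#'   confusion-matrix cell.
#' @export
tidy.retree_report <- function(x, ...) {
  df <- as.data.frame.table(x$confusion, responseName = "n",
                            stringsAsFactors = FALSE)
  tibble::tibble(actual = df$actual, predicted = df$predicted,
                 n = as.integer(df$n))
}

#' One-row summary of an evaluation report
#'
#' @param x A `retree_report`.
#' @param ... Unused.
#' @return A tibble with `n`, `accuracy`, `n_correct`, `n_leaves_used`.
#' @export
glance.retree_report <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy,
                 n_correct = as.integer(sum(diag(x$confusion))),
                 n_leaves_used = sum(!is.na(x$leaf_accuracy)))
}
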