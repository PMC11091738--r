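#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

tree_layout <- function(tree) {
  leaf_x <- 0
  rows <- list()
  recurse <- function(node, parent_id) {
    if (node$kind == "leaf") {
      leaf_x <<- leaf_x + 1
      x <- leaf_x
      lab <- sprintf("%s\n(%s)", tree$class_levels[node$predicted_class_index],
                     paste(node$train_counts, collapse = "/"))
    } else {
      xl <- recurse(node$left, node$id)
      xr <- recurse(node$right, node$id)
      x <- (xl + xr) / 2
      lab <- render_test(node$test)
    }
    rows[[length(rows) + 1]] <<- tibble::tibble(
      id = node$id, parent = parent_id, x = x, y = -node$depth,
      kind = node$kind, label = lab)
    x
  }
  recurse(tree$root, NA_character_)
  dplyr::bind_rows(rows)
}

#' Plot a classification tree
#'
#' Draws the tree with internal nodes labelled by their canonical test
#' string and leaves by predicted class and class counts.
#'
#' @param object A `retree`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.retree <- function(object, ...) {
  lay <- tree_layout(object)
  edges <- dplyr::left_join(
    dplyr::filter(lay, !is.na(.data$parent)),
    dplyr::select(lay, parent = "id", px = "x", py = "y"),
    by = "parent")
  ggplot2::ggplot(lay, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$px, y = .data$py,
                                       xend = .data$x, yend = .data$y),
                          colour = "grey60") +
    ggplot2::geom_label(ggplot2::aes(label = .data$label,
                                     fill = .data$kind), size = 3) +
    ggplot2::scale_fill_manual(values = c(internal = "grey90",
                                          leaf = "lightsteelblue1"),
                               guide = "none") +
    ggplot2::theme_void()
}

#' @rdname autoplot.retree
#' @param x A `retree`.
#' @export
plot.retree <- function(x, ...) print(autoplot(x, ...))

#' Plot a confusion matrix
#'
#' @param object A `retree_report`.
#' @param ... Unused.
#' @return A ggplot object (tile heatmap, rows = actual, columns =
#'   predicted).
#' @export
autoplot.retree_report <- function(object, ...) {
  df <- tidy.retree_report(object)
  df$actual <- factor(df$actual, levels = rev(rownames(object$confusion)))
  df$predicted <- factor(df$predicted, levels = colnames(object$confusion))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                   fill = .data$n)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 guide = "none") +
    ggplot2::labs(x = "predicted", y = "actual",
                  title = sprintf("accuracy %.3f (n = %d)",
                                  object$accuracy, object$n)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
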