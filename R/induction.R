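#' Induction configuration
#'
#' Parameters of greedy top-down induction. "Maximum tree size" is
#' enforced both as a depth limit (`max_depth`) and as a budget on the
#' number of internal nodes (`max_nodes`); either can be used alone by
#' leaving the other large. `min_node_size` is enforced on **children**:
#' a candidate split is ineligible if either child would receive fewer
#' rows. `entropy_threshold` (bits) turns a node into a leaf once its
#' class entropy is at or below it; the default 0 stops only at pure
#' nodes. No post-pruning is ever applied: pruning is the user's `fold`.
#'
#' @param families Non-empty subset of `c("c45", "tsp", "wtsp")`
#'   (case-insensitive).
#' @param min_node_size Minimum rows per child (>= 1).
#' @param max_depth Maximum node depth; the root has depth 0.
#' @param max_nodes Budget on the number of internal nodes.
#' @param entropy_threshold Node entropy (bits) at or below which a node
#'   becomes a leaf.
#' @param suggestion_k Default number of top splits suggested per node.
#' @param max_pairs Optional cap on ordered pairs scanned by TSP/WTSP
#'   searches (variance-ranked attribute prefilter); `NULL` = exhaustive.
#' @return An `induction_config` object.
#' @export
induction_config <- function(families = "c45", min_node_size = 5,
                             max_depth = 10, max_nodes = 50,
                             entropy_threshold = 0, suggestion_k = 5,
                             max_pairs = NULL) {
  families <- normalize_families(families)
  chk <- function(x, nm, min) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min)
      stop_config(sprintf("%s must be a number >= %s", nm, min))
  }
  chk(min_node_size, "min_node_size", 1)
  chk(max_depth, "max_depth", 1)
  chk(max_nodes, "max_nodes", 1)
  chk(entropy_threshold, "entropy_threshold", 0)
  chk(suggestion_k, "suggestion_k", 1)
  if (!is.null(max_pairs)) chk(max_pairs, "max_pairs", 2)
  structure(
    list(families = families, min_node_size = as.integer(min_node_size),
         max_depth = as.integer(max_depth), max_nodes = as.integer(max_nodes),
         entropy_threshold = as.numeric(entropy_threshold),
         suggestion_k = as.integer(suggestion_k),
         max_pairs = if (is.null(max_pairs)) NULL else as.integer(max_pairs)),
    class = "induction_config"
  )
}

majority_class_index <- function(counts) which.max(counts)  # tie: lowest index

new_leaf <- function(id, counts, depth, reason = "none") {
  list(id = id, kind = "leaf", test = NULL, left = NULL, right = NULL,
       train_counts = as.integer(counts),
       predicted_class_index = majority_class_index(counts),
       depth = depth, stop_reason = reason)
}

new_internal <- function(id, test, counts, depth, left, right) {
  list(id = id, kind = "internal", test = test, left = left, right = right,
       train_counts = as.integer(counts), predicted_class_index = NULL,
       depth = depth)
}

#' Why a node stops splitting
#'
#' Reports the first stopping rule, in the fixed order `min_size` (the
#' node is too small for two legal children), `max_depth`, `entropy`,
#' `budget` (internal-node budget exhausted), `no_split` (no candidate
#' with positive information gain and both children at least
#' `min_node_size`), that fires for a node; `"none"` means the node will
#' split.
#'
#' @inheritParams best_c45_split
#' @param config An [induction_config()].
#' @param depth The node's depth (root = 0).
#' @param internal_count Internal nodes already created in the tree.
#' @return One of `"min_size"`, `"max_depth"`, `"entropy"`, `"budget"`,
#'   `"no_split"`, `"none"`.
#' @export
stopping_reason <- function(dataset, rows = seq_len(n_samples(dataset)),
                            config = induction_config(), depth = 0,
                            internal_count = 0) {
  counts <- class_counts(dataset, rows)
  if (length(rows) < 2L * config$min_node_size) return("min_size")
  if (depth >= config$max_depth) return("max_depth")
  if (entropy_bits(counts) <= config$entropy_threshold) return("entropy")
  if (internal_count >= config$max_nodes) return("budget")
  sp <- tryCatch(
    best_split(dataset, rows, config$families,
               min_child = config$min_node_size, max_pairs = config$max_pairs),
    retree_not_applicable_error = function(e) NULL)
  if (is.null(sp)) return("no_split")
  "none"
}

# Breadth-first induction over a task frontier. Each task is
# list(rows, depth, id). Internal nodes are counted in BFS creation
# order; once `max_nodes` is reached remaining frontier nodes become
# leaves. Returns an environment of node records keyed by id, to be
# assembled recursively.
induce_bfs <- function(dataset, tasks, config, internal_count = 0L) {
  store <- new.env(parent = emptyenv())
  queue <- tasks
  while (length(queue)) {
    task <- queue[[1]]; queue <- queue[-1]
    rows <- task$rows; depth <- task$depth; id <- task$id
    counts <- class_counts(dataset, rows)
    reason <- "none"
    sp <- NULL
    if (length(rows) < 2L * config$min_node_size) reason <- "min_size"
    else if (depth >= config$max_depth) reason <- "max_depth"
    else if (entropy_bits(counts) <= config$entropy_threshold) reason <- "entropy"
    else if (internal_count >= config$max_nodes) reason <- "budget"
    else {
      sp <- tryCatch(
        best_split(dataset, rows, config$families,
                   min_child = config$min_node_size,
                   max_pairs = config$max_pairs),
        retree_not_applicable_error = function(e) NULL)
      if (is.null(sp)) reason <- "no_split"
    }
    if (reason != "none") {
      assign(id, new_leaf(id, counts, depth, reason), envir = store)
    } else {
      internal_count <- internal_count + 1L
      left_mask <- route_rows(sp$test, dataset, rows)
      assign(id, list(id = id, kind = "internal", test = sp$test,
                      train_counts = as.integer(counts), depth = depth),
             envir = store)
      queue <- c(queue,
                 list(list(rows = rows[left_mask], depth = depth + 1L,
                           id = paste0(id, "L")),
                      list(rows = rows[!left_mask], depth = depth + 1L,
                           id = paste0(id, "R"))))
    }
  }
  store
}

assemble_node <- function(store, id) {
  nd <- get(id, envir = store)
  if (nd$kind == "leaf") return(nd)
  new_internal(nd$id, nd$test, nd$train_counts, nd$depth,
               assemble_node(store, paste0(id, "L")),
               assemble_node(store, paste0(id, "R")))
}

new_tree <- function(root, config, dataset) {
  structure(
    list(root = root, config = config,
         attributes = dataset$attributes, class_levels = dataset$class_levels,
         class_name = dataset$class_name),
    class = "retree"
  )
}

#' Induce a classification tree
#'
#' Top-down greedy binary induction: at each node the best split across
#' the enabled families is chosen by gain ratio (canonical tie-break) and
#' the node's rows are redirected to the two children; the process
#' repeats breadth-first until a stopping rule fires (see
#' [stopping_reason()] and [induction_config()]). No post-pruning is
#' applied; manual pruning is available as [fold()].
#'
#' @param dataset A `retree_dataset` (the training set).
#' @param config An [induction_config()].
#' @return A `retree` classification tree.
#' @examples
#' d <- simulate_planted(planted_pair(1, 2), n_samples = 60,
#'                       n_attributes = 5, seed = 1)
#' tree <- induce(d, induction_config(families = "tsp", min_node_size = 5))
#' tree
#' @export
induce <- function(dataset, config = induction_config()) {
  if (!inherits(dataset, "retree_dataset")) stop_input("dataset must be a retree_dataset")
  if (n_samples(dataset) < 1) stop_input("cannot induce from an empty dataset")
  if (config$entropy_threshold > log2(max(2, length(dataset$class_levels))) + 1e-12)
    stop_config("entropy_threshold exceeds log2(number of classes)")
  usable <- dataset$attributes[!dataset$attributes$ignored, ]
  has_any <- ("c45" %in% config$families && nrow(usable) > 0) ||
    (any(c("tsp", "wtsp") %in% config$families) &&
       sum(usable$kind == "continuous") >= 2)
  if (!has_any)
    stop_not_applicable("no eligible attributes for any enabled test family")
  store <- induce_bfs(dataset,
                      list(list(rows = seq_len(n_samples(dataset)),
                                depth = 0L, id = "r")),
                      config, internal_count = 0L)
  new_tree(assemble_node(store, "r"), config, dataset)
}

# ---- tree utilities --------------------------------------------------------

walk_nodes <- function(node, fn) {
  fn(node)
  if (node$kind == "internal") {
    walk_nodes(node$left, fn)
    walk_nodes(node$right, fn)
  }
  invisible(NULL)
}

count_internal <- function(node) {
  if (node$kind == "leaf") return(0L)
  1L + count_internal(node$left) + count_internal(node$right)
}

tree_depth <- function(node) {
  if (node$kind == "leaf") return(node$depth)
  max(tree_depth(node$left), tree_depth(node$right))
}

#' @export
print.retree <- function(x, ...) {
  n_int <- count_internal(x$root)
  cat(sprintf("<retree> %d internal node(s), %d leaf(s), depth %d, classes: %s\n",
              n_int, n_int + 1L, tree_depth(x$root),
              paste(x$class_levels, collapse = ", ")))
  print_node <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$kind == "leaf") {
      cat(sprintf("%s[%s] leaf -> %s (%s)\n", pad, node$id,
                  x$class_levels[node$predicted_class_index],
                  paste(node$train_counts, collapse = "/")))
    } else {
      cat(sprintf("%s[%s] %s (%s)\n", pad, node$id, render_test(node$test),
                  paste(node$train_counts, collapse = "/")))
      print_node(node$left, indent + 1)
      print_node(node$right, indent + 1)
    }
  }
  print_node(x$root, 0)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a tree into one row per node
#'
#' @param x A `retree`.
#' @param ... Unused.
#' @return A tibble with one row per node: `id`, `depth`, `kind`, `test`
#'   (canonical string or `NA` for leaves), `n`, per-class counts, and
#'   `predicted_class` for leaves.
#' @export
tidy.retree <- function(x, ...) {
  acc <- list()
  walk_nodes(x$root, function(nd) {
    acc[[length(acc) + 1]] <<- tibble::tibble(
      id = nd$id, depth = nd$depth, kind = nd$kind,
      test = if (nd$kind == "internal") render_test(nd$test) else NA_character_,
      n = sum(nd$train_counts),
      counts = list(stats::setNames(nd$train_counts, x$class_levels)),
      predicted_class = if (nd$kind == "leaf")
        x$class_levels[nd$predicted_class_index] else NA_character_
    )
  })
  dplyr::bind_rows(acc)
}

#' One-row summary of a tree
#'
#' @param x A `retree`.
#' @param ... Unused.
#' @return A tibble with `n_nodes`, `n_internal`, `n_leaves`, `depth`,
#'   `n_train`, and the enabled `families`.
#' @export
glance.retree <- function(x, ...) {
  n_int <- count_internal(x$root)
  tibble::tibble(
    n_nodes = 2L * n_int + 1L, n_internal = n_int, n_leaves = n_int + 1L,
    depth = tree_depth(x$root), n_train = sum(x$root$train_counts),
    families = paste(x$config$families, collapse = ",")
  )
}
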