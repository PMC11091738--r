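#' Interactive tree editing
#'
#' Deterministic, pure tree transformations mirroring interactive
#' editing: fold a subtree to a leaf (manual pruning), unfold a leaf by
#' one split or by full recursive induction, replace a node's test and
#' either re-route the preserved descendants ("update") or re-induce them
#' ("rebuild"). Every operation returns a new tree together with
#' freshly computed train (and optional test) reports — edits never leave
#' stale statistics, and the input tree is never mutated. Test-set rows
#' are routed and reported but never influence structure, labels, or
#' split choice.
#'
#' Nodes are addressed by a path of left/right steps from the root,
#' written `""` (root), `"L"`, `"L.R.L"`, ... — stable under
#' serialization.
#'
#' @name tree_edit
NULL

parse_node_path <- function(path) {
  if (length(path) == 1 && is.character(path)) {
    path <- trimws(path)
    if (path %in% c("", "root", "r")) return(character(0))
    path <- strsplit(path, "[./]")[[1]]
  }
  path <- toupper(as.character(path))
  if (!all(path %in% c("L", "R")))
    stop_structural("node path steps must be L or R")
  path
}

resolve_node <- function(tree, steps) {
  node <- tree$root
  for (s in steps) {
    if (node$kind != "internal")
      stop_structural(sprintf("node path does not resolve: leaf reached before step '%s'", s))
    node <- if (s == "L") node$left else node$right
  }
  node
}

replace_node <- function(node, steps, new_node) {
  if (!length(steps)) return(new_node)
  s <- steps[1]
  if (node$kind != "internal") stop_structural("node path does not resolve")
  if (s == "L") node$left <- replace_node(node$left, steps[-1], new_node)
  else node$right <- replace_node(node$right, steps[-1], new_node)
  node
}

rows_reaching <- function(tree, data, steps) {
  rows <- seq_len(n_samples(data))
  node <- tree$root
  for (s in steps) {
    if (node$kind != "internal") stop_structural("node path does not resolve")
    left <- route_rows(node$test, data, rows)
    rows <- if (s == "L") rows[left] else rows[!left]
    node <- if (s == "L") node$left else node$right
  }
  rows
}

# Recompute every node's counts and every leaf's predicted class from the
# training rows routed to it; a leaf left with no rows predicts the
# majority class of its nearest ancestor that still holds rows.
refresh_node <- function(node, data, rows, inherited_major) {
  counts <- class_counts(data, rows)
  node$train_counts <- as.integer(counts)
  major <- if (sum(counts) > 0) majority_class_index(counts) else inherited_major
  if (node$kind == "leaf") {
    node$predicted_class_index <- major
  } else {
    left <- route_rows(node$test, data, rows)
    node$left <- refresh_node(node$left, data, rows[left], major)
    node$right <- refresh_node(node$right, data, rows[!left], major)
  }
  node
}

refresh_tree <- function(tree, train) {
  tree$root <- refresh_node(tree$root, train, seq_len(n_samples(train)),
                            inherited_major = 1L)
  tree
}

make_edit_result <- function(tree, changed, train, test) {
  structure(
    list(tree = tree, changed_node = paste(changed, collapse = "."),
         train_report = evaluate(tree, train),
         test_report = if (is.null(test)) NULL else evaluate(tree, test)),
    class = "retree_edit"
  )
}

#' @export
print.retree_edit <- function(x, ...) {
  cat(sprintf("<retree_edit> changed node: '%s'\n",
              if (nzchar(x$changed_node)) x$changed_node else "(root)"))
  cat(sprintf("  train accuracy: %.4f\n", x$train_report$accuracy))
  if (!is.null(x$test_report))
    cat(sprintf("  test accuracy:  %.4f\n", x$test_report$accuracy))
  invisible(x)
}

#' Fold a subtree into a leaf (manual pruning)
#'
#' The addressed subtree is replaced by a leaf predicting the majority
#' class of the training rows reaching that node; all statistics are
#' recomputed. Folding a leaf is a no-op.
#'
#' @param tree A `retree`.
#' @param node Node path (`""` = root, else e.g. `"L.R"`).
#' @param train Training `retree_dataset`.
#' @param test Optional test `retree_dataset`.
#' @return A `retree_edit` with the new tree and refreshed reports.
#' @export
fold <- function(tree, node, train, test = NULL) {
  steps <- parse_node_path(node)
  nd <- resolve_node(tree, steps)
  if (nd$kind == "internal") {
    rows <- rows_reaching(tree, train, steps)
    leaf <- new_leaf(nd$id, class_counts(train, rows), nd$depth, "folded")
    tree$root <- replace_node(tree$root, steps, leaf)
    tree <- refresh_tree(tree, train)
  }
  make_edit_result(tree, steps, train, test)
}

#' Expand a leaf by one best split
#'
#' The leaf becomes an internal node carrying the best split found among
#' the chosen families (by default the tree's configured families; an
#' override lets this operation use a different algorithm than the
#' initial settings) with exactly two leaf children — no recursion.
#'
#' @inheritParams fold
#' @param family_override Optional subset of `c("c45","tsp","wtsp")` used
#'   instead of the tree's configured families.
#' @param config Induction configuration (defaults to the tree's).
#' @return A `retree_edit`.
#' @export
unfold_once <- function(tree, node, train, test = NULL,
                        family_override = NULL, config = tree$config) {
  steps <- parse_node_path(node)
  nd <- resolve_node(tree, steps)
  if (nd$kind != "leaf") stop_structural("unfold_once requires a leaf node")
  rows <- rows_reaching(tree, train, steps)
  fams <- if (is.null(family_override)) config$families
          else normalize_families(family_override)
  sp <- tryCatch(
    best_split(train, rows, fams, min_child = config$min_node_size,
               max_pairs = config$max_pairs),
    retree_not_applicable_error = function(e) NULL)
  if (is.null(sp))
    stop_not_applicable("no legal split exists at this leaf")
  left <- route_rows(sp$test, train, rows)
  internal <- new_internal(
    nd$id, sp$test, class_counts(train, rows), nd$depth,
    new_leaf(paste0(nd$id, "L"), class_counts(train, rows[left]),
             nd$depth + 1L, "unfolded"),
    new_leaf(paste0(nd$id, "R"), class_counts(train, rows[!left]),
             nd$depth + 1L, "unfolded"))
  tree$root <- replace_node(tree$root, steps, internal)
  make_edit_result(refresh_tree(tree, train), steps, train, test)
}

#' Expand a leaf into a full subtree
#'
#' Runs full recursive induction on the rows reaching the leaf, rooted at
#' that position. Depth is counted from the tree's root and the
#' internal-node budget is counted tree-wide, so unfolding never exceeds
#' the configured `max_nodes`.
#'
#' @inheritParams unfold_once
#' @return A `retree_edit`.
#' @export
unfold_all <- function(tree, node, train, test = NULL,
                       family_override = NULL, config = tree$config) {
  steps <- parse_node_path(node)
  nd <- resolve_node(tree, steps)
  if (nd$kind != "leaf") stop_structural("unfold_all requires a leaf node")
  rows <- rows_reaching(tree, train, steps)
  if (!is.null(family_override)) config$families <- normalize_families(family_override)
  existing <- count_internal(tree$root)
  store <- induce_bfs(train,
                      list(list(rows = rows, depth = nd$depth, id = nd$id)),
                      config, internal_count = existing)
  tree$root <- replace_node(tree$root, steps, assemble_node(store, nd$id))
  make_edit_result(refresh_tree(tree, train), steps, train, test)
}

#' Replace a node's test and re-route instances ("Update")
#'
#' The node's test is replaced while the descendant structure (all tests
#' below) is preserved; the instances that reached the node are
#' rearranged through the preserved subtree, every descendant's counts
#' are refreshed and every descendant leaf's predicted class is
#' recomputed as the majority of its re-routed rows (a leaf left empty
#' predicts its nearest ancestor's majority class). Reports for the
#' training and test sets are recomputed from scratch.
#'
#' @inheritParams fold
#' @param new_test A `split_test` (e.g. from [parse_test()]).
#' @return A `retree_edit`.
#' @export
update_test <- function(tree, node, new_test, train, test = NULL) {
  steps <- parse_node_path(node)
  nd <- resolve_node(tree, steps)
  if (nd$kind != "internal")
    stop_structural("update_test requires an internal node")
  validate_test(new_test, train)
  nd$test <- new_test
  tree$root <- replace_node(tree$root, steps, nd)
  make_edit_result(refresh_tree(tree, train), steps, train, test)
}

#' Replace a node's test and re-induce its children ("Rebuild")
#'
#' The node's test is set to `new_test` when supplied (otherwise the best
#' split is re-searched under `config`), and both children are re-induced
#' from scratch on the re-routed rows under `config` — unlike
#' [update_test()], the old descendant structure is discarded.
#'
#' @inheritParams update_test
#' @param new_test Optional `split_test`; when `NULL` the best split is
#'   re-searched.
#' @param config Induction configuration (defaults to the tree's).
#' @return A `retree_edit`.
#' @export
rebuild_subtree <- function(tree, node, new_test = NULL, train, test = NULL,
                            config = tree$config) {
  steps <- parse_node_path(node)
  nd <- resolve_node(tree, steps)
  if (nd$kind == "leaf" && is.null(new_test))
    stop_structural("rebuilding at a leaf requires new_test")
  rows <- rows_reaching(tree, train, steps)
  if (!is.null(new_test)) {
    validate_test(new_test, train)
    test_used <- new_test
  } else {
    sp <- tryCatch(
      best_split(train, rows, config$families,
                 min_child = config$min_node_size,
                 max_pairs = config$max_pairs),
      retree_not_applicable_error = function(e) NULL)
    if (is.null(sp))
      stop_not_applicable("no legal split exists at this node")
    test_used <- sp$test
  }
  elsewhere <- count_internal(tree$root) -
    (if (nd$kind == "internal") count_internal(nd) else 0L)
  left <- route_rows(test_used, train, rows)
  store <- induce_bfs(
    train,
    list(list(rows = rows[left], depth = nd$depth + 1L, id = paste0(nd$id, "L")),
         list(rows = rows[!left], depth = nd$depth + 1L, id = paste0(nd$id, "R"))),
    config, internal_count = elsewhere + 1L)
  internal <- new_internal(nd$id, test_used, class_counts(train, rows),
                           nd$depth, assemble_node(store, paste0(nd$id, "L")),
                           assemble_node(store, paste0(nd$id, "R")))
  tree$root <- replace_node(tree$root, steps, internal)
  make_edit_result(refresh_tree(tree, train), steps, train, test)
}
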