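edit_fixture <- function(seed = 7, n = 60, noise = 0.15) {
  d <- simulate_planted(planted_pair(1, 2), n_samples = n, n_attributes = 5,
                        noise_rate = noise, seed = seed)
  cfg <- induction_config(families = c("c45", "tsp"), min_node_size = 3,
                          max_depth = 5, max_nodes = 20)
  list(d = d, cfg = cfg, tree = induce(d, cfg))
}

test_that("fold collapses a subtree to a majority-class leaf", {
  fx <- edit_fixture()
  res <- fold(fx$tree, "", fx$d)
  expect_equal(res$tree$root$kind, "leaf")
  maj <- which.max(tabulate(fx$d$labels, 2))
  expect_equal(res$tree$root$predicted_class_index, maj)
  expect_equal(res$train_report$accuracy,
               max(tabulate(fx$d$labels, 2)) / length(fx$d$labels))

  # folding a leaf is a no-op
  res2 <- fold(res$tree, "", fx$d)
  expect_identical(export_tree(res2$tree), export_tree(res$tree))

  # folded accuracy equals the independent from-scratch evaluation
  if (fx$tree$root$kind == "internal") {
    resL <- fold(fx$tree, "L", fx$d)
    expect_equal(resL$train_report$accuracy,
                 oracle_evaluate(resL$tree, fx$d)$accuracy)
  }
  expect_error(fold(fx$tree, "L.L.L.L.L.L.L", fx$d),
               class = "retree_structural_error")
})

test_that("unfold_once installs exactly one split with two leaves", {
  d <- simulate_planted(planted_pair(2, 4), n_samples = 50, n_attributes = 5,
                        seed = 8)
  cfg <- induction_config(families = "c45", min_node_size = 2)
  single <- fold(induce(d, cfg), "", d)$tree

  # family override may differ from the tree's configured families
  res <- unfold_once(single, "", d, family_override = "tsp")
  expect_equal(res$tree$root$kind, "internal")
  expect_equal(res$tree$root$test$family, "tsp")
  expect_equal(render_test(res$tree$root$test), "g2 < g4")
  expect_equal(res$tree$root$left$kind, "leaf")
  expect_equal(res$tree$root$right$kind, "leaf")
  expect_equal(res$tree$root$left$depth, res$tree$root$depth + 1L)
  expect_equal(res$train_report$accuracy, 1.0)

  # a pure leaf offers no legal split
  pureL <- res$tree$root$left
  expect_error(unfold_once(res$tree, "L", d),
               class = "retree_not_applicable_error")
  # and the failed edit left the tree unchanged
  expect_identical(export_tree(res$tree),
                   export_tree(unfold_once(single, "", d,
                                           family_override = "tsp")$tree))
})

test_that("fold then unfold_all under the same config restores the subtree", {
  fx <- edit_fixture(seed = 17)
  skip_if(fx$tree$root$kind == "leaf")
  before <- export_tree(fx$tree)
  folded <- fold(fx$tree, "L", fx$d)$tree
  restored <- unfold_all(folded, "L", fx$d)$tree
  expect_identical(export_tree(restored), before)

  # unfold_all at the root of a single-leaf tree reproduces induce()
  folded_root <- fold(fx$tree, "", fx$d)$tree
  rebuilt <- unfold_all(folded_root, "", fx$d)$tree
  expect_identical(export_tree(rebuilt), before)
})

test_that("unfold_all respects the tree-wide internal-node budget", {
  d <- random_dataset(131, n = 30, p = 5)
  cfg <- induction_config(families = "c45", min_node_size = 1, max_depth = 8,
                          max_nodes = 4)
  tree <- induce(d, cfg)
  expect_lte(count_internal_nodes(tree), 4)
  td <- tidy(tree)
  leaves <- td$id[td$kind == "leaf"]
  for (id in leaves) {
    path <- gsub("r", "", id)
    path <- paste(strsplit(path, "")[[1]], collapse = ".")
    res <- tryCatch(unfold_all(tree, path, d),
                    retree_not_applicable_error = function(e) NULL)
    if (!is.null(res)) expect_lte(count_internal_nodes(res$tree), 4)
  }
})

test_that("update_test re-routes instances through the preserved structure", {
  dt <- toy_threshold()
  cfg <- induction_config(families = "c45", min_node_size = 1)
  tree <- induce(dt, cfg)
  expect_equal(render_test(tree$root$test), "g1 >= 3.5")

  # identical test: tree and reports unchanged
  same <- update_test(tree, "", c45_test("g1", threshold = 3.5), dt)
  expect_identical(export_tree(same$tree), export_tree(tree))
  expect_equal(same$train_report$accuracy, evaluate(tree, dt)$accuracy)

  # threshold beyond the data: all rows route right, the empty left leaf
  # predicts the root majority (tie -> first class level)
  moved <- update_test(tree, "", c45_test("g1", threshold = 10), dt)
  expect_equal(moved$tree$root$left$train_counts, c(0L, 0L))
  expect_equal(moved$tree$root$left$predicted_class_index, 1L)
  expect_equal(sum(moved$tree$root$right$train_counts), 4)
  expect_equal(moved$train_report$accuracy, 0.5)
})

test_that("edited trees never carry stale statistics", {
  for (seed in 141:150) {
    fx <- edit_fixture(seed = seed, n = 40)
    if (fx$tree$root$kind != "internal") next
    new_test <- tsp_test("g3", "g5")
    upd <- update_test(fx$tree, "", new_test, fx$d)
    scratch <- evaluate(upd$tree, fx$d)
    expect_identical(upd$train_report$confusion, scratch$confusion)
    expect_identical(upd$train_report$node_assignments,
                     scratch$node_assignments)
    expect_equal(upd$train_report$accuracy,
                 oracle_evaluate(upd$tree, fx$d)$accuracy)

    reb <- rebuild_subtree(fx$tree, "", new_test = new_test, train = fx$d)
    scratch2 <- evaluate(reb$tree, fx$d)
    expect_identical(reb$train_report$confusion, scratch2$confusion)
    # counts stored in the tree equal the re-routed assignment sizes
    td <- tidy(reb$tree)
    for (id in td$id)
      expect_equal(sum(td$counts[[match(id, td$id)]]),
                   length(scratch2$node_assignments[[id]]))
  }
})

test_that("rebuild re-induces children as greedy subtrees of their rows", {
  fx <- edit_fixture(seed = 23, n = 50)
  bad <- tsp_test("g4", "g5")   # a deliberately poor root test
  reb <- rebuild_subtree(fx$tree, "", new_test = bad, train = fx$d)
  expect_equal(render_test(reb$tree$root$test), "g4 < g5")

  # each child equals induction run on the rows that side receives
  mask <- vapply(seq_along(fx$d$labels), function(i)
    oracle_route_row(bad, fx$d, i), logical(1))
  for (side in c("L", "R")) {
    rows <- which(if (side == "L") mask else !mask)
    sub <- as_tibble(fx$d)[rows, ]
    dsub <- as_retree_dataset(sub, class_column = "class",
                              class_levels = fx$d$class_levels)
    ind <- induce(dsub, fx$cfg)
    child <- if (side == "L") reb$tree$root$left else reb$tree$root$right
    strip <- function(node) {
      if (node$kind == "leaf")
        return(list(kind = "leaf", pc = node$predicted_class_index,
                    counts = node$train_counts))
      list(kind = "internal", test = render_test(node$test),
           counts = node$train_counts,
           left = strip(node$left), right = strip(node$right))
    }
    expect_identical(strip(child), strip(ind$root))
  }

  # rebuild at the root with no new test reproduces induce()
  reb0 <- rebuild_subtree(fx$tree, "", train = fx$d, config = fx$cfg)
  expect_identical(export_tree(reb0$tree), export_tree(induce(fx$d, fx$cfg)))
})

test_that("update and rebuild differ exactly below the edited node", {
  fx <- edit_fixture(seed = 29, n = 80, noise = 0.25)
  skip_if(fx$tree$root$kind != "internal" ||
            fx$tree$root$left$kind != "internal")
  new_test <- tsp_test("g1", "g3")
  upd <- update_test(fx$tree, "", new_test, fx$d)
  reb <- rebuild_subtree(fx$tree, "", new_test = new_test, train = fx$d)
  # same root test either way
  expect_equal(render_test(upd$tree$root$test),
               render_test(reb$tree$root$test))
  # update preserves descendant tests
  old_tests <- tidy(fx$tree)$test
  expect_identical(tidy(upd$tree)$test[-1], old_tests[-1])
})

test_that("edit operations are pure: inputs are never mutated", {
  fx <- edit_fixture(seed = 31)
  before <- export_tree(fx$tree)
  invisible(fold(fx$tree, "", fx$d))
  invisible(update_test(fx$tree, "", tsp_test("g1", "g3"), fx$d))
  invisible(rebuild_subtree(fx$tree, "", new_test = tsp_test("g1", "g3"),
                            train = fx$d))
  expect_identical(export_tree(fx$tree), before)
})

test_that("test-set rows are reported but never shape the tree", {
  d <- simulate_planted(planted_pair(1, 2), n_samples = 60, n_attributes = 4,
                        noise_rate = 0.1, seed = 37)
  f <- tempfile(fileext = ".csv")
  write_csv_dataset(simulate_planted(planted_pair(1, 2), n_samples = 30,
                                     n_attributes = 4, noise_rate = 0.1,
                                     seed = 38), f)
  te <- align_test_set(d, f)
  cfg <- induction_config(families = "tsp", min_node_size = 3)
  tree <- induce(d, cfg)
  res <- fold(tree, "", d, test = te)
  expect_false(is.null(res$test_report))
  # same edit without the test set yields the identical tree
  res2 <- fold(tree, "", d)
  expect_identical(export_tree(res$tree), export_tree(res2$tree))
})
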