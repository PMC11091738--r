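cfg_small <- function(...) induction_config(min_node_size = 1, ...)

test_that("a planted pair rule is recovered as a root TSP split with pure leaves", {
  d <- simulate_planted(planted_pair(1, 2), n_samples = 40, n_attributes = 5,
                        seed = 3)
  tree <- induce(d, cfg_small(families = "tsp"))
  expect_equal(tree$root$kind, "internal")
  expect_equal(render_test(tree$root$test), "g1 < g2")
  expect_true(split_matches_cand(
    score_split_for_test(tree, d), oracle_best(d, seq_along(d$labels), "tsp"), d))
  expect_equal(tree$root$left$kind, "leaf")
  expect_equal(tree$root$right$kind, "leaf")
  expect_equal(evaluate(tree, d)$accuracy, 1.0)
})

test_that("stopping rules fire in their fixed order", {
  # entropy threshold at the root of balanced data -> single leaf
  bal <- as_retree_dataset(data.frame(g1 = c(1, 2, 3, 4), g2 = c(4, 3, 2, 1),
                                      class = c("A", "B", "A", "B")),
                           class_column = "class")
  t1 <- induce(bal, cfg_small(families = "c45", entropy_threshold = 1))
  expect_equal(t1$root$kind, "leaf")
  expect_equal(stopping_reason(bal, config = cfg_small(entropy_threshold = 1)),
               "entropy")

  # max_depth = 1 allows at most one internal node
  d <- random_dataset(61, n = 30, p = 4)
  t2 <- induce(d, cfg_small(families = "c45", max_depth = 1))
  expect_lte(count_internal_nodes(t2), 1)

  pure <- as_retree_dataset(data.frame(g1 = 1:6, class = "A"),
                            class_column = "class")
  expect_equal(stopping_reason(pure, config = cfg_small()), "entropy")
  small <- as_retree_dataset(data.frame(g1 = c(1, 2, 9), class = c("A", "A", "B")),
                             class_column = "class")
  expect_equal(stopping_reason(small, config = induction_config(min_node_size = 2)),
               "min_size")
  mixed <- toy_tsp()
  expect_equal(stopping_reason(mixed, config = cfg_small(families = "tsp")),
               "none")
  expect_equal(stopping_reason(mixed, config = cfg_small(families = "tsp"),
                               internal_count = 50), "budget")
})

test_that("children are forced to hold at least min_node_size rows", {
  d <- simulate_planted(planted_pair(1, 2), n_samples = 80, n_attributes = 4,
                        noise_rate = 0.1, seed = 9)
  tree <- induce(d, induction_config(families = "tsp", min_node_size = 10,
                                     max_depth = 10, max_nodes = 50))
  tidy_tree <- tidy(tree)
  leaves <- tidy_tree[tidy_tree$kind == "leaf", ]
  # a leaf smaller than min_node_size can only arise from a non-size rule
  # firing at a node that was never split, never from an installed split
  internal <- tidy_tree[tidy_tree$kind == "internal", ]
  for (id in internal$id) {
    kids <- tidy_tree[tidy_tree$id %in% paste0(id, c("L", "R")), ]
    expect_true(all(kids$n >= 10))
  }
})

test_that("induced trees conserve counts and strictly reduce entropy", {
  for (seed in 71:80) {
    d <- random_dataset(seed, n = 30, p = 5, with_nominal = seed %% 2 == 0)
    tree <- induce(d, cfg_small(families = c("c45", "tsp", "wtsp")))
    check_node <- function(node) {
      if (node$kind == "leaf") return(invisible(NULL))
      expect_equal(node$left$train_counts + node$right$train_counts,
                   node$train_counts)
      n <- sum(node$train_counts)
      nl <- sum(node$left$train_counts); nr <- sum(node$right$train_counts)
      wchild <- (nl / n) * oracle_entropy(node$left$train_counts) +
        (nr / n) * oracle_entropy(node$right$train_counts)
      expect_lt(wchild, oracle_entropy(node$train_counts))
      check_node(node$left); check_node(node$right)
    }
    check_node(tree$root)
    expect_lte(tree_max_depth(tree), 10)
  }
})

test_that("the internal-node budget bounds total tree size", {
  d <- random_dataset(81, n = 30, p = 5)
  tree <- induce(d, induction_config(families = "c45", min_node_size = 1,
                                     max_depth = 10, max_nodes = 3))
  expect_lte(count_internal_nodes(tree), 3)
  expect_lte(nrow(tidy(tree)), 2 * 3 + 1)
})

test_that("induction is fully deterministic, ids included", {
  d <- random_dataset(91, n = 30, p = 5)
  cfg <- cfg_small(families = c("c45", "tsp", "wtsp"))
  t1 <- induce(d, cfg)
  t2 <- induce(d, cfg)
  expect_identical(export_tree(t1), export_tree(t2))
  expect_identical(tidy(t1)$id, tidy(t2)$id)
})

test_that("degenerate inputs are rejected with typed errors", {
  d <- toy_nominal()  # only one nominal attribute: no TSP possible
  expect_error(induce(d, cfg_small(families = "tsp")),
               class = "retree_not_applicable_error")
  expect_error(induction_config(families = "c45", min_node_size = 0),
               class = "retree_config_error")
  expect_error(induce(toy_tsp(), cfg_small(entropy_threshold = 2)),
               class = "retree_config_error")
})
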