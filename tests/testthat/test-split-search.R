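# Frozen expected values below were computed with the direct-formula
# oracle in helper-oracle.R before being asserted against the package.

test_that("entropy matches hand-checkable values", {
  expect_equal(entropy_bits(c(8, 8)), 1.0)
  expect_equal(entropy_bits(c(4, 0)), 0.0)
  expect_equal(oracle_entropy(c(6, 2)), 0.8112781244591328)
  expect_equal(entropy_bits(c(6, 2)), 0.8112781244591328, tolerance = 1e-12)
  expect_error(entropy_bits(integer(0)), class = "retree_input_error")
  expect_error(entropy_bits(c(0, 0)), class = "retree_input_error")
})

test_that("gain ratio matches hand evaluation and rejects degenerate splits", {
  g <- gain_ratio(c(4, 4), c(4, 0), c(0, 4))
  expect_equal(g$gain_ratio, 1.0)
  expect_equal(g$info_gain, 1.0)
  expect_equal(g$split_info, 1.0)

  o <- oracle_score(c(6, 2), c(4, 0))
  expect_equal(o$gr, 0.31127812445913283)
  g2 <- gain_ratio(c(6, 2), c(4, 0), c(2, 2))
  expect_equal(g2$gain_ratio, o$gr, tolerance = 1e-12)
  expect_equal(g2$info_gain, o$ig, tolerance = 1e-12)
  expect_equal(g2$split_info, 1.0)

  expect_error(gain_ratio(c(5, 3), c(5, 3), c(0, 0)),
               class = "retree_degenerate_split_error")
  expect_error(gain_ratio(c(5, 3), c(4, 0), c(2, 2)),
               class = "retree_input_error")
})

test_that("continuous threshold search finds the optimal midpoint", {
  d <- toy_threshold()
  s <- best_c45_split(d, attribute = "g1")
  expect_equal(s$test$threshold, 3.5)
  expect_equal(s$gain_ratio, 1.0)
  expect_equal(s$left_counts, c(0L, 2L))  # left = g1 >= 3.5 = class B
  # pure node: no positive-gain split exists
  pure <- as_retree_dataset(data.frame(g1 = 1:4, class = "A"),
                            class_column = "class")
  expect_null(best_c45_split(pure, attribute = "g1"))
})

test_that("nominal search evaluates each category as a binary equality test", {
  d <- toy_nominal()
  s <- best_c45_split(d, attribute = "col")
  expect_equal(s$test$category, "red")
  expect_equal(s$gain_ratio, 1.0)
})

test_that("TSP search equals brute force on the 4-sample toy", {
  d <- toy_tsp()
  s <- best_tsp_split(d)
  expect_equal(s$test$attribute1, "g1")
  expect_equal(s$test$attribute2, "g2")
  expect_equal(s$gain_ratio, 1.0)
  expect_true(split_matches_cand(s, oracle_best(d, 1:4, "tsp"), d))

  # completion: attribute1 fixed restricts the scan to that first element
  s3 <- best_tsp_split(d, pair_filter = list(attribute1 = "g3"))
  expect_equal(s3$test$attribute1, "g3")
  o3 <- oracle_cands(d, 1:4, "tsp")
  o3 <- oracle_pick(o3[o3$a1 == 3, , drop = FALSE])
  expect_true(split_matches_cand(s3, o3, d))

  single <- as_retree_dataset(data.frame(g1 = c(1, 2), class = c("A", "B")),
                              class_column = "class")
  expect_error(best_tsp_split(single), class = "retree_not_applicable_error")
})

test_that("WTSP search scans ratio midpoints and skips non-positive pairs", {
  d <- toy_wtsp()
  s <- best_wtsp_split(d, pair_filter = list(attribute1 = "g1", attribute2 = "g2"))
  expect_equal(s$test$weight, 1.0)   # candidates {0.65, 1, 1.6}
  expect_equal(s$gain_ratio, 1.0)

  # zero in attribute2 disqualifies that pair but not the search
  dz <- as_retree_dataset(
    data.frame(g1 = c(1, 2, 3, 4), g2 = c(0, 1, 2, 3), g3 = c(2, 3, 1, 1),
               class = c("+", "+", "-", "-")),
    class_column = "class")
  sz <- best_wtsp_split(dz)
  expect_false(identical(sz$test$attribute2, "g2"))

  # weight fixed at 1 coincides with TSP on all-positive pairs
  d2 <- random_dataset(21, n = 20, p = 4)
  s_w1 <- best_wtsp_split(d2, pair_filter = list(weight = 1))
  s_tsp <- best_tsp_split(d2)
  if (!is.null(s_w1) && !is.null(s_tsp)) {
    expect_equal(s_w1$gain_ratio, s_tsp$gain_ratio, tolerance = 1e-12)
  }
})

test_that("suggestions pool families, sort by gain ratio, and obey the prefix property", {
  pure <- as_retree_dataset(data.frame(g1 = c(1, 2, 3, 4), g2 = c(2, 1, 4, 3),
                                       class = "A"),
                            class_column = "class")
  expect_equal(nrow(suggest_top_splits(pure, k = 3)), 0)

  d <- toy_tsp()
  top3 <- suggest_top_splits(d, families = c("c45", "tsp", "wtsp"), k = 3)
  expect_equal(top3$gain_ratio[1], 1.0)
  expect_true(all(diff(top3$gain_ratio) <= 1e-12))
  expect_false(any(duplicated(top3$test)))
  top1 <- suggest_top_splits(d, families = c("c45", "tsp", "wtsp"), k = 1)
  expect_identical(top1$test[1], top3$test[1])
})

test_that("partial tests are completed over their free parameters only", {
  dthr <- toy_threshold()
  s <- complete_partial_test(dthr, partial = partial_test("c45", attribute = "g1"))
  expect_equal(s$test$threshold, 3.5)

  dtsp <- toy_tsp()
  s2 <- complete_partial_test(dtsp, partial = partial_test("tsp", attribute1 = "g1"))
  expect_equal(s2$test$attribute2, "g2")

  dw <- toy_wtsp()
  s3 <- complete_partial_test(dw, partial = partial_test(
    "wtsp", attribute1 = "g1", attribute2 = "g2"))
  expect_equal(s3$test$attribute1, "g1")
  expect_equal(s3$test$weight, 1.0)

  expect_error(complete_partial_test(dw, partial = partial_test(
    "wtsp", attribute1 = "g1", attribute2 = "g1")),
    class = "retree_structural_error")
})

test_that("searches match brute-force enumeration on random small datasets", {
  for (seed in 1:30) {
    d <- random_dataset(seed, with_nominal = seed %% 3 == 0)
    rows <- seq_along(d$labels)
    oc45 <- oracle_cands(d, rows, "c45")
    for (a_idx in which(!d$attributes$ignored)) {
      s <- best_c45_split(d, rows, d$attributes$name[a_idx])
      oc <- oracle_pick(oc45[oc45$a1 == a_idx, , drop = FALSE])
      expect_true(split_matches_cand(s, oc, d))
    }
    s <- tryCatch(best_tsp_split(d, rows),
                  retree_not_applicable_error = function(e) NULL)
    expect_true(split_matches_cand(s, oracle_best(d, rows, "tsp"), d))
    s <- tryCatch(best_wtsp_split(d, rows),
                  retree_not_applicable_error = function(e) NULL)
    expect_true(split_matches_cand(s, oracle_best(d, rows, "wtsp"), d))
  }
})

test_that("gain ratio is invariant to row order and class-level order", {
  d <- random_dataset(31, n = 24, p = 4)
  s <- best_tsp_split(d)
  # permute rows
  perm <- withr::with_seed(1, sample(24))
  dp <- as_retree_dataset(as_tibble(d)[perm, ], class_column = "class",
                          class_levels = d$class_levels)
  sp <- best_tsp_split(dp)
  expect_equal(sp$gain_ratio, s$gain_ratio, tolerance = 1e-12)
  expect_equal(render_test(sp$test), render_test(s$test))
  # permute class levels
  dl <- as_retree_dataset(as_tibble(d), class_column = "class",
                          class_levels = rev(d$class_levels))
  sl <- best_tsp_split(dl)
  expect_equal(sl$gain_ratio, s$gain_ratio, tolerance = 1e-12)
})

test_that("returned splits always conserve counts with positive gain", {
  for (seed in 41:50) {
    d <- random_dataset(seed)
    parent <- tabulate(d$labels, length(d$class_levels))
    for (s in list(tryCatch(best_tsp_split(d),
                            retree_not_applicable_error = function(e) NULL),
                   tryCatch(best_wtsp_split(d),
                            retree_not_applicable_error = function(e) NULL))) {
      if (is.null(s)) next
      expect_equal(s$left_counts + s$right_counts, parent)
      expect_gt(s$info_gain, 0)
      expect_gt(s$split_info, 0)
      expect_equal(s$gain_ratio, s$info_gain / s$split_info, tolerance = 1e-12)
    }
  }
})

test_that("two identical searches return identical splits", {
  d <- random_dataset(55, n = 30, p = 6)
  expect_identical(best_wtsp_split(d), best_wtsp_split(d))
  expect_identical(suggest_top_splits(d, k = 5)$test,
                   suggest_top_splits(d, k = 5)$test)
})
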