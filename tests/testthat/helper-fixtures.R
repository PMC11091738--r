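# Fixtures built in code: small canonical toys from hand-checkable
# examples plus random dataset generators for property tests.

# 4 samples, 2 continuous attributes; class separable by g1 >= 3.5.
toy_threshold <- function() {
  as_retree_dataset(
    data.frame(g1 = c(1, 2, 5, 6), g2 = c(10, 20, 30, 40),
               class = c("A", "A", "B", "B")),
    class_column = "class")
}

# 4 samples where class == (g1 < g2); g3 is a decoy.
toy_tsp <- function() {
  as_retree_dataset(
    data.frame(g1 = c(1, 2, 3, 5), g2 = c(2, 3, 1, 2), g3 = c(5, 1, 4, 2),
               class = c("+", "+", "-", "-")),
    class_column = "class")
}

# ratios g1/g2: class + has {0.5, 0.8}, class - has {1.2, 2.0};
# weight candidates are the ratio midpoints {0.65, 1.0, 1.6}.
toy_wtsp <- function() {
  as_retree_dataset(
    data.frame(g1 = c(1.0, 1.6, 2.4, 4.0), g2 = c(2, 2, 2, 2),
               class = c("+", "+", "-", "-")),
    class_column = "class")
}

toy_nominal <- function() {
  as_retree_dataset(
    data.frame(col = c("red", "red", "blue", "green"),
               class = c("A", "A", "B", "B")),
    class_column = "class")
}

# Random mixed dataset for oracle-equivalence and invariant checks.
# Values positive so WTSP pairs are eligible; optionally one nominal
# column and occasional ties via rounding.
random_dataset <- function(seed, n = NULL, p = NULL, K = 2,
                           with_nominal = FALSE) {
  withr::with_seed(seed, {
    if (is.null(n)) n <- sample(4:30, 1)
    if (is.null(p)) p <- sample(2:6, 1)
    df <- as.data.frame(matrix(round(stats::rlnorm(n * p), 2), n, p))
    names(df) <- paste0("g", seq_len(p))
    if (with_nominal)
      df$c1 <- sample(c("red", "blue", "green"), n, replace = TRUE)
    df$class <- sample(LETTERS[seq_len(K)], n, replace = TRUE)
    if (length(unique(df$class)) < K)
      df$class[seq_len(K)] <- LETTERS[seq_len(K)]
    as_retree_dataset(df, class_column = "class")
  })
}

write_toy_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

count_internal_nodes <- function(tree) sum(tidy(tree)$kind == "internal")
tree_max_depth <- function(tree) max(tidy(tree)$depth)

# Wrap a tree's root test as a scored split via the independent router,
# so it can be compared against oracle candidates.
score_split_for_test <- function(tree, d) {
  K <- length(d$class_levels)
  mask <- vapply(seq_along(d$labels), function(i)
    oracle_route_row(tree$root$test, d, i), logical(1))
  left <- vapply(seq_len(K), function(k) sum(d$labels[mask] == k), integer(1))
  parent <- vapply(seq_len(K), function(k) sum(d$labels == k), integer(1))
  sc <- oracle_score(parent, left)
  list(test = tree$root$test, gain_ratio = sc$gr, info_gain = sc$ig)
}
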