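# Independent oracles: brute-force enumeration of the entire candidate
# space with plain loops and direct formulas, kept deliberately separate
# from the package's vectorised search path.

oracle_entropy <- function(counts) {
  n <- sum(counts)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

oracle_score <- function(parent, left) {
  right <- parent - left
  nL <- sum(left); nR <- sum(right); n <- nL + nR
  if (nL == 0 || nR == 0) return(NULL)
  ig <- oracle_entropy(parent) - (nL / n) * oracle_entropy(left) -
    (nR / n) * oracle_entropy(right)
  si <- -(nL / n) * log2(nL / n) - (nR / n) * log2(nR / n)
  list(gr = ig / si, ig = ig, si = si, nL = nL, nR = nR)
}

# Candidate midpoint between consecutive distinct sorted values, with the
# documented guard against the midpoint rounding onto the lower value.
oracle_mid <- function(lo, hi) {
  m <- (lo + hi) / 2
  if (m <= lo) hi else m
}

oracle_counts <- function(labels, K, mask) {
  vapply(seq_len(K), function(k) sum(labels[mask] == k), integer(1))
}

# Enumerate every candidate split of one family at a node. Returns a data
# frame with family, a1, a2, value, cat, gr, ig.
oracle_cands <- function(d, rows, family, min_child = 1) {
  K <- length(d$class_levels)
  y <- d$labels[rows]
  parent <- vapply(seq_len(K), function(k) sum(y == k), integer(1))
  out <- list()
  add <- function(a1, a2, value, cat, sc) {
    if (is.null(sc) || sc$ig <= 1e-12) return(invisible(NULL))
    if (sc$nL < min_child || sc$nR < min_child) return(invisible(NULL))
    out[[length(out) + 1]] <<- data.frame(family = family, a1 = a1, a2 = a2,
                                          value = value, cat = cat,
                                          gr = sc$gr, ig = sc$ig)
  }
  cont <- which(d$attributes$kind == "continuous" & !d$attributes$ignored)
  if (family == "c45") {
    for (a in which(!d$attributes$ignored)) {
      if (d$attributes$kind[a] == "continuous") {
        v <- d$data[[a]][rows]
        u <- sort(unique(v))
        if (length(u) < 2) next
        for (t in seq_len(length(u) - 1)) {
          thr <- oracle_mid(u[t], u[t + 1])
          left <- vapply(seq_len(K), function(k) sum(y == k & v >= thr), integer(1))
          add(a, 0, thr, 0, oracle_score(parent, left))
        }
      } else {
        x <- d$data[[a]][rows]
        levs <- d$attributes$levels[[a]]
        for (ci in seq_along(levs)) {
          if (!levs[ci] %in% x) next
          left <- vapply(seq_len(K), function(k) sum(y == k & x == levs[ci]), integer(1))
          add(a, 0, 0, ci, oracle_score(parent, left))
        }
      }
    }
  } else if (family == "tsp") {
    for (i in cont) for (j in cont) {
      if (i == j) next
      mask <- d$data[[i]][rows] < d$data[[j]][rows]
      left <- vapply(seq_len(K), function(k) sum(y == k & mask), integer(1))
      add(i, j, 0, 0, oracle_score(parent, left))
    }
  } else if (family == "wtsp") {
    for (i in cont) for (j in cont) {
      if (i == j) next
      v2 <- d$data[[j]][rows]
      if (any(v2 <= 0)) next
      r <- d$data[[i]][rows] / v2
      u <- sort(unique(r))
      if (length(u) < 2) next
      for (t in seq_len(length(u) - 1)) {
        w <- oracle_mid(u[t], u[t + 1])
        if (w <= 0) next
        left <- vapply(seq_len(K), function(k) sum(y == k & r < w), integer(1))
        add(i, j, w, 0, oracle_score(parent, left))
      }
    }
  }
  if (!length(out))
    return(data.frame(family = character(), a1 = numeric(), a2 = numeric(),
                      value = numeric(), cat = numeric(), gr = numeric(),
                      ig = numeric()))
  do.call(rbind, out)
}

# The documented canonical choice: highest gain ratio, then highest info
# gain (ties within 1e-12), then family order c45 < tsp < wtsp, then
# lowest attribute indices, smaller threshold/weight, earliest category.
oracle_pick <- function(cands) {
  if (!nrow(cands)) return(NULL)
  top <- cands[cands$gr >= max(cands$gr) - 1e-12, , drop = FALSE]
  top <- top[top$ig >= max(top$ig) - 1e-12, , drop = FALSE]
  fam <- match(top$family, c("c45", "tsp", "wtsp"))
  top[order(fam, top$a1, top$a2, top$value, top$cat)[1], , drop = FALSE]
}

oracle_best <- function(d, rows, family, min_child = 1) {
  oracle_pick(oracle_cands(d, rows, family, min_child))
}

# Does a retree_split match an oracle candidate row?
split_matches_cand <- function(split, cand, d) {
  if (is.null(split) || is.null(cand)) return(is.null(split) && is.null(cand))
  test <- split$test
  nm <- d$attributes$name
  if (test$family != cand$family) return(FALSE)
  ok <- switch(test$family,
    c45 = test$attribute == nm[cand$a1] &&
      if (cand$cat > 0) test$mode == "category" &&
        test$category == d$attributes$levels[[cand$a1]][cand$cat]
      else test$mode == "threshold" && abs(test$threshold - cand$value) <= 1e-12,
    tsp = test$attribute1 == nm[cand$a1] && test$attribute2 == nm[cand$a2],
    wtsp = test$attribute1 == nm[cand$a1] && test$attribute2 == nm[cand$a2] &&
      abs(test$weight - cand$value) <= 1e-12)
  ok && abs(split$gain_ratio - cand$gr) <= 1e-9
}

# ---- independent instance router / evaluator -------------------------------

oracle_route_row <- function(test, d, i) {
  v <- function(nm) d$data[[nm]][i]
  switch(test$family,
    c45 = if (test$mode == "threshold") v(test$attribute) >= test$threshold
          else as.character(v(test$attribute)) == test$category,
    tsp = v(test$attribute1) < v(test$attribute2),
    wtsp = v(test$attribute1) < test$weight * v(test$attribute2))
}

oracle_predict_row <- function(tree, d, i) {
  node <- tree$root
  while (node$kind == "internal")
    node <- if (oracle_route_row(node$test, d, i)) node$left else node$right
  tree$class_levels[node$predicted_class_index]
}

oracle_evaluate <- function(tree, d) {
  pred <- vapply(seq_along(d$labels), function(i) oracle_predict_row(tree, d, i),
                 character(1))
  actual <- d$class_levels[d$labels]
  K <- length(tree$class_levels)
  conf <- matrix(0L, K, K, dimnames = list(actual = tree$class_levels,
                                           predicted = tree$class_levels))
  for (i in seq_along(pred)) {
    conf[actual[i], pred[i]] <- conf[actual[i], pred[i]] + 1L
  }
  list(accuracy = mean(pred == actual), confusion = conf, predictions = pred)
}
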