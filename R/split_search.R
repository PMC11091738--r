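#' Entropy of a class-count vector, in bits
#'
#' `H = -sum(p_i log2 p_i)` over classes with positive count. Bounded by
#' `log2(#classes)`.
#'
#' @param counts Non-negative integer vector, one entry per class level.
#' @return Entropy in bits.
#' @examples
#' entropy_bits(c(8, 8)) # 1
#' entropy_bits(c(4, 0)) # 0
#' @export
entropy_bits <- function(counts) {
  if (length(counts) == 0) stop_input("empty class-count vector")
  if (any(counts < 0)) stop_input("negative class count")
  n <- sum(counts)
  if (n < 1) stop_input("entropy of an empty node is undefined")
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Gain ratio of a binary split
#'
#' `info_gain = H(parent) - (nL/n) H(left) - (nR/n) H(right)`;
#' `split_info` is the entropy of the branch-size distribution; the gain
#' ratio is their quotient. A split with an empty side is degenerate
#' (its split information would be zero) and is rejected here and
#' excluded from every search.
#'
#' @param parent,left,right Class-count vectors; `left + right` must equal
#'   `parent` elementwise.
#' @return A list with `gain_ratio`, `info_gain`, `split_info`.
#' @examples
#' gain_ratio(c(4, 4), c(4, 0), c(0, 4)) # perfect balanced split: all 1
#' @export
gain_ratio <- function(parent, left, right) {
  if (length(left) != length(parent) || length(right) != length(parent))
    stop_input("count vectors must share one entry per class level")
  if (!all(left + right == parent))
    stop_input("left + right counts must sum to the parent counts")
  nL <- sum(left); nR <- sum(right); n <- nL + nR
  if (nL == 0 || nR == 0)
    stop_degenerate("split leaves one side empty (split information would be 0)")
  ig <- entropy_bits(parent) -
    (nL / n) * entropy_bits(left) - (nR / n) * entropy_bits(right)
  si <- -(nL / n) * log2(nL / n) - (nR / n) * log2(nR / n)
  list(gain_ratio = ig / si, info_gain = ig, split_info = si)
}

# Row-wise entropy of a candidates x classes count matrix.
ent_rows <- function(mat) {
  n <- rowSums(mat)
  p <- mat / n
  t0 <- p * log2(p)
  t0[!is.finite(t0)] <- 0
  h <- -rowSums(t0)
  h[n == 0] <- NA_real_
  h
}

# Vectorised scoring of candidate left-count matrices against one parent.
# Returns per-candidate gain ratio / info gain / split info; candidates
# with an empty side get NA.
score_left_counts <- function(parent, left_mat) {
  left_mat <- matrix(left_mat, ncol = length(parent))
  n <- sum(parent)
  hp <- entropy_bits(parent)
  right_mat <- matrix(rep(parent, each = nrow(left_mat)),
                      nrow = nrow(left_mat)) - left_mat
  nL <- rowSums(left_mat); nR <- n - nL
  ok <- nL > 0 & nR > 0
  ig <- si <- gr <- rep(NA_real_, nrow(left_mat))
  if (any(ok)) {
    pl <- nL[ok] / n; pr <- nR[ok] / n
    ig[ok] <- hp - pl * ent_rows(left_mat[ok, , drop = FALSE]) -
      pr * ent_rows(right_mat[ok, , drop = FALSE])
    si[ok] <- -(pl * log2(pl) + pr * log2(pr))
    gr[ok] <- ig[ok] / si[ok]
  }
  list(gr = gr, ig = ig, si = si, nL = nL, nR = nR, ok = ok)
}

new_scored_split <- function(test, gr, ig, si, left_counts, right_counts) {
  structure(
    list(test = test, gain_ratio = gr, info_gain = ig, split_info = si,
         left_counts = as.integer(left_counts),
         right_counts = as.integer(right_counts)),
    class = "retree_split"
  )
}

#' @export
print.retree_split <- function(x, ...) {
  cat(sprintf("<split> %s  gain_ratio=%.4f info_gain=%.4f (n_left=%d, n_right=%d)\n",
              render_test(x$test), x$gain_ratio, x$info_gain,
              sum(x$left_counts), sum(x$right_counts)))
  invisible(x)
}

# ---- candidate enumeration -------------------------------------------------
# Candidate tables share columns: family ("c45","tsp","wtsp"), a1, a2
# (attribute indices; a2 = 0 for c45), value (threshold or weight; 0 for
# tsp), cat (category index; 0 otherwise), gr, ig, si, nL.
# Only non-degenerate candidates with info_gain > SCORE_TOL and both
# children >= min_child are emitted.

empty_cands <- function() {
  data.frame(family = character(), a1 = integer(), a2 = integer(),
             value = numeric(), cat = integer(), gr = numeric(),
             ig = numeric(), si = numeric(), nL = numeric())
}

# Prefix class-count matrix of labels in a given order (n x K).
prefix_counts <- function(labels_ord, K) {
  n <- length(labels_ord)
  M <- matrix(0L, n, K)
  M[cbind(seq_len(n), labels_ord)] <- 1L
  apply(M, 2, cumsum)
}

# Midpoint between two consecutive distinct sorted values; guarded so the
# resulting predicate reproduces the intended partition even when the
# midpoint rounds onto the lower value.
mid_guarded <- function(lo, hi) {
  m <- (lo + hi) / 2
  ifelse(m <= lo, hi, m)
}

cands_c45 <- function(dataset, rows, attr_index, min_child = 1) {
  K <- length(dataset$class_levels)
  y <- dataset$labels[rows]
  parent <- tabulate(y, K)
  kind <- dataset$attributes$kind[attr_index]
  if (kind == "continuous") {
    v <- dataset$data[[attr_index]][rows]
    ord <- order(v, method = "radix")
    vs <- v[ord]
    b <- which(diff(vs) > 0)
    if (!length(b)) return(empty_cands())
    cum <- prefix_counts(y[ord], K)
    left_mat <- matrix(rep(parent, each = length(b)), nrow = length(b)) -
      cum[b, , drop = FALSE]                     # left = values >= threshold
    thr <- mid_guarded(vs[b], vs[b + 1])
    sc <- score_left_counts(parent, left_mat)
    keep <- sc$ok & sc$ig > SCORE_TOL & sc$nL >= min_child & sc$nR >= min_child
    if (!any(keep)) return(empty_cands())
    data.frame(family = "c45", a1 = attr_index, a2 = 0L, value = thr[keep],
               cat = 0L, gr = sc$gr[keep], ig = sc$ig[keep], si = sc$si[keep],
               nL = sc$nL[keep])
  } else {
    x <- dataset$data[[attr_index]][rows]
    levs <- dataset$attributes$levels[[attr_index]]
    present <- levs[levs %in% unique(x)]
    if (!length(present)) return(empty_cands())
    left_mat <- t(vapply(present,
                         function(cat) tabulate(y[x == cat], K),
                         integer(K)))
    sc <- score_left_counts(parent, left_mat)
    keep <- sc$ok & sc$ig > SCORE_TOL & sc$nL >= min_child & sc$nR >= min_child
    if (!any(keep)) return(empty_cands())
    data.frame(family = "c45", a1 = attr_index, a2 = 0L, value = 0,
               cat = match(present, levs)[keep], gr = sc$gr[keep],
               ig = sc$ig[keep], si = sc$si[keep], nL = sc$nL[keep])
  }
}

# Continuous, non-ignored attribute indices; `force_keep` (indices) are
# retained even under the variance prefilter.
tsp_eligible <- function(dataset, rows, max_pairs = NULL, force_keep = integer()) {
  elig <- which(dataset$attributes$kind == "continuous" &
                  !dataset$attributes$ignored)
  if (!is.null(max_pairs) && length(elig) * (length(elig) - 1L) > max_pairs) {
    m <- max(2L, floor((1 + sqrt(1 + 4 * max_pairs)) / 2))
    vr <- vapply(elig, function(j) stats::var(dataset$data[[j]][rows]), numeric(1))
    keep <- elig[order(-vr, elig)][seq_len(min(m, length(elig)))]
    elig <- sort(unique(c(keep, intersect(force_keep, elig))))
  }
  elig
}

resolve_cont_attr <- function(dataset, name) {
  m <- attr_meta(dataset, name)
  if (m$kind != "continuous")
    stop_structural(sprintf("attribute '%s' is not continuous", name))
  m$index
}

cands_tsp <- function(dataset, rows, min_child = 1, pair_filter = NULL,
                      max_pairs = NULL) {
  K <- length(dataset$class_levels)
  y <- dataset$labels[rows]
  parent <- tabulate(y, K)
  f1 <- if (!is.null(pair_filter$attribute1))
    resolve_cont_attr(dataset, pair_filter$attribute1) else NULL
  f2 <- if (!is.null(pair_filter$attribute2))
    resolve_cont_attr(dataset, pair_filter$attribute2) else NULL
  if (!is.null(f1) && !is.null(f2) && f1 == f2)
    stop_structural("TSP test requires two distinct attributes")
  elig <- tsp_eligible(dataset, rows,
                       max_pairs = if (is.null(f1) && is.null(f2)) max_pairs,
                       force_keep = c(f1, f2))
  if (is.null(f1) && is.null(f2) && length(elig) < 2L)
    stop_not_applicable("TSP search needs at least two eligible continuous attributes")
  A1 <- f1 %||% elig
  A2 <- f2 %||% elig
  if (sum(vapply(A1, function(i) length(setdiff(A2, i)), integer(1))) == 0L)
    stop_not_applicable("no eligible attribute pair for a TSP split")

  Y <- matrix(0L, length(rows), K)
  Y[cbind(seq_along(rows), y)] <- 1L
  out <- vector("list", length(A1))
  for (ii in seq_along(A1)) {
    i <- A1[ii]
    js <- setdiff(A2, i)
    if (!length(js)) next
    v1 <- dataset$data[[i]][rows]
    left <- vapply(js, function(j) v1 < dataset$data[[j]][rows],
                   logical(length(rows)))
    left_mat <- t(crossprod(Y, matrix(left, ncol = length(js))))
    sc <- score_left_counts(parent, left_mat)
    keep <- sc$ok & sc$ig > SCORE_TOL & sc$nL >= min_child & sc$nR >= min_child
    if (!any(keep)) next
    out[[ii]] <- data.frame(family = "tsp", a1 = i, a2 = js[keep], value = 0,
                            cat = 0L, gr = sc$gr[keep], ig = sc$ig[keep],
                            si = sc$si[keep], nL = sc$nL[keep])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_cands())
  do.call(rbind, out)
}

cands_wtsp <- function(dataset, rows, min_child = 1, pair_filter = NULL,
                       max_pairs = NULL, keep_per_pair = 1L) {
  K <- length(dataset$class_levels)
  y <- dataset$labels[rows]
  parent <- tabulate(y, K)
  f1 <- if (!is.null(pair_filter$attribute1))
    resolve_cont_attr(dataset, pair_filter$attribute1) else NULL
  f2 <- if (!is.null(pair_filter$attribute2))
    resolve_cont_attr(dataset, pair_filter$attribute2) else NULL
  fw <- pair_filter$weight
  if (!is.null(fw) && (!is.numeric(fw) || fw <= 0))
    stop_structural("fixed WTSP weight must be positive")
  if (!is.null(f1) && !is.null(f2) && f1 == f2)
    stop_structural("WTSP test requires two distinct attributes")
  elig <- tsp_eligible(dataset, rows,
                       max_pairs = if (is.null(f1) && is.null(f2)) max_pairs,
                       force_keep = c(f1, f2))
  if (is.null(f1) && is.null(f2) && length(elig) < 2L)
    stop_not_applicable("WTSP search needs at least two eligible continuous attributes")
  A1 <- f1 %||% elig
  A2 <- f2 %||% elig
  if (sum(vapply(A1, function(i) length(setdiff(A2, i)), integer(1))) == 0L)
    stop_not_applicable("no eligible attribute pair for a WTSP split")

  # a pair is eligible only when attribute2 is strictly positive on every
  # row of the node (ratios are otherwise undefined for expression data)
  pos <- vapply(seq_len(nrow(dataset$attributes)),
                function(j) dataset$attributes$kind[j] == "continuous" &&
                  all(dataset$data[[j]][rows] > 0), logical(1))

  res <- list(); ri <- 0L
  for (i in A1) {
    v1 <- dataset$data[[i]][rows]
    for (j in setdiff(A2, i)) {
      if (!pos[j]) next
      r <- v1 / dataset$data[[j]][rows]
      if (!is.null(fw)) {
        lc <- tabulate(y[r < fw], K)
        sc <- score_left_counts(parent, matrix(lc, nrow = 1))
        if (sc$ok && sc$ig > SCORE_TOL && sc$nL >= min_child && sc$nR >= min_child) {
          ri <- ri + 1L
          res[[ri]] <- data.frame(family = "wtsp", a1 = i, a2 = j, value = fw,
                                  cat = 0L, gr = sc$gr, ig = sc$ig,
                                  si = sc$si, nL = sc$nL)
        }
        next
      }
      ord <- order(r, method = "radix")
      rs <- r[ord]
      b <- which(diff(rs) > 0)
      if (!length(b)) next
      w <- mid_guarded(rs[b], rs[b + 1])
      posw <- w > 0
      if (!any(posw)) next
      b <- b[posw]; w <- w[posw]
      cum <- prefix_counts(y[ord], K)
      left_mat <- cum[b, , drop = FALSE]          # left = ratio < weight
      sc <- score_left_counts(parent, left_mat)
      keep <- which(sc$ok & sc$ig > SCORE_TOL &
                      sc$nL >= min_child & sc$nR >= min_child)
      if (!length(keep)) next
      o <- keep[order(-sc$gr[keep], -sc$ig[keep], w[keep])]
      o <- o[seq_len(min(keep_per_pair, length(o)))]
      ri <- ri + 1L
      res[[ri]] <- data.frame(family = "wtsp", a1 = i, a2 = j, value = w[o],
                              cat = 0L, gr = sc$gr[o], ig = sc$ig[o],
                              si = sc$si[o], nL = sc$nL[o])
    }
  }
  if (!ri) return(empty_cands())
  do.call(rbind, res[seq_len(ri)])
}

# ---- canonical choice ------------------------------------------------------
# Global tie-break: higher gain ratio, then higher info gain (each with a
# tolerance of SCORE_TOL so last-ulp noise cannot flip the choice), then
# family order c45 < tsp < wtsp, then lowest first-attribute index, lowest
# second-attribute index, smaller threshold/weight, earliest category.
pick_best_cand <- function(cands) {
  if (!nrow(cands)) return(NULL)
  top <- cands[cands$gr >= max(cands$gr) - SCORE_TOL, , drop = FALSE]
  top <- top[top$ig >= max(top$ig) - SCORE_TOL, , drop = FALSE]
  fam <- match(top$family, c("c45", "tsp", "wtsp"))
  top[order(fam, top$a1, top$a2, top$value, top$cat)[1], , drop = FALSE]
}

cand_to_test <- function(dataset, cand) {
  nm <- dataset$attributes$name
  switch(cand$family,
    c45 = if (cand$cat > 0)
      c45_test(nm[cand$a1],
               category = dataset$attributes$levels[[cand$a1]][cand$cat])
    else c45_test(nm[cand$a1], threshold = cand$value),
    tsp = tsp_test(nm[cand$a1], nm[cand$a2]),
    wtsp = wtsp_test(nm[cand$a1], nm[cand$a2], weight = cand$value)
  )
}

cand_to_split <- function(dataset, rows, cand) {
  if (is.null(cand) || !nrow(cand)) return(NULL)
  test <- cand_to_test(dataset, cand)
  left <- route_rows(test, dataset, rows)
  lc <- tabulate(dataset$labels[rows][left], length(dataset$class_levels))
  rc <- tabulate(dataset$labels[rows][!left], length(dataset$class_levels))
  new_scored_split(test, cand$gr, cand$ig, cand$si, lc, rc)
}

# ---- public searches -------------------------------------------------------

#' Best univariate split on one attribute
#'
#' Continuous attributes: candidate thresholds are the midpoints between
#' consecutive distinct sorted values present in `rows` (the classical
#' C4.5 candidate set), and the maximum-gain-ratio non-degenerate split is
#' returned. Nominal attributes: the binary equality test is evaluated
#' for each distinct category present. Returns `NULL` when every
#' candidate is degenerate or has non-positive information gain.
#'
#' @param dataset A `retree_dataset`.
#' @param rows Integer row indices defining the node (default: all rows).
#' @param attribute Attribute name to search.
#' @param min_child Minimum number of rows each child must receive.
#' @return A `retree_split`, or `NULL`.
#' @export
best_c45_split <- function(dataset, rows = seq_len(n_samples(dataset)),
                           attribute, min_child = 1) {
  m <- attr_meta(dataset, attribute)
  if (length(rows) < 2) return(NULL)
  cand_to_split(dataset, rows,
                pick_best_cand(cands_c45(dataset, rows, m$index, min_child)))
}

#' Best Top-Scoring-Pair split
#'
#' Scans ordered pairs `(i, j)` of continuous, non-ignored attributes with
#' the test `v_i < v_j`, honouring `pair_filter` (a list with optional
#' `attribute1` / `attribute2` entries; used by partial-test completion),
#' and returns the maximum-gain-ratio split under the canonical
#' tie-break. `max_pairs` optionally caps the search via a
#' variance-ranked attribute prefilter.
#'
#' @inheritParams best_c45_split
#' @param pair_filter Optional list fixing `attribute1` and/or `attribute2`.
#' @param max_pairs Optional cap on the number of ordered pairs scanned.
#' @return A `retree_split`, or `NULL`.
#' @export
best_tsp_split <- function(dataset, rows = seq_len(n_samples(dataset)),
                           pair_filter = NULL, min_child = 1,
                           max_pairs = NULL) {
  if (length(rows) < 2) return(NULL)
  cand_to_split(dataset, rows,
                pick_best_cand(cands_tsp(dataset, rows, min_child,
                                         pair_filter, max_pairs)))
}

#' Best weighted Top-Scoring-Pair split
#'
#' For each eligible ordered pair the per-row ratios `v1 / v2` are formed
#' and candidate weights are taken at midpoints between consecutive
#' distinct sorted ratios — the exact analogue of threshold search in
#' ratio space, which finds the optimum over all real weights because the
#' predicate only changes at observed ratios. Each `(pair, weight)` is
#' scored by gain ratio on all rows of the node. A pair where any row has
#' `v2 <= 0` is skipped entirely. `pair_filter` may additionally fix the
#' `weight`.
#'
#' @inheritParams best_tsp_split
#' @return A `retree_split`, or `NULL`.
#' @export
best_wtsp_split <- function(dataset, rows = seq_len(n_samples(dataset)),
                            pair_filter = NULL, min_child = 1,
                            max_pairs = NULL) {
  if (length(rows) < 2) return(NULL)
  cand_to_split(dataset, rows,
                pick_best_cand(cands_wtsp(dataset, rows, min_child,
                                          pair_filter, max_pairs)))
}

normalize_families <- function(families) {
  f <- tolower(families)
  bad <- setdiff(f, c("c45", "tsp", "wtsp"))
  if (length(bad)) stop_config(sprintf("unknown test family '%s'", bad[1]))
  if (!length(f)) stop_config("at least one test family must be enabled")
  unique(f)
}

all_cands <- function(dataset, rows, families, min_child = 1,
                      max_pairs = NULL, keep_per_pair = 1L) {
  families <- normalize_families(families)
  parts <- list()
  if ("c45" %in% families) {
    elig <- which(!dataset$attributes$ignored)
    parts <- c(parts, lapply(elig, function(a)
      cands_c45(dataset, rows, a, min_child)))
  }
  if ("tsp" %in% families) {
    parts <- c(parts, list(tryCatch(
      cands_tsp(dataset, rows, min_child, max_pairs = max_pairs),
      retree_not_applicable_error = function(e) empty_cands())))
  }
  if ("wtsp" %in% families) {
    parts <- c(parts, list(tryCatch(
      cands_wtsp(dataset, rows, min_child, max_pairs = max_pairs,
                 keep_per_pair = keep_per_pair),
      retree_not_applicable_error = function(e) empty_cands())))
  }
  parts <- parts[vapply(parts, nrow, integer(1)) > 0]
  if (!length(parts)) return(empty_cands())
  do.call(rbind, parts)
}

# Best split pooled across enabled families (the induction search).
best_split <- function(dataset, rows, families, min_child = 1,
                       max_pairs = NULL) {
  cand_to_split(dataset, rows,
                pick_best_cand(all_cands(dataset, rows, families, min_child,
                                         max_pairs)))
}

#' Top-k alternative splits for a node
#'
#' Pools all non-degenerate positive-gain candidate splits across the
#' enabled families and returns the `k` best by gain ratio under the
#' canonical tie-break — the "top splits" presented for a node to guide
#' manual editing.
#'
#' @inheritParams best_tsp_split
#' @param families Subset of `c("c45", "tsp", "wtsp")`.
#' @param k Maximum number of suggestions.
#' @return A tibble with columns `rank`, `family`, `test` (canonical
#'   string), `gain_ratio`, `info_gain`, `split_info`, `n_left`,
#'   `n_right`, and a `split` list-column of `retree_split` objects. May
#'   be empty (e.g. at a pure node).
#' @export
suggest_top_splits <- function(dataset, rows = seq_len(n_samples(dataset)),
                               families = c("c45", "tsp", "wtsp"), k = 5,
                               min_child = 1, max_pairs = NULL) {
  if (!length(rows)) stop_input("node is empty")
  cands <- all_cands(dataset, rows, families, min_child, max_pairs,
                     keep_per_pair = as.integer(k))
  if (!nrow(cands))
    return(tibble::tibble(rank = integer(), family = character(),
                          test = character(), gain_ratio = numeric(),
                          info_gain = numeric(), split_info = numeric(),
                          n_left = integer(), n_right = integer(),
                          split = list()))
  fam <- match(cands$family, c("c45", "tsp", "wtsp"))
  ord <- order(-round(cands$gr / SCORE_TOL), -round(cands$ig / SCORE_TOL),
               fam, cands$a1, cands$a2, cands$value, cands$cat)
  cands <- cands[ord[seq_len(min(k, length(ord)))], , drop = FALSE]
  splits <- lapply(seq_len(nrow(cands)), function(i)
    cand_to_split(dataset, rows, cands[i, , drop = FALSE]))
  tibble::tibble(
    rank = seq_along(splits),
    family = cands$family,
    test = vapply(splits, function(s) render_test(s$test), character(1)),
    gain_ratio = cands$gr, info_gain = cands$ig, split_info = cands$si,
    n_left = vapply(splits, function(s) sum(s$left_counts), integer(1)),
    n_right = vapply(splits, function(s) sum(s$right_counts), integer(1)),
    split = splits
  )
}

#' Describe a partially specified test
#'
#' Names a family and fixes any subset of its parameters; the free
#' parameters are searched by [complete_partial_test()].
#'
#' @param family One of `"c45"`, `"tsp"`, `"wtsp"`.
#' @param attribute,attribute1,attribute2,threshold,category,weight
#'   Optionally fixed parameters of the chosen family.
#' @return A `partial_test` object.
#' @export
partial_test <- function(family, attribute = NULL, attribute1 = NULL,
                         attribute2 = NULL, threshold = NULL,
                         category = NULL, weight = NULL) {
  family <- normalize_families(family)
  structure(list(family = family, attribute = attribute,
                 attribute1 = attribute1, attribute2 = attribute2,
                 threshold = threshold, category = category, weight = weight),
            class = "partial_test")
}

#' Complete a partially specified test
#'
#' Searches only the free parameters of a [partial_test()]: a C4.5 test
#' with the attribute fixed gets its best threshold (or category); a TSP
#' test with one attribute fixed gets the best partner; a WTSP test with
#' both attributes fixed gets the best weight, with one attribute fixed
#' the best partner-and-weight, and fully free the family's best split.
#'
#' @inheritParams best_c45_split
#' @param partial A `partial_test`.
#' @return A `retree_split`, or `NULL` when no positive-gain completion
#'   exists.
#' @export
complete_partial_test <- function(dataset, rows = seq_len(n_samples(dataset)),
                                  partial, min_child = 1) {
  if (!inherits(partial, "partial_test"))
    stop_structural("partial must be created with partial_test()")
  fam <- partial$family
  if (fam == "c45") {
    if (!is.null(partial$threshold) || !is.null(partial$category)) {
      if (is.null(partial$attribute))
        stop_structural("a fixed threshold/category requires a fixed attribute")
      test <- c45_test(partial$attribute, threshold = partial$threshold,
                       category = partial$category)
      validate_test(test, dataset)
      return(score_fixed_test(dataset, rows, test, min_child))
    }
    if (!is.null(partial$attribute))
      return(best_c45_split(dataset, rows, partial$attribute, min_child))
    elig <- which(!dataset$attributes$ignored)
    cands <- do.call(rbind, lapply(elig, function(a)
      cands_c45(dataset, rows, a, min_child)))
    return(cand_to_split(dataset, rows, pick_best_cand(cands %||% empty_cands())))
  }
  if (!is.null(partial$attribute1) && !is.null(partial$attribute2) &&
      identical(partial$attribute1, partial$attribute2))
    stop_structural("attribute1 and attribute2 must differ")
  filt <- list(attribute1 = partial$attribute1, attribute2 = partial$attribute2)
  if (fam == "tsp")
    return(best_tsp_split(dataset, rows, pair_filter = filt,
                          min_child = min_child))
  filt$weight <- partial$weight
  best_wtsp_split(dataset, rows, pair_filter = filt, min_child = min_child)
}

# Score one fully specified test at a node (used by completion and edits).
score_fixed_test <- function(dataset, rows, test, min_child = 1) {
  left <- route_rows(test, dataset, rows)
  K <- length(dataset$class_levels)
  lc <- tabulate(dataset$labels[rows][left], K)
  rc <- tabulate(dataset$labels[rows][!left], K)
  if (sum(lc) == 0 || sum(rc) == 0) return(NULL)
  if (sum(lc) < min_child || sum(rc) < min_child) return(NULL)
  g <- gain_ratio(lc + rc, lc, rc)
  if (g$info_gain <= SCORE_TOL) return(NULL)
  new_scored_split(test, g$gain_ratio, g$info_gain, g$split_info, lc, rc)
}
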