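#' Planted classification rules
#'
#' Rules for the synthetic expression-like data generator: a univariate
#' threshold rule `value >= t`, a pair rule `v1 < v2`, or a weighted pair
#' rule `v1 < w * v2`, on attributes addressed by index.
#'
#' @param attr,attr1,attr2 Attribute indices (1-based).
#' @param threshold,weight Rule parameters.
#' @return A `planted_rule` object.
#' @name planted_rule
NULL

#' @rdname planted_rule
#' @export
planted_threshold <- function(attr, threshold) {
  structure(list(type = "threshold", attr = as.integer(attr),
                 threshold = as.numeric(threshold)), class = "planted_rule")
}

#' @rdname planted_rule
#' @export
planted_pair <- function(attr1, attr2) {
  if (attr1 == attr2) stop_input("pair rule needs two distinct attributes")
  structure(list(type = "pair", attr1 = as.integer(attr1),
                 attr2 = as.integer(attr2)), class = "planted_rule")
}

#' @rdname planted_rule
#' @export
planted_weighted_pair <- function(attr1, attr2, weight) {
  if (attr1 == attr2) stop_input("pair rule needs two distinct attributes")
  if (weight <= 0) stop_input("weight must be positive")
  structure(list(type = "weighted_pair", attr1 = as.integer(attr1),
                 attr2 = as.integer(attr2), weight = as.numeric(weight)),
            class = "planted_rule")
}

#' Generate expression-like data with a planted rule
#'
#' Draws strictly positive attribute values from a log-normal model
#' (emulating the positivity and right skew of expression measurements;
#' no gene-gene correlation or batch structure is modelled), labels each
#' sample by the planted rule's predicate (`"pos"` when it holds, else
#' `"neg"`), then flips each label independently with probability
#' `noise_rate`. Fully reproducible from `seed`.
#'
#' @param rule A [planted_rule] (`planted_threshold()`, `planted_pair()`,
#'   or `planted_weighted_pair()`).
#' @param n_samples Number of samples (>= 4).
#' @param n_attributes Number of continuous attributes `g1..gp` (>= 2 for
#'   pair rules).
#' @param noise_rate Independent label-flip probability in `[0, 0.5)`.
#' @param meanlog,sdlog Log-normal location and scale.
#' @param seed Integer seed (required; the generator has no hidden state).
#' @return A `retree_dataset` with class column `class`, levels
#'   `c("pos", "neg")`.
#' @export
simulate_planted <- function(rule, n_samples, n_attributes, noise_rate = 0,
                             meanlog = 0, sdlog = 1, seed) {
  if (!inherits(rule, "planted_rule")) stop_input("rule must be a planted_rule")
  if (n_samples < 4) stop_input("n_samples must be at least 4")
  if (rule$type != "threshold" && n_attributes < 2)
    stop_input("pair rules need at least 2 attributes")
  if (noise_rate < 0 || noise_rate >= 0.5)
    stop_input("noise_rate must lie in [0, 0.5)")
  idx <- if (rule$type == "threshold") rule$attr else c(rule$attr1, rule$attr2)
  if (any(idx < 1 | idx > n_attributes))
    stop_input("rule attribute index out of range")
  if (missing(seed)) stop_input("seed is required")

  withr::with_seed(as.integer(seed), {
    X <- matrix(stats::rlnorm(n_samples * n_attributes, meanlog, sdlog),
                n_samples, n_attributes)
    sat <- switch(rule$type,
      threshold = X[, rule$attr] >= rule$threshold,
      pair = X[, rule$attr1] < X[, rule$attr2],
      weighted_pair = X[, rule$attr1] < rule$weight * X[, rule$attr2])
    flip <- stats::runif(n_samples) < noise_rate
    labels <- ifelse(xor(sat, flip), 1L, 2L)
    cols <- as.data.frame(X)
    names(cols) <- paste0("g", seq_len(n_attributes))
    new_retree_dataset(
      data = tibble::as_tibble(cols),
      attributes = tibble::tibble(
        name = names(cols), kind = "continuous",
        index = seq_len(n_attributes), ignored = FALSE,
        levels = vector("list", n_attributes)),
      class_name = "class", class_levels = c("pos", "neg"),
      labels = labels, sample_ids = as.character(seq_len(n_samples))
    )
  })
}

#' Generate a nominal attribute with a chosen category-class association
#'
#' Draws a class uniformly from the names of `class_association`, then a
#' category from that class's conditional distribution over categories.
#' Exercises the nominal (equality-test) split path.
#'
#' @param n Number of samples.
#' @param categories Character vector of at least 2 category labels.
#' @param class_association Named list: class label -> probability vector
#'   over `categories` (named or positional; each must sum to 1).
#' @param seed Integer seed.
#' @return A `retree_dataset` with one nominal attribute `x1`.
#' @export
generate_nominal_block <- function(n, categories, class_association, seed) {
  if (length(categories) < 2) stop_input("need at least 2 categories")
  if (is.null(names(class_association)) || length(class_association) < 2)
    stop_input("class_association must be a named list with >= 2 classes")
  probs <- lapply(class_association, function(p) {
    if (!is.null(names(p))) {
      if (!all(names(p) %in% categories))
        stop_input("class_association names unknown category")
      full <- stats::setNames(numeric(length(categories)), categories)
      full[names(p)] <- p
      p <- full
    }
    if (length(p) != length(categories))
      stop_input("each distribution needs one probability per category")
    if (abs(sum(p) - 1) > 1e-8)
      stop_input("each class's category distribution must sum to 1")
    p
  })
  withr::with_seed(as.integer(seed), {
    cls <- sample(names(class_association), n, replace = TRUE)
    x <- vapply(cls, function(cl)
      sample(categories, 1, prob = probs[[cl]]), character(1))
    lev_x <- unique(x)
    new_retree_dataset(
      data = tibble::tibble(x1 = unname(x)),
      attributes = tibble::tibble(name = "x1", kind = "nominal", index = 1L,
                                  ignored = FALSE, levels = list(lev_x)),
      class_name = "class", class_levels = names(class_association),
      labels = match(cls, names(class_association)),
      sample_ids = as.character(seq_len(n))
    )
  })
}
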