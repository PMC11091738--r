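#' Tree JSON interchange format
#'
#' Trees are imported and exported as a documented JSON format
#' (`format_version` "1.0"; the JSON-Schema document ships at
#' `system.file("extdata", "tree.schema.json", package = "retree")`).
#' Serialization is canonical — fixed key order, compact separators,
#' numbers in shortest round-trip decimal form — so exporting the same
#' tree is byte-stable across runs and export/import/export cycles are
#' byte-identical. The schema header records the routing convention:
#' instances satisfying a node's test always go to `"left"`. Stored
#' counts are validated on load (children must sum to their parent) and
#' rejected if inconsistent: a corrupted model must not load silently.
#'
#' @name tree_json
NULL

json_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  s
}
jstr <- function(s) paste0("\"", json_escape(s), "\"")
jarr <- function(xs) paste0("[", paste(xs, collapse = ","), "]")

test_to_json <- function(test) {
  fields <- switch(test$family,
    c45 = c(sprintf("\"family\":\"c45\",\"attribute\":%s", jstr(test$attribute)),
            if (test$mode == "threshold")
              sprintf("\"threshold\":%s", fmt_num(test$threshold))
            else sprintf("\"category\":%s", jstr(test$category))),
    tsp = sprintf("\"family\":\"tsp\",\"attribute1\":%s,\"attribute2\":%s",
                  jstr(test$attribute1), jstr(test$attribute2)),
    wtsp = sprintf("\"family\":\"wtsp\",\"attribute1\":%s,\"attribute2\":%s,\"weight\":%s",
                   jstr(test$attribute1), jstr(test$attribute2),
                   fmt_num(test$weight))
  )
  paste0("{", paste(fields, collapse = ","),
         sprintf(",\"repr\":%s}", jstr(render_test(test))))
}

node_to_json <- function(node, class_levels) {
  counts <- jarr(fmt_num(node$train_counts))
  if (node$kind == "leaf") {
    sprintf("{\"kind\":\"leaf\",\"predicted_class\":%s,\"train_counts\":%s}",
            jstr(class_levels[node$predicted_class_index]), counts)
  } else {
    sprintf("{\"kind\":\"internal\",\"test\":%s,\"train_counts\":%s,\"left\":%s,\"right\":%s}",
            test_to_json(node$test), counts,
            node_to_json(node$left, class_levels),
            node_to_json(node$right, class_levels))
  }
}

config_to_json <- function(cfg) {
  sprintf(paste0("{\"families\":%s,\"min_node_size\":%d,\"max_depth\":%d,",
                 "\"max_nodes\":%d,\"entropy_threshold\":%s,",
                 "\"suggestion_k\":%d,\"max_pairs\":%s}"),
          jarr(jstr(cfg$families)), cfg$min_node_size, cfg$max_depth,
          cfg$max_nodes, fmt_num(cfg$entropy_threshold), cfg$suggestion_k,
          if (is.null(cfg$max_pairs)) "null" else sprintf("%d", cfg$max_pairs))
}

#' Export a tree to canonical JSON
#'
#' @param tree A `retree`.
#' @param path Optional file path to write the document to.
#' @return The serialized JSON document as a single string (invisibly
#'   when `path` is given).
#' @export
export_tree <- function(tree, path = NULL) {
  attrs <- vapply(seq_len(nrow(tree$attributes)), function(k)
    sprintf("{\"name\":%s,\"kind\":%s,\"ignored\":%s}",
            jstr(tree$attributes$name[k]), jstr(tree$attributes$kind[k]),
            if (tree$attributes$ignored[k]) "true" else "false"),
    character(1))
  doc <- sprintf(paste0(
    "{\"format_version\":\"1.0\",",
    "\"semantics\":{\"satisfying_instances\":\"left\"},",
    "\"class_levels\":%s,\"attributes\":%s,\"config\":%s,\"root\":%s}"),
    jarr(jstr(tree$class_levels)), jarr(attrs),
    config_to_json(tree$config), node_to_json(tree$root, tree$class_levels))
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}

# --- import -----------------------------------------------------------------

need_key <- function(obj, key, path) {
  if (!key %in% names(obj))
    stop_format(sprintf("missing key '%s' at %s", key, path))
  obj[[key]]
}

need_num <- function(obj, key, path) {
  v <- need_key(obj, key, path)
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
    stop_format(sprintf("'%s' at %s must be a finite number", key, path))
  as.numeric(v)
}

need_str <- function(obj, key, path) {
  v <- need_key(obj, key, path)
  if (!is.character(v) || length(v) != 1)
    stop_format(sprintf("'%s' at %s must be a string", key, path))
  v
}

import_test <- function(obj, attrs, path) {
  fam <- need_str(obj, "family", path)
  resolve <- function(nm) {
    if (!nm %in% attrs$name)
      stop_structural(sprintf("test at %s references unknown attribute '%s'", path, nm))
    nm
  }
  test <- switch(fam,
    c45 = {
      a <- resolve(need_str(obj, "attribute", path))
      if ("threshold" %in% names(obj))
        c45_test(a, threshold = need_num(obj, "threshold", path))
      else if ("category" %in% names(obj))
        c45_test(a, category = need_str(obj, "category", path))
      else stop_format(sprintf("c45 test at %s needs 'threshold' or 'category'", path))
    },
    tsp = tsp_test(resolve(need_str(obj, "attribute1", path)),
                   resolve(need_str(obj, "attribute2", path))),
    wtsp = {
      if (!"weight" %in% names(obj))
        stop_format(sprintf("wtsp test at %s is missing 'weight'", path))
      wtsp_test(resolve(need_str(obj, "attribute1", path)),
                resolve(need_str(obj, "attribute2", path)),
                weight = need_num(obj, "weight", path))
    },
    stop_format(sprintf("unknown test family '%s' at %s", fam, path))
  )
  kind_of <- function(nm) attrs$kind[match(nm, attrs$name)]
  if (fam == "c45") {
    want <- if (test$mode == "threshold") "continuous" else "nominal"
    if (kind_of(test$attribute) != want)
      stop_structural(sprintf("test at %s needs a %s attribute", path, want))
  } else if (any(kind_of(c(test$attribute1, test$attribute2)) != "continuous")) {
    stop_structural(sprintf("test at %s needs continuous attributes", path))
  }
  test
}

import_node <- function(obj, attrs, class_levels, id, depth, path) {
  kind <- need_str(obj, "kind", path)
  counts <- need_key(obj, "train_counts", path)
  counts <- vapply(counts, function(x) {
    if (!is.numeric(x) || x < 0 || x != floor(x))
      stop_format(sprintf("train_counts at %s must be non-negative integers", path))
    as.integer(x)
  }, integer(1))
  if (length(counts) != length(class_levels))
    stop_format(sprintf("train_counts at %s must have one entry per class level", path))
  if (kind == "leaf") {
    pc <- need_str(obj, "predicted_class", path)
    idx <- match(pc, class_levels)
    if (is.na(idx))
      stop_format(sprintf("predicted_class '%s' at %s is not a class level", pc, path))
    nd <- new_leaf(id, counts, depth, "imported")
    nd$predicted_class_index <- idx
    return(nd)
  }
  if (kind != "internal")
    stop_format(sprintf("node kind at %s must be 'leaf' or 'internal'", path))
  test <- import_test(need_key(obj, "test", path), attrs,
                      paste0(path, ".test"))
  left <- import_node(need_key(obj, "left", path), attrs, class_levels,
                      paste0(id, "L"), depth + 1L, paste0(path, ".left"))
  right <- import_node(need_key(obj, "right", path), attrs, class_levels,
                       paste0(id, "R"), depth + 1L, paste0(path, ".right"))
  if (!all(left$train_counts + right$train_counts == counts))
    stop_format(sprintf("children's train_counts do not sum to the parent's at %s", path))
  new_internal(id, test, counts, depth, left, right)
}

#' Import a tree from JSON
#'
#' Accepts a JSON string or a file path. The document is validated
#' structurally (required keys, test/attribute consistency, count
#' conservation at every internal node) with errors naming the JSON path
#' of the offending element; an unknown `format_version` is rejected.
#'
#' @param text A JSON document string, or the path of a file holding one.
#' @param expected_schema Optional `retree_dataset` whose attribute
#'   schema the tree must be compatible with (same names and kinds).
#' @return A `retree`.
#' @export
import_tree <- function(text, expected_schema = NULL) {
  if (length(text) == 1 && !startsWith(trimws(text)[1], "{") && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e)
                    stop_format(sprintf("invalid JSON: %s", conditionMessage(e))))
  ver <- need_str(doc, "format_version", "$")
  if (!identical(ver, "1.0"))
    stop_version(sprintf("unsupported format_version '%s' (expected '1.0')", ver))
  lv <- unlist(need_key(doc, "class_levels", "$"))
  if (!is.character(lv) || length(lv) < 1 || anyDuplicated(lv))
    stop_format("class_levels must be a non-empty list of unique strings")
  alist <- need_key(doc, "attributes", "$")
  attrs <- tibble::tibble(
    name = vapply(seq_along(alist), function(i)
      need_str(alist[[i]], "name", sprintf("$.attributes[%d]", i)), character(1)),
    kind = vapply(seq_along(alist), function(i)
      need_str(alist[[i]], "kind", sprintf("$.attributes[%d]", i)), character(1)),
    index = seq_along(alist),
    ignored = vapply(seq_along(alist), function(i)
      isTRUE(need_key(alist[[i]], "ignored", sprintf("$.attributes[%d]", i))),
      logical(1)),
    levels = vector("list", length(alist))
  )
  if (anyDuplicated(attrs$name)) stop_format("duplicate attribute names in $.attributes")
  if (!all(attrs$kind %in% c("continuous", "nominal")))
    stop_format("attribute kind must be 'continuous' or 'nominal'")
  cfg_raw <- need_key(doc, "config", "$")
  cfg <- induction_config(
    families = unlist(need_key(cfg_raw, "families", "$.config")),
    min_node_size = need_num(cfg_raw, "min_node_size", "$.config"),
    max_depth = need_num(cfg_raw, "max_depth", "$.config"),
    max_nodes = need_num(cfg_raw, "max_nodes", "$.config"),
    entropy_threshold = need_num(cfg_raw, "entropy_threshold", "$.config"),
    suggestion_k = need_num(cfg_raw, "suggestion_k", "$.config"),
    max_pairs = cfg_raw$max_pairs)
  root <- import_node(need_key(doc, "root", "$"), attrs, lv, "r", 0L, "$.root")
  if (!is.null(expected_schema)) {
    es <- expected_schema$attributes
    for (k in seq_len(nrow(attrs))) {
      j <- match(attrs$name[k], es$name)
      if (is.na(j) || es$kind[j] != attrs$kind[k])
        stop_structural(sprintf(
          "tree attribute '%s' (%s) is absent or differently typed in the supplied schema",
          attrs$name[k], attrs$kind[k]))
    }
  }
  structure(
    list(root = root, config = cfg, attributes = attrs, class_levels = lv,
         class_name = "class"),
    class = "retree"
  )
}
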