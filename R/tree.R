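# Classification-tree engine for CFS scoring.
#
# A tree is a nested list. Internal node:
#   list(item = "<one of the six items>", op = "<", "<=", ">=", ">", "==", "in",
#        value = <threshold, level or level set>, yes = <node>, no = <node>)
# Leaf: list(cfs = <integer 1..9>).
# Ordinal items compare by level rank; `in` tests membership of a level/value
# set. Every comparison is binary, so the tree is a total function whenever
# its structure is well-formed and item values are in-domain.

TREE_OPS <- c("<", "<=", ">=", ">", "==", "in")

is_leaf <- function(node) !is.null(node$cfs)

# Numeric representation of an item column for comparisons: counts as-is,
# ordinals as ranks, booleans as 0/1.
item_values_numeric <- function(x, item) {
  lv <- cfs_levels()
  if (item %in% names(lv)) {
    vapply(x, level_rank, numeric(1), item = item)
  } else if (item == "active_past_week") {
    as.numeric(as.logical(x))
  } else {
    as.numeric(x)
  }
}

threshold_numeric <- function(value, item) {
  lv <- cfs_levels()
  if (item %in% names(lv)) {
    vapply(value, level_rank, numeric(1), item = item)
  } else if (item == "active_past_week") {
    as.numeric(as.logical(value))
  } else {
    as.numeric(value)
  }
}

# Evaluate one node's condition on item columns; returns logical vector.
eval_node_condition <- function(node, items) {
  if (!node$item %in% names(items))
    stop("tree references unknown item '", node$item, "'", call. = FALSE)
  x <- item_values_numeric(items[[node$item]], node$item)
  if (anyNA(x))
    stop("value outside declared domain for item '", node$item,
         "' at tree node (op '", node$op, "')", call. = FALSE)
  v <- threshold_numeric(node$value, node$item)
  switch(node$op,
    "<"  = x <  v,
    "<=" = x <= v,
    ">=" = x >= v,
    ">"  = x >  v,
    "==" = x == v,
    "in" = x %in% v,
    stop("unknown operator '", node$op, "' in tree node", call. = FALSE)
  )
}

#' Score CFS categories with a classification tree
#'
#' Deterministically assigns each item vector to the CFS category of the
#' single leaf its values reach. Works row-wise on a data frame of item
#' vectors (see [item_vector()] / [cfs_item_domain()]).
#'
#' @param items Data frame with the six item columns; one row per
#'   participant-wave.
#' @param tree A tree definition (see [read_cfs_tree()]); defaults to the
#'   tree shipped with the package.
#' @return Integer vector of CFS categories, one per row of `items`.
#' @export
#' @examples
#' classify_cfs(item_vector(0, 0, 0, "excellent", "rarely/none", TRUE))
classify_cfs <- function(items, tree = cfs_tree()) {
  items <- as.data.frame(items)
  out <- rep(NA_integer_, nrow(items))
  recurse <- function(node, idx) {
    if (!length(idx)) return(invisible(NULL))
    if (is_leaf(node)) {
      out[idx] <<- as.integer(node$cfs)
      return(invisible(NULL))
    }
    hit <- eval_node_condition(node, items[idx, , drop = FALSE])
    recurse(node$yes, idx[hit])
    recurse(node$no, idx[!hit])
  }
  recurse(tree, seq_len(nrow(items)))
  out
}

#' Collapse CFS categories into analysis states
#'
#' Categories 1-3 collapse to `"fit"`, category 4 to `"vulnerable"` and
#' categories 5-9 to `"frail"`.
#'
#' @param category Integer vector of CFS categories (1-9).
#' @return Character vector of states.
#' @export
#' @examples
#' collapse_state(1:7)
collapse_state <- function(category) {
  if (anyNA(category) || !all(category %in% 1:9))
    stop("CFS category out of range 1-9: ",
         paste(unique(category[!category %in% 1:9]), collapse = ", "),
         call. = FALSE)
  c("fit", "fit", "fit", "vulnerable", "frail", "frail", "frail", "frail",
    "frail")[category]
}

#' Read or write a tree definition file
#'
#' Tree definitions are stored as JSON or YAML with the node schema
#' `{item, op, value, yes, no}` and leaf schema `{cfs}`. Reading and writing
#' round-trips the structure exactly.
#'
#' @param path File path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return For `read_cfs_tree`, the tree (nested list). `write_cfs_tree`
#'   returns `path` invisibly.
#' @export
read_cfs_tree <- function(path) {
  ext <- tolower(tools::file_ext(path))
  tree <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  }
  normalise_tree(tree)
}

#' @rdname read_cfs_tree
#' @param tree Tree definition to write.
#' @export
write_cfs_tree <- function(tree, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(tree, path, precision = 17)
  } else {
    jsonlite::write_json(tree, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(path)
}

# Coerce parsed scalars to canonical types (integers for cfs and count
# thresholds, character level sets kept as-is).
normalise_tree <- function(node) {
  if (is_leaf(node)) return(list(cfs = as.integer(node$cfs)))
  list(item = node$item, op = node$op,
       value = if (is.list(node$value)) unlist(node$value) else node$value,
       yes = normalise_tree(node$yes), no = normalise_tree(node$no))
}

#' The CFS classification tree shipped with the package
#'
#' A transcription of the published CFS classification-tree structure over the
#' six questionnaire items: dependency in basic activities drives the frail
#' categories, instrumental-activity dependency marks mild frailty, symptom
#' burden (effort, poor self-rated health) marks the vulnerable category, and
#' activity, condition count and self-rated health separate the fit
#' categories. Thresholds are a version-controlled configuration
#' (`inst/extdata/cfs_tree.json`), not engine code: users scoring real data
#' should review them against the published instrument and may supply their
#' own tree via [read_cfs_tree()].
#'
#' @return Tree definition (nested list).
#' @export
cfs_tree <- function() {
  path <- system.file("extdata", "cfs_tree.json", package = "cfstrans",
                      mustWork = TRUE)
  read_cfs_tree(path)
}

#' Validate a tree definition
#'
#' Report-only structural and semantic checks: node schema, known item names
#' and operators, known ordinal levels, leaf categories in 1-9, and — by
#' exhaustive classification of a discretised item domain — which leaf
#' categories are actually reachable.
#'
#' @param tree Tree definition.
#' @param domain Data frame of item vectors over which reachability is
#'   enumerated (default [cfs_item_domain()]).
#' @return List with `valid` (logical), `issues` (character vector),
#'   `leaf_categories` and `reachable_categories` (integer vectors; the
#'   latter is `NULL` when structural issues prevent enumeration).
#' @export
validate_tree <- function(tree, domain = cfs_item_domain()) {
  issues <- character()
  leaves <- integer()
  known_items <- c("badl_help_count", "iadl_help_count", "condition_count",
                   "self_rated_health", "effort_frequency",
                   "active_past_week")
  lv <- cfs_levels()
  walk <- function(node, depth) {
    if (!is.list(node)) {
      issues <<- c(issues, "malformed node (not a list)")
      return(invisible(NULL))
    }
    if (is_leaf(node)) {
      cfs <- suppressWarnings(as.integer(node$cfs))
      if (is.na(cfs) || !cfs %in% 1:9) {
        issues <<- c(issues, paste0("leaf category out of range 1-9: ",
                                    deparse(node$cfs)))
      } else {
        leaves <<- c(leaves, cfs)
      }
      return(invisible(NULL))
    }
    if (is.null(node$item) || is.null(node$op) || is.null(node$value) ||
        is.null(node$yes) || is.null(node$no)) {
      issues <<- c(issues, "internal node missing item/op/value/yes/no")
      return(invisible(NULL))
    }
    if (!node$item %in% known_items)
      issues <<- c(issues, paste0("unknown item '", node$item, "'"))
    if (!node$op %in% TREE_OPS)
      issues <<- c(issues, paste0("unknown operator '", node$op, "'"))
    if (node$item %in% names(lv)) {
      bad <- setdiff(tolower(as.character(node$value)),
                     c(tolower(lv[[node$item]]),
                       tolower(names(.effort_aliases))))
      if (length(bad))
        issues <<- c(issues, paste0("unknown level '", bad, "' for item '",
                                    node$item, "'"))
    }
    walk(node$yes, depth + 1L)
    walk(node$no, depth + 1L)
  }
  walk(tree, 0L)
  reachable <- NULL
  if (!length(issues)) {
    reachable <- sort(unique(classify_cfs(domain, tree)))
    unreachable <- setdiff(sort(unique(leaves)), reachable)
    if (length(unreachable))
      issues <- c(issues,
                  paste0("category with empty preimage (unreachable leaf): ",
                         paste(unreachable, collapse = ", ")))
  }
  list(valid = !length(issues), issues = issues,
       leaf_categories = sort(unique(leaves)),
       reachable_categories = reachable)
}

#' Enumerate the preimage of each CFS category under a tree
#'
#' Classifies every item vector of a discretised domain and returns, for each
#' category, the rows of the domain mapping to it. Used by the synthetic
#' generator to draw item vectors consistent with an assigned category.
#'
#' @inheritParams validate_tree
#' @return Named list (names `"1"`, `"2"`, ...) of integer row indices into
#'   `domain`, with `domain` attached as attribute `"domain"`.
#' @export
tree_preimage <- function(tree = cfs_tree(), domain = cfs_item_domain()) {
  cat <- classify_cfs(domain, tree)
  out <- split(seq_len(nrow(domain)), cat)
  attr(out, "domain") <- domain
  out
}
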