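#' Labeled ordered trees
#'
#' `struct_tree` is the common currency of all syntactic views used by the
#' tree-kernel model: shortest-dependency-path trees (SDPT), structured
#' dependency features (SDF), structured phrase features (SPF) and
#' path-enclosed trees (PT). A node has a `label`, an ordered list of
#' `children`, and optionally a `token_index` (set on word leaves only).
#'
#' @param label Node label (non-empty string).
#' @param children List of `struct_tree` children (order is significant).
#' @param token_index Optional 0-based token index, for word leaves.
#' @param ... Extra named fields attached to the node (e.g. `rel`, `pos`,
#'   `surface` on SDPT nodes).
#' @return A `struct_tree` object.
#' @export
struct_tree <- function(label, children = list(), token_index = NULL, ...) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  node <- list(label = label, children = children, token_index = token_index, ...)
  class(node) <- "struct_tree"
  node
}

is_leaf <- function(node) length(node$children) == 0L

#' Serialize a tree as a bracketed string
#'
#' Round-trip safe with [parse_penn()] as long as labels contain no
#' parentheses or whitespace (word leaves are printed bare).
#'
#' @param tree A `struct_tree`.
#' @return A single bracketed string, e.g. `"(S (NP (NN a)) (VP (VB b)))"`.
#' @export
tree_format <- function(tree) {
  if (is_leaf(tree)) return(tree$label)
  paste0("(", tree$label, " ",
         paste(vapply(tree$children, tree_format, character(1)), collapse = " "),
         ")")
}

#' @export
format.struct_tree <- function(x, ...) tree_format(x)

#' @export
print.struct_tree <- function(x, ...) {
  cat(tree_format(x), "\n")
  invisible(x)
}

#' Parse a Penn-Treebank bracketed tree
#'
#' Leaves are assigned consecutive 0-based `token_index` values in
#' left-to-right order, so phrase-tree leaves align 1:1 with sentence tokens.
#'
#' @param string One bracketed tree, e.g. `"(S (NP (NN a)) (VP (VB b)))"`.
#' @return A `struct_tree`.
#' @export
parse_penn <- function(string) {
  toks <- regmatches(string, gregexpr("\\(|\\)|[^()\\s]+", string, perl = TRUE))[[1]]
  if (length(toks) == 0L) stop("empty tree string")
  pos <- 1L
  leaf_counter <- 0L
  parse_node <- function() {
    if (toks[pos] != "(") {
      # bare word leaf
      leaf <- struct_tree(toks[pos], token_index = leaf_counter)
      leaf_counter <<- leaf_counter + 1L
      pos <<- pos + 1L
      return(leaf)
    }
    pos <<- pos + 1L                       # consume "("
    label <- toks[pos]
    if (label %in% c("(", ")")) stop("malformed tree: missing label")
    pos <<- pos + 1L
    children <- list()
    while (pos <= length(toks) && toks[pos] != ")") {
      children[[length(children) + 1L]] <- parse_node()
    }
    if (pos > length(toks)) stop("malformed tree: unbalanced parentheses")
    pos <<- pos + 1L                       # consume ")"
    struct_tree(label, children)
  }
  out <- parse_node()
  if (pos <= length(toks)) stop("malformed tree: trailing tokens")
  out
}

#' Count nodes of a tree
#' @param tree A `struct_tree`.
#' @return Integer node count (root included).
#' @export
tree_n_nodes <- function(tree) {
  1L + sum(vapply(tree$children, tree_n_nodes, integer(1)))
}

#' Leaves of a tree, left to right
#' @param tree A `struct_tree`.
#' @return List of leaf `struct_tree` nodes.
#' @export
tree_leaves <- function(tree) {
  if (is_leaf(tree)) return(list(tree))
  unlist(lapply(tree$children, tree_leaves), recursive = FALSE)
}
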