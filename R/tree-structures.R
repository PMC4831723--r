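#' Syntactic views of a candidate
#'
#' These functions derive the tree and sequence representations used by the
#' tree-kernel and neural models from a sentence's dependency and phrase
#' parses: the shortest-dependency-path tree (SDPT), structured dependency
#' features (SDF) and their extended variant, structured phrase features
#' (SPF), the path-enclosed tree (PT) baseline, and the two SDP sequence
#' orderings.
#'
#' @name tree_views
NULL

#' Syntactic head of an entity mention
#'
#' The head is the token inside the mention span whose dependency head lies
#' outside the span (the rightmost such token if several); a single-token
#' mention is its own head. If every token heads outside the span (a parse
#' artifact), the rightmost span token is returned with a warning.
#'
#' @param tok_start,tok_end 0-based half-open token span of the mention.
#' @param sentence A `cdr_sentence`.
#' @return The 0-based token index of the head.
#' @export
entity_head <- function(tok_start, tok_end, sentence) {
  span <- tok_start:(tok_end - 1L)
  if (length(span) == 1L) return(span)
  arcs <- sentence$dep_arcs
  heads <- arcs$head[match(span, arcs$dependent)]
  outside <- span[!(heads %in% span)]
  if (length(outside) == 0L) {
    warning("every span token heads inside the span; falling back to the rightmost token",
            call. = FALSE)
    return(max(span))
  }
  if (length(outside) > 1L) return(max(outside))
  outside
}

# Undirected shortest path between two tokens in the dependency tree.
# Returns list(path = token indices from `from` to `to`, rels = relation label
# of the arc between consecutive path tokens, lca_pos = position of the lowest
# common ancestor within `path`). Errors if the tokens sit in different
# components (fragmented parse) or are identical.
dep_path <- function(sentence, from, to) {
  if (from == to) stop("degenerate candidate: the two entity heads coincide")
  arcs <- sentence$dep_arcs
  head_of <- arcs$head[match(arcs$dependent, arcs$dependent)]
  names(head_of) <- as.character(arcs$dependent)
  rel_of <- arcs$relation
  names(rel_of) <- as.character(arcs$dependent)
  chain <- function(i) {            # i and all its ancestors up to the root
    out <- i
    while ((i <- head_of[[as.character(i)]]) != -1L) out <- c(out, i)
    out
  }
  a <- chain(from); b <- chain(to)
  common <- intersect(a, b)
  if (length(common) == 0L) {
    stop(structure(class = c("cdr_no_path", "error", "condition"),
                   list(message = "entity heads lie in different dependency components",
                        call = NULL)))
  }
  lca <- common[[1L]]               # first common ancestor walking up from `from`
  up <- a[seq_len(match(lca, a))]                 # from -> lca
  down <- rev(b[seq_len(match(lca, b) - 1L)])     # below lca -> to
  path <- c(up, down)
  rels <- character(length(path) - 1L)
  for (k in seq_len(length(path) - 1L)) {
    u <- path[[k]]; v <- path[[k + 1L]]
    rels[[k]] <- if (head_of[[as.character(u)]] == v) rel_of[[as.character(u)]]
                 else rel_of[[as.character(v)]]
  }
  list(path = path, rels = rels, lca_pos = match(lca, path))
}

sdpt_node <- function(sentence, idx, rel = NULL, children = list()) {
  tok <- sentence$tokens[sentence$tokens$index == idx, ]
  struct_tree(paste0(tok$surface, "/", tok$pos), children = children,
              token_index = idx, surface = tok$surface, pos = tok$pos, rel = rel)
}

#' Shortest dependency path tree between two entity heads
#'
#' The unique undirected dependency-tree path between the two head tokens,
#' materialized as a tree rooted at their lowest common ancestor. Nodes are
#' labeled `surface/POS`, carry `token_index`, `surface`, `pos`, and the
#' relation label (`rel`) of the arc to their SDPT parent (arc direction is
#' not preserved). Children are ordered by ascending token index.
#'
#' @param sentence A `cdr_sentence`.
#' @param head_c,head_d Token indices of the chemical and disease heads.
#' @return A `struct_tree`.
#' @export
sdpt <- function(sentence, head_c, head_d) {
  dp <- dep_path(sentence, head_c, head_d)
  build_chain <- function(pos_seq, rel_idx) {
    # pos_seq: positions in dp$path, root-to-leaf order; rel_idx[k]: index in
    # dp$rels of the arc between path[pos_seq[k]] and its SDPT parent
    node <- NULL
    for (k in rev(seq_along(pos_seq))) {
      node <- sdpt_node(sentence, dp$path[[pos_seq[[k]]]], rel = dp$rels[[rel_idx[[k]]]],
                        children = if (is.null(node)) list() else list(node))
    }
    node
  }
  lca <- dp$lca_pos
  branches <- list()
  if (lca > 1L) {
    pos_seq <- seq(lca - 1L, 1L)       # parent of path[k] is path[k+1]: arc k
    branches <- c(branches, list(build_chain(pos_seq, pos_seq)))
  }
  if (lca < length(dp$path)) {
    pos_seq <- seq(lca + 1L, length(dp$path))   # parent is path[k-1]: arc k-1
    branches <- c(branches, list(build_chain(pos_seq, pos_seq - 1L)))
  }
  branches <- branches[order(vapply(branches, function(b) b$token_index, integer(1)))]
  sdpt_node(sentence, dp$path[[lca]], rel = NULL, children = branches)
}

#' Structured dependency features (SDF) from an SDPT
#'
#' Replaces each non-root SDPT node `word/POS`, reached via dependency
#' relation `r`, by the 3-level chain `r -> POS -> word`; the relation node
#' also carries the transformed children, so the SDPT shape is preserved at
#' the relation level. The root (which has no incoming relation) is labeled
#' `ROOT` with its own `POS -> word` chain beneath. Consequently the SDF has
#' exactly `3 *` (number of SDPT nodes) nodes.
#'
#' @param sdpt_tree A tree from [sdpt()].
#' @return A `struct_tree`.
#' @export
sdf <- function(sdpt_tree) {
  transform <- function(node, is_root) {
    pos_chain <- struct_tree(node$pos, children = list(
      struct_tree(node$surface, token_index = node$token_index)))
    kids <- lapply(node$children, transform, is_root = FALSE)
    struct_tree(if (is_root) "ROOT" else node$rel,
                children = c(list(pos_chain), kids))
  }
  transform(sdpt_tree, is_root = TRUE)
}

#' Extended SDF: SDF enriched with off-path dependents
#'
#' As [sdf()], then every word on the SDPT additionally receives, as extra
#' `r -> POS -> word` chains, its immediate dependents that are not
#' themselves on the path. Added chains are ordered by token index after the
#' node's POS chain and interleaved with on-path children by token index.
#'
#' @param sdpt_tree A tree from [sdpt()].
#' @param sentence The `cdr_sentence` the SDPT was derived from.
#' @return A `struct_tree`.
#' @export
extended_sdf <- function(sdpt_tree, sentence) {
  on_path <- sdpt_token_indices(sdpt_tree)
  arcs <- sentence$dep_arcs
  transform <- function(node, is_root) {
    pos_chain <- struct_tree(node$pos, children = list(
      struct_tree(node$surface, token_index = node$token_index)))
    kids <- lapply(node$children, transform, is_root = FALSE)
    kid_idx <- vapply(node$children, function(k) k$token_index, integer(1))
    deps <- arcs$dependent[arcs$head == node$token_index]
    extra_idx <- setdiff(deps, on_path)
    extras <- lapply(extra_idx, function(i) {
      rel <- arcs$relation[[match(i, arcs$dependent)]]
      tok <- sentence$tokens[sentence$tokens$index == i, ]
      struct_tree(rel, children = list(
        struct_tree(tok$pos, children = list(
          struct_tree(tok$surface, token_index = i)))))
    })
    all_kids <- c(kids, extras)
    all_idx <- c(kid_idx, extra_idx)
    struct_tree(if (is_root) "ROOT" else node$rel,
                children = c(list(pos_chain), all_kids[order(all_idx)]))
  }
  transform(sdpt_tree, is_root = TRUE)
}

#' Token indices on an SDPT
#' @param sdpt_tree A tree from [sdpt()].
#' @return Sorted integer vector of token indices on the path.
#' @export
sdpt_token_indices <- function(sdpt_tree) {
  walk <- function(n) c(n$token_index, unlist(lapply(n$children, walk)))
  sort(unlist(walk(sdpt_tree)))
}

# Prune a phrase tree to the minimal connected subtree containing the leaves
# with token_index in `keep_idx`, then root it at their lowest common ancestor
# (descend while a node has a single non-leaf child).
prune_phrase_tree <- function(phrase_tree, keep_idx) {
  if (length(keep_idx) == 0L) stop("empty token index set")
  prune <- function(node) {
    if (is_leaf(node)) {
      if (!is.null(node$token_index) && node$token_index %in% keep_idx) node else NULL
    } else {
      kids <- Filter(Negate(is.null), lapply(node$children, prune))
      if (length(kids) == 0L) NULL else struct_tree(node$label, kids)
    }
  }
  out <- prune(phrase_tree)
  if (is.null(out)) stop("no phrase-tree leaf carries a selected token index")
  while (!is_leaf(out) && length(out$children) == 1L && !is_leaf(out$children[[1L]])) {
    out <- out$children[[1L]]
  }
  out
}

#' Structured phrase features (SPF) from the SDPT word set
#'
#' The minimal connected subtree of the phrase tree containing the leaves
#' whose token index lies on the SDPT, with all their ancestral constituents,
#' rooted at the lowest common ancestor. A single selected leaf degenerates
#' to leaf + its preterminal.
#'
#' @param phrase_tree The sentence's phrase `struct_tree` (leaves aligned to
#'   tokens).
#' @param sdpt_tokens Integer token indices (e.g. [sdpt_token_indices()]).
#' @return A `struct_tree`.
#' @export
spf <- function(phrase_tree, sdpt_tokens) {
  prune_phrase_tree(phrase_tree, sdpt_tokens)
}

#' Path-enclosed tree (PT) baseline
#'
#' The minimal phrase subtree enclosing the two entity spans: all leaves
#' between and including the spans, rooted at their lowest common ancestor.
#'
#' @param phrase_tree The sentence's phrase `struct_tree`.
#' @param chem_span,dis_span 0-based half-open token spans `c(start, end)`.
#' @return A `struct_tree`.
#' @export
pt <- function(phrase_tree, chem_span, dis_span) {
  if (max(chem_span[1], dis_span[1]) < min(chem_span[2], dis_span[2])) {
    stop("overlapping entity spans")
  }
  lo <- min(chem_span[1], dis_span[1])
  hi <- max(chem_span[2], dis_span[2]) - 1L
  prune_phrase_tree(phrase_tree, lo:hi)
}

#' Shortest-dependency-path sequences
#'
#' `dep` mode interleaves words and relation labels in path order from the
#' chemical head to the disease head. `seq` mode lists the same words in
#' natural sentence order (ascending token index); each path relation is
#' placed at the midpoint of its arc's endpoint indices, with words preceding
#' relations on ties.
#'
#' @param sentence A `cdr_sentence`.
#' @param head_c,head_d Chemical and disease head token indices.
#' @param order_mode `"dep"` or `"seq"`.
#' @return A tibble with columns `kind` (`word`/`relation`), `label`, and
#'   `token_index` (`NA` for relations).
#' @export
sdp_sequence <- function(sentence, head_c, head_d, order_mode = c("dep", "seq")) {
  order_mode <- match.arg(order_mode)
  dp <- dep_path(sentence, head_c, head_d)
  toks <- sentence$tokens
  words <- tibble(kind = "word",
                  label = toks$surface[match(dp$path, toks$index)],
                  token_index = dp$path,
                  key = as.numeric(dp$path), tie = 0)
  rels <- tibble(kind = "relation", label = dp$rels, token_index = NA_integer_,
                 key = (dp$path[-length(dp$path)] + dp$path[-1L]) / 2, tie = 1)
  out <- if (order_mode == "dep") {
    # path order: word, relation, word, relation, ..., word
    idx <- order(c(seq_along(dp$path) * 2 - 1, seq_len(length(dp$rels)) * 2))
    bind_rows(words, rels)[idx, ]
  } else {
    dplyr::arrange(bind_rows(words, rels), .data$key, .data$tie)
  }
  out$key <- NULL; out$tie <- NULL
  out
}

#' Position of the SDPT root relative to the two entities
#'
#' `"before"` if the root token lies strictly before the first entity span,
#' `"after"` if strictly after the last, else `"between"` (a root inside an
#' entity span counts as between).
#'
#' @param sdpt_tree A tree from [sdpt()].
#' @param chem_span,dis_span 0-based half-open token spans.
#' @return One of `"before"`, `"between"`, `"after"`.
#' @export
sdpt_root_position <- function(sdpt_tree, chem_span, dis_span) {
  root_idx <- sdpt_tree$token_index
  first_start <- min(chem_span[1], dis_span[1])
  last_end <- max(chem_span[2], dis_span[2])
  if (root_idx < first_start) "before"
  else if (root_idx >= last_end) "after"
  else "between"
}
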