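# Independent oracles and fixture builders shared across test files.

# Build a cdr_sentence directly (no files): surfaces, POS, 0-based heads with
# -1 root, relations; stems default to lowercased surfaces.
make_sentence <- function(surface, pos, heads, rels,
                          stems = tolower(surface),
                          chunk = rep("B-NP", length(surface)),
                          tree = NULL) {
  n <- length(surface)
  starts <- cumsum(c(0L, nchar(surface[-n]) + 1L))
  structure(list(
    tokens = tibble::tibble(index = seq_len(n) - 1L, surface = surface,
                            stem = stems, pos = pos, chunk = chunk,
                            char_start = starts,
                            char_end = starts + nchar(surface)),
    dep_arcs = tibble::tibble(dependent = seq_len(n) - 1L,
                              head = as.integer(heads), relation = rels),
    phrase_tree = if (is.null(tree)) NULL else parse_penn(tree),
    char_span = c(0L, starts[n] + nchar(surface[n]))),
    class = "cdr_sentence")
}

make_candidate <- function(chem_span, dis_span, doc_id = "d1", sent = 0L) {
  tibble::tibble(doc_id = doc_id, sentence_index = sent,
                 chem_concept = "Dchem", chem_text = "chem",
                 chem_start = chem_span[1], chem_end = chem_span[2],
                 dis_concept = "Ddis", dis_text = "dis",
                 dis_start = dis_span[1], dis_end = dis_span[2],
                 label = 1L, candidate_id = "d1:0:0:0")
}

# ---- tree-kernel oracle: explicit fragment enumeration ----------------------

# Independent serializer (not tree_format): leaves bare, internal bracketed.
oracle_tree_string <- function(node) {
  if (length(node$children) == 0L) return(node$label)
  paste0("[", node$label, "|",
         paste(vapply(node$children, oracle_tree_string, ""), collapse = ","), "]")
}

# All fragments rooted at `node` (an internal node), as data.frame(str, k)
# where k = number of production nodes in the fragment.
# ST: every included node fully expanded to leaves (one fragment per node).
# SST: each non-terminal child may be left unexpanded (label only) or
# replaced by any of its own fragments; terminal children are always kept.
oracle_frags_at <- function(node, variant) {
  child_opts <- lapply(node$children, function(ch) {
    if (length(ch$children) == 0L) {
      data.frame(str = ch$label, k = 0L, stringsAsFactors = FALSE)
    } else if (variant == "ST") {
      full <- oracle_frags_at(ch, "ST")      # exactly one row (full subtree)
      full
    } else {
      rbind(data.frame(str = ch$label, k = 0L, stringsAsFactors = FALSE),
            oracle_frags_at(ch, "SST"))
    }
  })
  combos <- Reduce(function(acc, opt) {
    do.call(rbind, lapply(seq_len(nrow(opt)), function(r) {
      data.frame(str = paste(acc$str, opt$str[r], sep = ","),
                 k = acc$k + opt$k[r], stringsAsFactors = FALSE)
    }))
  }, child_opts, accumulate = FALSE,
     init = data.frame(str = "", k = 0L, stringsAsFactors = FALSE))
  data.frame(str = paste0("[", node$label, "|", sub("^,", "", combos$str), "]"),
             k = combos$k + 1L, stringsAsFactors = FALSE)
}

oracle_all_frags <- function(tree, variant) {
  out <- list()
  walk <- function(node) {
    if (length(node$children) == 0L) return()
    out[[length(out) + 1L]] <<- oracle_frags_at(node, variant)
    for (ch in node$children) walk(ch)
  }
  walk(tree)
  do.call(rbind, out)
}

# K(t1, t2) by brute-force matching of enumerated fragment pairs.
oracle_tree_kernel <- function(t1, t2, variant, lambda) {
  f1 <- oracle_all_frags(t1, variant)
  f2 <- oracle_all_frags(t2, variant)
  if (is.null(f1) || is.null(f2)) return(0)
  total <- 0
  tab2 <- table(f2$str)
  for (s in unique(f1$str)) {
    if (!s %in% names(tab2)) next
    k <- f1$k[match(s, f1$str)]
    total <- total + sum(f1$str == s) * tab2[[s]] * lambda^k
  }
  total
}

# ---- dependency-path oracle: BFS on the undirected arc graph ----------------

oracle_shortest_path <- function(sentence, from, to) {
  arcs <- sentence$dep_arcs[sentence$dep_arcs$head != -1L, ]
  g <- igraph::graph_from_edgelist(
    cbind(as.character(arcs$dependent), as.character(arcs$head)),
    directed = FALSE)
  p <- igraph::shortest_paths(g, from = as.character(from),
                              to = as.character(to))$vpath[[1]]
  as.integer(names(p))
}

# ---- phrase-tree prune oracle: leaf-path prefixes ---------------------------

# Leaf root-paths as integer vectors of child positions.
oracle_leaf_paths <- function(tree) {
  out <- list()
  walk <- function(node, path) {
    if (length(node$children) == 0L) {
      out[[length(out) + 1L]] <<- list(path = path, idx = node$token_index)
      return()
    }
    for (i in seq_along(node$children)) walk(node$children[[i]], c(path, i))
  }
  walk(tree, integer())
  out
}

node_at_path <- function(tree, path) {
  for (i in path) tree <- tree$children[[i]]
  tree
}

# Keep nodes on a root-path prefix of any selected leaf; root the result at
# the deepest common prefix (backing off one step for a single selected leaf
# so the preterminal survives).
oracle_prune <- function(tree, keep_idx) {
  lp <- oracle_leaf_paths(tree)
  sel <- Filter(function(l) !is.null(l$idx) && l$idx %in% keep_idx, lp)
  stopifnot(length(sel) > 0L)
  paths <- lapply(sel, `[[`, "path")
  lcp <- paths[[1]]
  for (p in paths[-1]) {
    m <- 0L
    while (m < min(length(lcp), length(p)) && lcp[m + 1L] == p[m + 1L]) m <- m + 1L
    lcp <- lcp[seq_len(m)]
  }
  if (length(paths) == 1L) lcp <- lcp[-length(lcp)]   # leaf + its preterminal
  keyset <- unique(unlist(lapply(paths, function(p)
    vapply(seq_along(p), function(m) paste(p[seq_len(m)], collapse = "."), ""))))
  rebuild <- function(node, path) {
    if (length(node$children) == 0L) return(node)
    kids <- list()
    for (i in seq_along(node$children)) {
      key <- paste(c(path, i), collapse = ".")
      if (key %in% keyset) {
        kids[[length(kids) + 1L]] <- rebuild(node$children[[i]], c(path, i))
      }
    }
    struct_tree(node$label, kids)
  }
  rebuild(node_at_path(tree, lcp), lcp)
}

# ---- straight-line peephole LSTM re-implementation --------------------------

oracle_lstm_step <- function(x, h, cc, p) {
  sg <- function(z) 1 / (1 + exp(-z))
  i <- sg(as.vector(p$Wi %*% x) + as.vector(p$Ui %*% h) + p$vi * cc + p$bi)
  f <- sg(as.vector(p$Wf %*% x) + as.vector(p$Uf %*% h) + p$vf * cc + p$bf)
  c_t <- f * cc + i * tanh(as.vector(p$Wc %*% x) + as.vector(p$Uc %*% h) + p$bc)
  o <- sg(as.vector(p$Wo %*% x) + as.vector(p$Uo %*% h) + p$vo * c_t + p$bo)
  list(h = o * tanh(c_t), c = c_t)
}

random_lstm_params <- function(D, H, seed = 1) {
  set.seed(seed)
  rp <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.5), nr, nc)
  list(Wi = rp(H, D), Wf = rp(H, D), Wc = rp(H, D), Wo = rp(H, D),
       Ui = rp(H, H), Uf = rp(H, H), Uc = rp(H, H), Uo = rp(H, H),
       vi = rnorm(H, sd = 0.5), vf = rnorm(H, sd = 0.5), vo = rnorm(H, sd = 0.5),
       bi = rnorm(H, sd = 0.5), bf = rnorm(H, sd = 0.5),
       bc = rnorm(H, sd = 0.5), bo = rnorm(H, sd = 0.5))
}

# Small bank of trees (<= 8 nodes each) for kernel oracle tests.
kernel_fixture_trees <- function() {
  lapply(c("(S (NP (NN a)) (VP (VB b)))",
           "(S (NN a) (VP (VB b) (NN c)))",
           "(S (NP (NN a) (NN c)) (VB b))",
           "(VP (VB b) (NP (NN a)))",
           "(S (NP (NN a)) (VP (VB d)))",
           "(X (Y (Z q)))",
           "(S (NP (NN a)) (NP (NN a)))"),
         parse_penn)
}

# Small shared corpus for structural property tests (cached per session).
shared_fixture_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_corpus(fixture_spec(n_documents = 25L, seed = 99L))
    }
    cache
  }
})
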