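# chain parse: a <-nsubj- b -dobj-> c  (b is root)
chain_sentence <- function() {
  make_sentence(c("a", "b", "c"), c("NN", "VB", "NN"),
                heads = c(1L, -1L, 1L), rels = c("nsubj", "root", "dobj"),
                tree = "(S (NP (NN a)) (VP (VB b) (NN c)))")
}

test_that("entity head: single token, multiword, and fallback", {
  ex <- worked_example_sentence1()
  sent <- ex$sentences[[2]]
  m <- ex$mentions
  hyp <- m[m$text == "hypotension", ]
  expect_equal(entity_head(hyp$tok_start, hyp$tok_end, sent), 15L)
  cwr <- m[m$text == "chest wall rigidity", ]
  # "rigidity" governs "chest" and "wall"
  expect_equal(entity_head(cwr$tok_start, cwr$tok_end, sent), 11L)
  # span whose tokens all head inside each other is impossible in a tree, but
  # a span where several tokens head outside falls back to the rightmost
  s <- make_sentence(c("x", "y", "z"), c("NN", "NN", "VB"),
                     heads = c(2L, 2L, -1L), rels = c("nn", "nsubj", "root"))
  expect_equal(entity_head(0L, 2L, s), 1L)  # both head outside -> rightmost
})

test_that("SDPT covers chains, ancestor paths and the worked example", {
  s <- chain_sentence()
  st <- sdpt(s, 0L, 2L)
  expect_equal(st$token_index, 1L)                 # rooted at the LCA "b"
  expect_equal(sdpt_token_indices(st), c(0L, 1L, 2L))
  expect_equal(tree_n_nodes(st), 3L)
  # one endpoint is the ancestor of the other
  st2 <- sdpt(s, 1L, 2L)
  expect_equal(st2$token_index, 1L)
  expect_equal(sdpt_token_indices(st2), c(1L, 2L))
  # degenerate pair
  expect_error(sdpt(s, 1L, 1L), "coincide")
  # Sentence 1: the path between fentanyl and hypotension runs through the
  # governing verb "include"
  ex <- worked_example_sentence1()
  sent <- ex$sentences[[2]]
  st3 <- sdpt(sent, 5L, 15L)
  words <- sent$tokens$surface[match(sdpt_token_indices(st3), sent$tokens$index)]
  expect_true(all(c("fentanyl", "hypotension", "include") %in% words))
})

test_that("SDPT equals the BFS shortest path on every fixture candidate", {
  skip_if_not_installed("igraph")
  corpus <- shared_fixture_corpus()
  cand <- corpus_candidates(corpus$documents)
  docs <- setNames(corpus$documents,
                   vapply(corpus$documents, function(d) d$doc_id, ""))
  for (i in seq_len(nrow(cand))) {
    sent <- docs[[cand$doc_id[i]]]$sentences[[cand$sentence_index[i] + 1L]]
    hc <- entity_head(cand$chem_start[i], cand$chem_end[i], sent)
    hd <- entity_head(cand$dis_start[i], cand$dis_end[i], sent)
    st <- sdpt(sent, hc, hd)
    oracle <- oracle_shortest_path(sent, hc, hd)
    expect_setequal(sdpt_token_indices(st), oracle)
    expect_equal(tree_n_nodes(st), length(oracle))   # path length + 1
  }
})

test_that("SDF rewrites nodes into relation -> POS -> word chains", {
  ex <- worked_example_sentence1()
  sent <- ex$sentences[[2]]
  f <- sdf(sdpt(sent, 5L, 15L))
  expect_equal(f$label, "ROOT")
  # the dobj relation between include and rigidity appears as dobj -> NN -> rigidity
  txt <- tree_format(f)
  expect_match(txt, "(dobj (NN rigidity)", fixed = TRUE)
  # single-edge SDPT: ROOT with its POS chain plus one relation chain
  s <- chain_sentence()
  f2 <- sdf(sdpt(s, 1L, 2L))
  expect_equal(f2$label, "ROOT")
  expect_length(f2$children, 2L)
  expect_equal(f2$children[[1]]$label, "VB")          # root POS chain
  expect_equal(f2$children[[2]]$label, "dobj")
})

test_that("SDF node-count law holds on fixture candidates", {
  corpus <- shared_fixture_corpus()
  cand <- corpus_candidates(corpus$documents)
  docs <- setNames(corpus$documents,
                   vapply(corpus$documents, function(d) d$doc_id, ""))
  for (i in seq_len(min(nrow(cand), 40L))) {
    sent <- docs[[cand$doc_id[i]]]$sentences[[cand$sentence_index[i] + 1L]]
    hc <- entity_head(cand$chem_start[i], cand$chem_end[i], sent)
    hd <- entity_head(cand$dis_start[i], cand$dis_end[i], sent)
    st <- sdpt(sent, hc, hd)
    # every SDPT node becomes a 3-node chain (the root keeps its chain under
    # the ROOT marker)
    expect_equal(tree_n_nodes(sdf(st)), 3L * tree_n_nodes(st))
  }
})

test_that("extended SDF adds exactly the off-path dependents", {
  s <- make_sentence(c("mod", "a", "b", "c", "extra"),
                     c("JJ", "NN", "VB", "NN", "RB"),
                     heads = c(1L, 2L, -1L, 2L, 2L),
                     rels = c("amod", "nsubj", "root", "dobj", "advmod"))
  st <- sdpt(s, 1L, 3L)
  base <- sdf(st)
  ext <- extended_sdf(st, s)
  # two off-path dependents (mod -> a, extra -> b): two extra 3-node chains
  expect_equal(tree_n_nodes(ext), tree_n_nodes(base) + 6L)
  txt <- tree_format(ext)
  expect_match(txt, "(amod (JJ mod)", fixed = TRUE)
  expect_match(txt, "(advmod (RB extra)", fixed = TRUE)
  # when the SDPT covers all tokens there is nothing to add
  s2 <- chain_sentence()
  st2 <- sdpt(s2, 0L, 2L)
  expect_equal(tree_format(extended_sdf(st2, s2)), tree_format(sdf(st2)))
})

test_that("SPF and PT match the brute-force prune oracle", {
  corpus <- shared_fixture_corpus()
  cand <- corpus_candidates(corpus$documents)
  docs <- setNames(corpus$documents,
                   vapply(corpus$documents, function(d) d$doc_id, ""))
  for (i in seq_len(min(nrow(cand), 30L))) {
    sent <- docs[[cand$doc_id[i]]]$sentences[[cand$sentence_index[i] + 1L]]
    hc <- entity_head(cand$chem_start[i], cand$chem_end[i], sent)
    hd <- entity_head(cand$dis_start[i], cand$dis_end[i], sent)
    idx <- sdpt_token_indices(sdpt(sent, hc, hd))
    expect_equal(tree_format(spf(sent$phrase_tree, idx)),
                 tree_format(oracle_prune(sent$phrase_tree, idx)))
    lo <- min(cand$chem_start[i], cand$dis_start[i])
    hi <- max(cand$chem_end[i], cand$dis_end[i]) - 1L
    expect_equal(tree_format(pt(sent$phrase_tree,
                                c(cand$chem_start[i], cand$chem_end[i]),
                                c(cand$dis_start[i], cand$dis_end[i]))),
                 tree_format(oracle_prune(sent$phrase_tree, lo:hi)))
  }
})

test_that("SPF/PT edge cases: whole tree, single leaf, overlap error", {
  tree <- parse_penn("(S (NP (NN a) (NN b)) (VP (VB c) (NP (NN d) (NN e))))")
  expect_equal(tree_format(spf(tree, 0:4)), tree_format(tree))
  single <- spf(tree, 2L)
  expect_equal(tree_format(single), "(VB c)")         # leaf + its preterminal
  expect_equal(tree_format(pt(tree, c(1L, 2L), c(3L, 4L))),
               tree_format(oracle_prune(tree, 1:3)))
  expect_error(pt(tree, c(1L, 3L), c(2L, 4L)), "overlap")
  expect_error(spf(tree, integer()), "empty")
})

test_that("SDP sequences: dep vs seq ordering and word-set equality", {
  s <- chain_sentence()
  dep <- sdp_sequence(s, 0L, 2L, "dep")
  seqq <- sdp_sequence(s, 0L, 2L, "seq")
  expect_equal(dep$label, seqq$label)      # natural order = path order here
  expect_equal(dep$label, c("a", "nsubj", "b", "dobj", "c"))
  # path whose dep order differs from sentence order
  ex <- worked_example_sentence1()
  sent <- ex$sentences[[2]]
  dep2 <- sdp_sequence(sent, 5L, 15L, "dep")
  seq2 <- sdp_sequence(sent, 5L, 15L, "seq")
  w_dep <- dep2$label[dep2$kind == "word"]
  w_seq <- seq2$label[seq2$kind == "word"]
  expect_false(identical(w_dep, w_seq))
  expect_setequal(w_dep, w_seq)
  # seq mode is sorted by token index; both contain exactly the SDPT words
  expect_equal(seq2$token_index[seq2$kind == "word"],
               sort(seq2$token_index[seq2$kind == "word"]))
  st_words <- sdpt_token_indices(sdpt(sent, 5L, 15L))
  expect_setequal(dep2$token_index[dep2$kind == "word"], st_words)
  # dep mode starts at the chemical head
  expect_equal(dep2$token_index[1], 5L)
})

test_that("SDPT root position classifies before/between/after", {
  ex <- worked_example_sentence1()
  sent <- ex$sentences[[2]]
  st <- sdpt(sent, 5L, 15L)           # root "include" (7) between 5 and 15
  expect_equal(sdpt_root_position(st, c(5L, 6L), c(15L, 16L)), "between")
  expect_equal(sdpt_root_position(st, c(8L, 9L), c(15L, 16L)), "before")
  expect_equal(sdpt_root_position(st, c(1L, 2L), c(3L, 4L)), "after")
  # root inside an entity span counts as between
  expect_equal(sdpt_root_position(st, c(7L, 8L), c(15L, 16L)), "between")
})

test_that("tree transforms are deterministic and leave the sentence unchanged", {
  ex <- worked_example_sentence1()
  sent <- ex$sentences[[2]]
  before <- sent
  st <- sdpt(sent, 5L, 15L)
  a <- tree_format(sdf(st)); b <- tree_format(sdf(sdpt(sent, 5L, 15L)))
  expect_identical(a, b)
  expect_identical(tree_format(extended_sdf(st, sent)),
                   tree_format(extended_sdf(st, sent)))
  expect_identical(sent, before)
})
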