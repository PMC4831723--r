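two_doc_pubtator <- function(path) {
  writeLines(c(
    "101|t|aspirin caused nausea .",
    "101|a|patients recovered fully .",
    "101\t0\t7\taspirin\tChemical\tD001241",
    "101\t15\t21\tnausea\tDisease\tD009325",
    "101\tCID\tD001241\tD009325",
    "",
    "102|t|warfarin and bleeding .",
    "102|a|no relation was found .",
    "102\t0\t8\twarfarin\tChemical\tD014859",
    "102\t13\t21\tbleeding\tDisease\tD006470"), path)
  path
}

test_that("PubTator reader builds documents with mentions and relations", {
  f <- two_doc_pubtator(tempfile(fileext = ".pubtator"))
  docs <- read_pubtator(f)
  expect_length(docs, 2L)
  expect_equal(vapply(docs, function(d) nrow(d$mentions), integer(1)), c(2L, 2L))
  expect_equal(docs[[1]]$gold_relations,
               tibble::tibble(chem_id = "D001241", dis_id = "D009325"))
  expect_equal(nrow(docs[[2]]$gold_relations), 0L)
  expect_true(all(docs[[1]]$mentions$offset_ok))
  # direct copy of a relation line into the gold set
  expect_true(paste("D001241", "D009325") %in%
                with(docs[[1]]$gold_relations, paste(chem_id, dis_id)))
})

test_that("offset/text mismatch warns but keeps the document", {
  f <- tempfile(fileext = ".pubtator")
  writeLines(c("103|t|aspirin caused nausea .",
               "103|a|end .",
               "103\t0\t7\tibuprofen\tChemical\tD007052"), f)
  expect_warning(docs <- read_pubtator(f), "slice")
  expect_length(docs, 1L)
  expect_false(docs[[1]]$mentions$offset_ok[1])
})

test_that("writer round-trips entity and relation lines", {
  f <- two_doc_pubtator(tempfile(fileext = ".pubtator"))
  docs <- read_pubtator(f)
  out <- tempfile(fileext = ".pubtator")
  write_pubtator(docs, out)
  docs2 <- read_pubtator(out)
  for (i in 1:2) {
    expect_equal(docs2[[i]]$mentions, docs[[i]]$mentions)
    expect_equal(docs2[[i]]$gold_relations, docs[[i]]$gold_relations)
    expect_equal(docs2[[i]]$text, docs[[i]]$text)
  }
})

write_parse_fixture <- function(dep_lines, tree_lines) {
  dp <- tempfile(fileext = ".dep"); tp <- tempfile(fileext = ".ptb")
  writeLines(dep_lines, dp); writeLines(tree_lines, tp)
  list(dep = dp, tree = tp)
}

test_that("parse attachment aligns tokens, arcs and tree leaves", {
  f <- tempfile(fileext = ".pubtator")
  writeLines(c("201|t|a b c", "201|a|d e"), f)
  p <- write_parse_fixture(
    c("0\ta\ta\tNN\tB-NP\t_\t1\tnsubj",
      "1\tb\tb\tVB\tB-VP\t_\t-1\troot",
      "2\tc\tc\tNN\tB-NP\t_\t1\tdobj",
      "",
      "0\td\td\tNN\tB-NP\t_\t-1\troot",
      "1\te\te\tNN\tI-NP\t_\t0\tnn"),
    c("(S (NP (NN a)) (VP (VB b) (NN c)))", "(NP (NN d) (NN e))"))
  docs <- read_parses(p$dep, p$tree, read_pubtator(f))
  expect_length(docs[[1]]$sentences, 2L)
  s1 <- docs[[1]]$sentences[[1]]
  expect_equal(nrow(s1$tokens), 3L)
  expect_equal(nrow(s1$dep_arcs), 3L)
  expect_length(tree_leaves(s1$phrase_tree), 3L)
  expect_equal(s1$char_span, c(0L, 5L))
})

test_that("cyclic, empty and mismatched parses are rejected", {
  f <- tempfile(fileext = ".pubtator")
  writeLines(c("202|t|a b", "202|a|"), f)
  cyc <- write_parse_fixture(
    c("0\ta\ta\tNN\tB-NP\t_\t1\tnsubj", "1\tb\tb\tVB\tB-VP\t_\t0\tdep"),
    "(S (NN a) (VB b))")
  expect_error(read_parses(cyc$dep, cyc$tree, read_pubtator(f)), "root|tree")
  mism <- write_parse_fixture(
    c("0\ta\ta\tNN\tB-NP\t_\t-1\troot", "1\tb\tb\tVB\tB-VP\t_\t0\tdep"),
    "(S (NN a))")
  expect_error(read_parses(mism$dep, mism$tree, read_pubtator(f)), "leaf")
  empt <- write_parse_fixture(character(), character())
  expect_error(read_parses(empt$dep, empt$tree, read_pubtator(f)),
               "ran out of parse blocks")
})

test_that("candidate generation enumerates co-sentential pairs with gold labels", {
  corpus <- shared_fixture_corpus()
  cand <- corpus_candidates(corpus$documents)
  gold_key <- with(corpus$relations, paste(doc_id, chem_id, dis_id))
  # brute-force pair enumeration per sentence
  for (doc in corpus$documents) {
    m <- doc$mentions
    for (si in unique(m$sentence_index)) {
      n_chem <- sum(m$etype == "chemical" & m$sentence_index == si)
      n_dis <- sum(m$etype == "disease" & m$sentence_index == si)
      got <- sum(cand$doc_id == doc$doc_id & cand$sentence_index == si)
      expect_identical(got, as.integer(n_chem * n_dis))
    }
  }
  # distant-supervision labels match the document-level gold set
  expect_identical(cand$label == 1L,
                   paste(cand$doc_id, cand$chem_concept, cand$dis_concept) %in% gold_key)
  # every gold relation with a co-sentential pair yields >= 1 positive candidate
  covered <- with(cand[cand$label == 1L, ], paste(doc_id, chem_concept, dis_concept))
  expect_true(all(gold_key %in% covered))
})

test_that("cross-sentence pairs yield no candidates", {
  f <- tempfile(fileext = ".pubtator")
  writeLines(c("301|t|aspirin was given .",
               "301|a|nausea developed later .",
               "301\t0\t7\taspirin\tChemical\tD001241",
               "301\t20\t26\tnausea\tDisease\tD009325",
               "301\tCID\tD001241\tD009325"), f)
  p <- write_parse_fixture(
    c("0\taspirin\taspirin\tNN\tB-NP\t_\t2\tnsubjpass",
      "1\twas\tbe\tVBD\tB-VP\t_\t2\tauxpass",
      "2\tgiven\tgive\tVBN\tI-VP\t_\t-1\troot",
      "3\t.\t.\t.\tO\t_\t2\tpunct",
      "",
      "0\tnausea\tnausea\tNN\tB-NP\t_\t1\tnsubj",
      "1\tdeveloped\tdevelop\tVBD\tB-VP\t_\t-1\troot",
      "2\tlater\tlater\tRB\tB-ADVP\t_\t1\tadvmod",
      "3\t.\t.\t.\tO\t_\t1\tpunct"),
    c("(S (NP (NN aspirin)) (VP (VBD was) (VP (VBN given))) (. .))",
      "(S (NP (NN nausea)) (VP (VBD developed) (ADVP (RB later))) (. .))"))
  docs <- expect_message(read_parses(p$dep, p$tree, read_pubtator(f)), NA)
  expect_equal(nrow(generate_candidates(docs[[1]])), 0L)
})

test_that("unnormalized mentions are labeled negative", {
  corpus <- shared_fixture_corpus()
  doc <- corpus$documents[[1]]
  doc$mentions$concept_id[doc$mentions$etype == "disease"] <- "-1"
  cand <- generate_candidates(doc)
  expect_true(all(cand$label == -1L))
})
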