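scores_tbl <- function(ff, fk, pn) {
  tibble::tibble(doc_id = "d", chem_concept = "C", dis_concept = "D",
                 f_feature = ff, f_kernel = fk, p_neural = pn)
}

test_that("combination is the stated convex mixture", {
  s <- scores_tbl(0.9, 0.8, 0.6)
  # corner of the simplex: pure feature model
  expect_equal(combine_scores(s, list(alpha = 1, beta = 0))$p_combined,
               sigmoid(0.9))
  expect_equal(combine_scores(s, list(alpha = 0, beta = 0))$p_combined, 0.6)
  # all components at 0.5 -> 0.5 for any valid weights
  s5 <- scores_tbl(0, 0, 0.5)
  for (w in list(c(0.2, 0.3), c(0.68, 0.15), c(0, 1))) {
    expect_equal(combine_scores(s5, list(alpha = w[1], beta = w[2]))$p_combined, 0.5)
  }
  # the published weight setting, on probability-scale components
  p <- 0.68 * 0.9 + 0.15 * 0.8 + (1 - 0.68 - 0.15) * 0.6
  expect_equal(p, 0.834)
  s_probs <- scores_tbl(log(0.9 / 0.1), log(0.8 / 0.2), 0.6)  # sigmoid^-1
  expect_equal(combine_scores(s_probs, list(alpha = 0.68, beta = 0.15))$p_combined,
               0.834, tolerance = 1e-12)
})

test_that("combination is monotone in each component", {
  w <- list(alpha = 0.4, beta = 0.3)
  base <- combine_scores(scores_tbl(0.1, -0.2, 0.5), w)$p_combined
  expect_gt(combine_scores(scores_tbl(0.6, -0.2, 0.5), w)$p_combined, base)
  expect_gt(combine_scores(scores_tbl(0.1, 0.3, 0.5), w)$p_combined, base)
  expect_gt(combine_scores(scores_tbl(0.1, -0.2, 0.9), w)$p_combined, base)
})

test_that("weight config enforces the simplex", {
  expect_error(weight_config(0.7, 0.5), "alpha")
  expect_error(weight_config(-0.1, 0.2), "alpha")
  w <- weight_config(0.68, 0.15)
  expect_equal(w$threshold, 0.5)
})

test_that("document aggregation takes the maximum and applies the boundary", {
  tbl <- tibble::tibble(
    doc_id = c("d1", "d1", "d1", "d2"),
    chem_concept = c("C1", "C1", "C1", "C2"),
    dis_concept = c("D1", "D1", "D1", "D2"),
    p_combined = c(0.2, 0.7, 0.4, 0.51))
  rel <- document_relations(tbl)
  expect_equal(nrow(rel), 2L)
  expect_equal(rel$p[rel$doc_id == "d1"], 0.7)   # max over the three mentions
  expect_equal(nrow(document_relations(dplyr::mutate(tbl, p_combined = 0.4))), 0L)
  # invariance to candidate ordering
  perm <- c(3, 1, 4, 2)
  expect_equal(dplyr::arrange(document_relations(tbl[perm, ]), doc_id),
               dplyr::arrange(rel, doc_id))
  # unnormalized concepts are never emitted
  tbl$chem_concept[4] <- "-1"
  expect_equal(nrow(document_relations(tbl)), 1L)
})

# Build a one-sentence document from a single template (title = sentence,
# empty abstract), going through the standard readers so offsets are honest.
rule_doc <- function(template_idx, chem = "fentanyl", dis = "hypotension") {
  tpl <- default_templates()[[template_idx]]
  slots <- unique(sub("^\\{(.+)\\}$", "\\1",
                      grep("^\\{.+\\}$", tpl$tokens, value = TRUE)))
  dis_pool <- c(dis, "bradycardia", "seizures")
  di <- 0L
  ents <- list()
  for (s in slots) {
    if (startsWith(s, "C")) {
      ents[[s]] <- list(name = chem, id = "Dchem", etype = "chemical")
    } else {
      di <- di + 1L
      ents[[s]] <- list(name = dis_pool[[di]], id = paste0("Ddis", di),
                        etype = "disease")
    }
  }
  inst <- cdrhybrid:::instantiate_template(tpl, ents)
  text <- paste(inst$surface, collapse = " ")
  starts <- cumsum(c(0L, nchar(inst$surface) + 1L))
  ment <- vapply(inst$mentions, function(m)
    paste("7000001", starts[m$tok_start + 1L],
          starts[m$tok_end] + nchar(inst$surface[[m$tok_end]]), m$name,
          if (m$etype == "chemical") "Chemical" else "Disease", m$id,
          sep = "\t"), character(1))
  rels <- vapply(inst$gold, function(g)
    paste("7000001", "CID", g[[1]], g[[2]], sep = "\t"), character(1))
  td <- tempfile(); dir.create(td)
  writeLines(c(paste0("7000001|t|", text), "7000001|a|", ment, rels, ""),
             file.path(td, "d.pubtator"))
  writeLines(c(paste(seq_along(inst$surface) - 1L, inst$surface, inst$stem,
                     inst$pos, inst$chunk, "_", inst$head, inst$rel, sep = "\t"), ""),
             file.path(td, "d.dep"))
  writeLines(inst$tree, file.path(td, "d.ptb"))
  docs <- read_parses(file.path(td, "d.dep"), file.path(td, "d.ptb"),
                      read_pubtator(file.path(td, "d.pubtator")))
  unlink(td, recursive = TRUE)
  docs[[1]]
}

no_pred <- tibble::tibble(doc_id = character(), chem_id = character(),
                          dis_id = character())

test_that("causal rules fire on trigger patterns with the right direction", {
  doc <- rule_doc(1L)                                # "induced" pattern
  add <- causal_relation_rules(doc, no_pred)
  expect_equal(nrow(add), 1L)
  expect_equal(add$chem_id, "Dchem"); expect_equal(add$dis_id, "Ddis1")
  # disease <during> chemical
  add2 <- causal_relation_rules(rule_doc(2L), no_pred)
  expect_equal(nrow(add2), 1L)
  # adjacency: chemical immediately precedes disease
  add3 <- causal_relation_rules(rule_doc(5L), no_pred)
  expect_equal(add3$rule, "adjacency")
  # negative co-occurrence patterns do not fire
  expect_equal(nrow(causal_relation_rules(rule_doc(8L), no_pred)), 0L)
  # direction-sensitive: disease-before-chemical with "induced" between
  s <- make_sentence(c("nausea", "induced", "by", "aspirin", "."),
                     c("NN", "VBN", "IN", "NN", "."),
                     heads = c(1L, -1L, 1L, 2L, 1L),
                     rels = c("nsubj", "root", "prep", "pobj", "punct"),
                     stems = c("nausea", "induce", "by", "aspirin", "."),
                     tree = "(S (NP (NN nausea)) (VP (VBN induced) (PP (IN by) (NP (NN aspirin)))) (. .))")
  doc2 <- structure(list(
    doc_id = "x1", title = "t", abstract = "a", text = "t a",
    mentions = tibble::tibble(
      doc_id = "x1", char_start = c(0L, 18L), char_end = c(6L, 25L),
      text = c("nausea", "aspirin"), etype = c("disease", "chemical"),
      concept_id = c("Ddis", "Dchem"), offset_ok = TRUE,
      sentence_index = 0L, tok_start = c(0L, 3L), tok_end = c(1L, 4L)),
    gold_relations = tibble::tibble(chem_id = character(), dis_id = character()),
    sentences = list(s)), class = "cdr_document")
  expect_equal(nrow(causal_relation_rules(doc2, no_pred)), 0L)
  # already-predicted pairs are not re-added
  pred <- tibble::tibble(doc_id = doc$doc_id, chem_id = "Dchem", dis_id = "Ddis1")
  expect_equal(nrow(causal_relation_rules(doc, pred)), 0L)
})

test_that("focused-chemical rules fire only on empty documents", {
  corpus <- shared_fixture_corpus()
  doc <- corpus$documents[[1]]
  # with a predicted relation for this document: unchanged
  pred <- tibble::tibble(doc_id = doc$doc_id, chem_id = "X", dis_id = "Y")
  expect_equal(nrow(focused_chemical_rules(doc, pred)), 0L)
  # empty predictions: title chemicals x all diseases
  add <- focused_chemical_rules(doc, no_pred)
  title_chems <- with(doc$mentions,
                      unique(concept_id[etype == "chemical" &
                                          char_start < nchar(doc$title)]))
  n_dis <- length(unique(doc$mentions$concept_id[doc$mentions$etype == "disease"]))
  if (length(title_chems)) {
    expect_equal(nrow(add), length(title_chems) * n_dis)
    expect_setequal(unique(add$chem_id), title_chems)
  } else {
    expect_equal(nrow(add), n_dis)
  }
  # no title chemical: most frequent chemical wins, ties to first occurrence
  m <- tibble::tibble(
    doc_id = "z", char_start = c(10L, 20L, 30L, 40L, 50L),
    char_end = c(11L, 21L, 31L, 41L, 51L),
    text = c("a", "b", "a", "n1", "n2"),
    etype = c("chemical", "chemical", "chemical", "disease", "disease"),
    concept_id = c("CA", "CB", "CA", "DX", "DY"),
    offset_ok = TRUE, sentence_index = 0L, tok_start = 0L, tok_end = 1L)
  docz <- structure(list(doc_id = "z", title = "short", abstract = "abs",
                         text = "short abs", mentions = m,
                         gold_relations = no_pred[, 2:3], sentences = list()),
                    class = "cdr_document")
  add2 <- focused_chemical_rules(docz, no_pred)
  expect_setequal(unique(add2$chem_id), "CA")
  expect_equal(nrow(add2), 2L)
})

test_that("post-processing only ever adds relations", {
  corpus <- shared_fixture_corpus()
  docs <- corpus$documents
  base <- tibble::tibble(doc_id = docs[[1]]$doc_id,
                         chem_id = docs[[1]]$mentions$concept_id[1],
                         dis_id = "D000000")
  res <- apply_rules(docs, base)
  keys <- function(r) paste(r$doc_id, r$chem_id, r$dis_id)
  expect_true(all(keys(base) %in% keys(res$relations)))
  expect_gte(nrow(res$relations), nrow(base))
  # recall can only grow
  gold <- corpus$relations
  expect_gte(prf(gold, res$relations)$recall, prf(gold, base)$recall)
})

test_that("simplex grid geometry is exact", {
  g <- simplex_grid(0.1)
  expect_equal(nrow(g), 66L)
  expect_true(all(g$alpha + g$beta <= 1 + 1e-12))
  corners <- paste(g$alpha, g$beta)
  expect_true(all(c("1 0", "0 1", "0 0") %in% corners))
  expect_equal(nrow(simplex_grid(0.5)), 6L)
})
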