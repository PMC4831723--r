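#' Synthetic parsed corpora
#'
#' Generates fully parsed synthetic corpora — PubTator text, CoNLL-style
#' dependency blocks, bracketed phrase trees and gold relations — from a
#' small template grammar whose trigger patterns make the gold labels
#' recoverable from the text alone. Each template carries its own hand-coded
#' dependency arcs and phrase tree, so no parser is needed; entity slots are
#' filled from chemical/disease lexicons (multiword names are spliced in
#' with noun-compound arcs). This makes every stage of the pipeline testable
#' end to end without external resources.
#'
#' @name synthetic_fixtures
NULL

fixture_template <- function(id, positive, tokens, stems, pos, chunk,
                             heads, rels, tree, gold) {
  stopifnot(length(tokens) == length(stems), length(tokens) == length(pos),
            length(tokens) == length(chunk), length(tokens) == length(heads),
            length(tokens) == length(rels), sum(heads == -1L) == 1L)
  list(id = id, positive = positive, tokens = tokens, stems = stems, pos = pos,
       chunk = chunk, heads = heads, rels = rels, tree = tree, gold = gold)
}

#' Default sentence templates
#'
#' Nine templates covering positive causal patterns (trigger verbs in both
#' entity orders, entity adjacency, one-chemical/many-disease enumeration)
#' and negative co-occurrence patterns, with dependency paths of length 2-6
#' and off-path dependents for the extended-SDF case.
#'
#' @return List of template objects.
#' @export
default_templates <- function() {
  list(
    fixture_template("induce", TRUE,
      tokens = c("{C1}", "induced", "{D1}", "."),
      stems = c("{C1}", "induce", "{D1}", "."),
      pos = c("NN", "VBD", "NN", "."),
      chunk = c("B-NP", "B-VP", "B-NP", "O"),
      heads = c(1L, -1L, 1L, 1L),
      rels = c("nsubj", "root", "dobj", "punct"),
      tree = "(S (NP {C1}) (VP (VBD induced) (NP {D1})) (. .))",
      gold = list(c("C1", "D1"))),
    fixture_template("during", TRUE,
      tokens = c("{D1}", "developed", "during", "{C1}", "therapy", "."),
      stems = c("{D1}", "develop", "during", "{C1}", "therapy", "."),
      pos = c("NN", "VBD", "IN", "NN", "NN", "."),
      chunk = c("B-NP", "B-VP", "B-PP", "B-NP", "I-NP", "O"),
      heads = c(1L, -1L, 1L, 4L, 2L, 1L),
      rels = c("nsubj", "root", "prep", "nn", "pobj", "punct"),
      tree = "(S (NP {D1}) (VP (VBD developed) (PP (IN during) (NP {C1} (NN therapy)))) (. .))",
      gold = list(c("C1", "D1"))),
    fixture_template("cause", TRUE,
      tokens = c("treatment", "with", "{C1}", "caused", "severe", "{D1}", "."),
      stems = c("treatment", "with", "{C1}", "cause", "severe", "{D1}", "."),
      pos = c("NN", "IN", "NN", "VBD", "JJ", "NN", "."),
      chunk = c("B-NP", "B-PP", "B-NP", "B-VP", "B-NP", "I-NP", "O"),
      heads = c(3L, 0L, 1L, -1L, 5L, 3L, 3L),
      rels = c("nsubj", "prep", "pobj", "root", "amod", "dobj", "punct"),
      tree = "(S (NP (NN treatment) (PP (IN with) (NP {C1}))) (VP (VBD caused) (NP (JJ severe) {D1})) (. .))",
      gold = list(c("C1", "D1"))),
    fixture_template("associate", TRUE,
      tokens = c("{C1}", "was", "associated", "with", "{D1}", "in", "patients", "."),
      stems = c("{C1}", "be", "associate", "with", "{D1}", "in", "patient", "."),
      pos = c("NN", "VBD", "VBN", "IN", "NN", "IN", "NNS", "."),
      chunk = c("B-NP", "B-VP", "I-VP", "B-PP", "B-NP", "B-PP", "B-NP", "O"),
      heads = c(2L, 2L, -1L, 2L, 3L, 2L, 5L, 2L),
      rels = c("nsubjpass", "auxpass", "root", "prep", "pobj", "prep", "pobj", "punct"),
      tree = "(S (NP {C1}) (VP (VBD was) (VP (VBN associated) (PP (IN with) (NP {D1})) (PP (IN in) (NP (NNS patients))))) (. .))",
      gold = list(c("C1", "D1"))),
    fixture_template("adjacent", TRUE,
      tokens = c("{C1}", "{D1}", "was", "reported", "."),
      stems = c("{C1}", "{D1}", "be", "report", "."),
      pos = c("NN", "NN", "VBD", "VBN", "."),
      chunk = c("B-NP", "I-NP", "B-VP", "I-VP", "O"),
      heads = c(1L, 3L, 3L, -1L, 3L),
      rels = c("nn", "nsubjpass", "auxpass", "root", "punct"),
      tree = "(S (NP {C1} {D1}) (VP (VBD was) (VP (VBN reported))) (. .))",
      gold = list(c("C1", "D1"))),
    fixture_template("enumerate", TRUE,
      tokens = c("{C1}", "induced", "{D1}", ",", "{D2}", "and", "{D3}", "."),
      stems = c("{C1}", "induce", "{D1}", ",", "{D2}", "and", "{D3}", "."),
      pos = c("NN", "VBD", "NN", ",", "NN", "CC", "NN", "."),
      chunk = c("B-NP", "B-VP", "B-NP", "O", "B-NP", "O", "B-NP", "O"),
      heads = c(1L, -1L, 1L, 2L, 2L, 2L, 2L, 1L),
      rels = c("nsubj", "root", "dobj", "punct", "conj", "cc", "conj", "punct"),
      tree = "(S (NP {C1}) (VP (VBD induced) (NP (NP {D1}) (, ,) (NP {D2}) (CC and) (NP {D3}))) (. .))",
      gold = list(c("C1", "D1"), c("C1", "D2"), c("C1", "D3"))),
    fixture_template("conj_neg", FALSE,
      tokens = c("{C1}", "and", "{D1}", "levels", "were", "measured", "."),
      stems = c("{C1}", "and", "{D1}", "level", "be", "measure", "."),
      pos = c("NN", "CC", "NN", "NNS", "VBD", "VBN", "."),
      chunk = c("B-NP", "I-NP", "I-NP", "I-NP", "B-VP", "I-VP", "O"),
      heads = c(3L, 0L, 0L, 5L, 5L, -1L, 5L),
      rels = c("nn", "cc", "conj", "nsubjpass", "auxpass", "root", "punct"),
      tree = "(S (NP {C1} (CC and) {D1} (NNS levels)) (VP (VBD were) (VP (VBN measured))) (. .))",
      gold = list()),
    fixture_template("before_neg", FALSE,
      tokens = c("patients", "received", "{C1}", "before", "{D1}", "onset", "."),
      stems = c("patient", "receive", "{C1}", "before", "{D1}", "onset", "."),
      pos = c("NNS", "VBD", "NN", "IN", "NN", "NN", "."),
      chunk = c("B-NP", "B-VP", "B-NP", "B-PP", "B-NP", "I-NP", "O"),
      heads = c(1L, -1L, 1L, 1L, 5L, 3L, 1L),
      rels = c("nsubj", "root", "dobj", "prep", "nn", "pobj", "punct"),
      tree = "(S (NP (NNS patients)) (VP (VBD received) (NP {C1}) (PP (IN before) (NP {D1} (NN onset)))) (. .))",
      gold = list()),
    fixture_template("study_neg", FALSE,
      tokens = c("the", "study", "evaluated", "{C1}", "exposure", "and", "{D1}", "outcomes", "."),
      stems = c("the", "study", "evaluate", "{C1}", "exposure", "and", "{D1}", "outcome", "."),
      pos = c("DT", "NN", "VBD", "NN", "NN", "CC", "NN", "NNS", "."),
      chunk = c("B-NP", "I-NP", "B-VP", "B-NP", "I-NP", "O", "B-NP", "I-NP", "O"),
      heads = c(1L, 2L, -1L, 4L, 2L, 4L, 7L, 4L, 2L),
      rels = c("det", "nsubj", "root", "nn", "dobj", "cc", "nn", "conj", "punct"),
      tree = "(S (NP (DT the) (NN study)) (VP (VBD evaluated) (NP (NP {C1} (NN exposure)) (CC and) (NP {D1} (NNS outcomes)))) (. .))",
      gold = list()))
}

#' Default entity lexicons
#'
#' Small chemical and disease lexicons with MeSH-style concept IDs; a few
#' names are multiword to exercise head finding and mention splicing.
#'
#' @return List of two tibbles (`chemicals`, `diseases`) with `name`, `id`.
#' @export
default_lexicons <- function() {
  chems <- c("fentanyl", "aspirin", "morphine", "warfarin", "haloperidol",
             "clozapine", "lithium carbonate", "valproic acid", "cisplatin",
             "doxorubicin", "gentamicin", "ketamine", "naloxone", "propofol",
             "tacrolimus", "cyclosporine", "methotrexate", "ibuprofen",
             "dopamine", "heparin", "amiodarone", "phenytoin", "carbamazepine",
             "prednisone")
  dis <- c("hypotension", "bradycardia", "seizures", "nephrotoxicity",
           "hepatotoxicity", "thrombocytopenia", "chest wall rigidity",
           "respiratory depression", "cardiac arrhythmia", "renal failure",
           "hearing loss", "neutropenia", "hyperglycemia", "pancreatitis",
           "agranulocytosis", "tardive dyskinesia", "myopathy", "anemia",
           "hypertension", "delirium", "ototoxicity", "osteoporosis",
           "gingival hyperplasia", "akathisia")
  list(chemicals = tibble(name = chems, id = sprintf("D%06d", 1000L + seq_along(chems))),
       diseases = tibble(name = dis, id = sprintf("D%06d", 2000L + seq_along(dis))))
}

#' Specification of a synthetic corpus
#'
#' @param n_documents Number of documents.
#' @param sentences_per_doc Integer range `c(min, max)` of sentences per
#'   document (the first sentence is the title).
#' @param templates Template list (default [default_templates()]); must
#'   contain at least one positive and one negative pattern.
#' @param lexicons Entity lexicons (default [default_lexicons()]).
#' @param label_noise Probability in `[0, 0.5)` of flipping the
#'   document-level relation of a candidate pair (distant-supervision noise).
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return A `cdr_fixture_spec`.
#' @export
fixture_spec <- function(n_documents = 100L, sentences_per_doc = c(2L, 4L),
                         templates = default_templates(),
                         lexicons = default_lexicons(),
                         label_noise = 0, seed = 20160414L) {
  pos <- vapply(templates, function(t) t$positive, logical(1))
  stopifnot(n_documents >= 1L, any(pos), any(!pos),
            label_noise >= 0, label_noise < 0.5,
            length(sentences_per_doc) == 2L)
  structure(list(n_documents = as.integer(n_documents),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 templates = templates, lexicons = lexicons,
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "cdr_fixture_spec")
}

split_name <- function(name) strsplit(name, " ", fixed = TRUE)[[1]]

# instantiate one template with sampled entities; returns tokens tibble-ish
# lists plus mention descriptors and intended relation pairs
instantiate_template <- function(tpl, entities) {
  # entities: named list slot -> list(name, id, etype)
  surface <- character(); stem <- character(); pos <- character()
  chunk <- character(); head_t <- integer(); rel <- character()
  anchor <- integer(length(tpl$tokens))     # template position -> final anchor index
  owner <- integer(0)                       # final index -> template position
  mention_rows <- list()
  for (tpos in seq_along(tpl$tokens)) {
    tok <- tpl$tokens[[tpos]]
    slot <- sub("^\\{(.+)\\}$", "\\1", tok)
    if (slot != tok) {                      # entity placeholder
      ent <- entities[[slot]]
      parts <- split_name(ent$name)
      k <- length(parts)
      first_idx <- length(surface)
      surface <- c(surface, parts)
      stem <- c(stem, tolower(parts))
      pos <- c(pos, rep("NN", k))
      chunk <- c(chunk, tpl$chunk[[tpos]], rep("I-NP", k - 1L))
      head_t <- c(head_t, rep(NA_integer_, k))
      rel <- c(rel, rep(NA_character_, k))
      anchor[[tpos]] <- length(surface) - 1L    # last entity token (0-based)
      # entity-internal tokens depend on the last token via noun compounds
      for (q in seq_len(k - 1L)) {
        head_t[[first_idx + q]] <- anchor[[tpos]]
        rel[[first_idx + q]] <- "nn"
      }
      owner <- c(owner, rep(tpos, k))
      mention_rows[[slot]] <- list(slot = slot, tok_start = first_idx,
                                   tok_end = anchor[[tpos]] + 1L,
                                   name = ent$name, id = ent$id, etype = ent$etype)
    } else {
      surface <- c(surface, tok)
      stem <- c(stem, tpl$stems[[tpos]])
      pos <- c(pos, tpl$pos[[tpos]])
      chunk <- c(chunk, tpl$chunk[[tpos]])
      head_t <- c(head_t, NA_integer_)
      rel <- c(rel, NA_character_)
      anchor[[tpos]] <- length(surface) - 1L
      owner <- c(owner, tpos)
    }
  }
  # resolve template-level heads through the anchors
  for (i in seq_along(surface)) {
    if (!is.na(head_t[[i]])) next            # entity-internal, already set
    tpos <- owner[[i]]
    h <- tpl$heads[[tpos]]
    head_t[[i]] <- if (h == -1L) -1L else anchor[[h + 1L]]
    rel[[i]] <- tpl$rels[[tpos]]
  }
  tree <- tpl$tree
  for (slot in names(entities)) {
    leaves <- paste(sprintf("(NN %s)", split_name(entities[[slot]]$name)),
                    collapse = " ")
    tree <- sub(sprintf("{%s}", slot), leaves, tree, fixed = TRUE)
  }
  gold <- lapply(tpl$gold, function(pr) c(entities[[pr[[1]]]]$id, entities[[pr[[2]]]]$id))
  list(surface = surface, stem = stem, pos = pos, chunk = chunk,
       head = head_t, rel = rel, tree = tree,
       mentions = mention_rows, gold = gold, template_id = tpl$id)
}

template_slots <- function(tpl) {
  slots <- grep("^\\{.+\\}$", tpl$tokens, value = TRUE)
  sub("^\\{(.+)\\}$", "\\1", slots)
}

#' Generate a synthetic parsed corpus
#'
#' Writes three aligned files to `dir`: `corpus.pubtator` (text, mention and
#' relation lines), `corpus.dep` (CoNLL-style dependency blocks, head column
#' 0-based with -1 root) and `corpus.ptb` (one bracketed tree per line), plus
#' a `manifest.json` recording the seed and counts. Entities are sampled
#' without concept repetition within a document, so distant-supervision
#' labels are exact at `label_noise = 0`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return List with `paths`, the parsed `documents` (read back through
#'   [read_pubtator()] and [read_parses()], which re-validates all offsets),
#'   and the gold `relations` tibble.
#' @export
generate_corpus <- function(spec, dir = tempfile("cdr_fixture_")) {
  stopifnot(inherits(spec, "cdr_fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  n_tpl <- length(spec$templates)
  pub <- character(); dep <- character(); ptb <- character()
  all_gold <- list()
  for (di in seq_len(spec$n_documents)) {
    doc_id <- sprintf("9%06d", di)
    n_sent <- sample(spec$sentences_per_doc[1]:spec$sentences_per_doc[2], 1L)
    tpls <- spec$templates[sample.int(n_tpl, n_sent, replace = TRUE)]
    slot_counts <- lapply(tpls, template_slots)
    n_chem <- sum(vapply(slot_counts, function(s) sum(startsWith(s, "C")), integer(1)))
    n_dis <- sum(vapply(slot_counts, function(s) sum(startsWith(s, "D")), integer(1)))
    if (n_chem > nrow(spec$lexicons$chemicals) || n_dis > nrow(spec$lexicons$diseases)) {
      stop("entity lexicon too small for the requested distinct entities per document")
    }
    chem_pool <- spec$lexicons$chemicals[sample.int(nrow(spec$lexicons$chemicals), n_chem), ]
    dis_pool <- spec$lexicons$diseases[sample.int(nrow(spec$lexicons$diseases), n_dis), ]
    ci <- 0L; dii <- 0L
    sent_insts <- lapply(seq_along(tpls), function(si) {
      slots <- slot_counts[[si]]
      ents <- list()
      for (s in slots) {
        if (startsWith(s, "C")) {
          ci <<- ci + 1L
          ents[[s]] <- list(name = chem_pool$name[[ci]], id = chem_pool$id[[ci]],
                            etype = "chemical")
        } else {
          dii <<- dii + 1L
          ents[[s]] <- list(name = dis_pool$name[[dii]], id = dis_pool$id[[dii]],
                            etype = "disease")
        }
      }
      instantiate_template(tpls[[si]], ents)
    })
    # assemble text and offsets: title = sentence 1, abstract = the rest
    sent_texts <- vapply(sent_insts, function(s) paste(s$surface, collapse = " "),
                         character(1))
    title <- sent_texts[[1]]
    abstract <- paste(sent_texts[-1], collapse = " ")
    offset <- 0L
    mention_lines <- character()
    for (si in seq_along(sent_insts)) {
      inst <- sent_insts[[si]]
      tok_start_off <- integer(length(inst$surface))
      cur <- offset
      for (ti in seq_along(inst$surface)) {
        tok_start_off[[ti]] <- cur
        cur <- cur + nchar(inst$surface[[ti]]) + 1L   # +1 for the joining space
      }
      for (m in inst$mentions) {
        m_start <- tok_start_off[[m$tok_start + 1L]]
        m_end <- tok_start_off[[m$tok_end]] + nchar(inst$surface[[m$tok_end]])
        mention_lines <- c(mention_lines,
          paste(doc_id, m_start, m_end, m$name,
                if (m$etype == "chemical") "Chemical" else "Disease", m$id,
                sep = "\t"))
      }
      offset <- offset + nchar(sent_texts[[si]]) + 1L
    }
    # document-level gold relations with optional distant-supervision noise
    doc_gold <- list()
    for (inst in sent_insts) {
      chems <- Filter(function(m) m$etype == "chemical", inst$mentions)
      diss <- Filter(function(m) m$etype == "disease", inst$mentions)
      gold_keys <- vapply(inst$gold, paste, "", collapse = "\r")
      for (cm in chems) for (dm in diss) {
        intended <- paste(cm$id, dm$id, sep = "\r") %in% gold_keys
        if (spec$label_noise > 0 && stats::runif(1) < spec$label_noise) {
          intended <- !intended
        }
        if (intended) doc_gold[[length(doc_gold) + 1L]] <- c(cm$id, dm$id)
      }
    }
    rel_lines <- unique(vapply(doc_gold, function(g)
      paste(doc_id, "CID", g[[1]], g[[2]], sep = "\t"), character(1)))
    pub <- c(pub, paste0(doc_id, "|t|", title), paste0(doc_id, "|a|", abstract),
             mention_lines, rel_lines, "")
    dep <- c(dep, paste0("# doc ", doc_id))
    for (inst in sent_insts) {
      rows <- paste(seq_along(inst$surface) - 1L, inst$surface, inst$stem,
                    inst$pos, inst$chunk, "_", inst$head, inst$rel, sep = "\t")
      dep <- c(dep, rows, "")
      ptb <- c(ptb, inst$tree)
    }
    if (length(doc_gold)) {
      all_gold[[doc_id]] <- tibble(
        doc_id = doc_id,
        chem_id = vapply(doc_gold, `[`, "", 1L),
        dis_id = vapply(doc_gold, `[`, "", 2L))
    }
  }
  paths <- list(pubtator = file.path(dir, "corpus.pubtator"),
                dep = file.path(dir, "corpus.dep"),
                tree = file.path(dir, "corpus.ptb"),
                manifest = file.path(dir, "manifest.json"))
  writeLines(pub, paths$pubtator)
  writeLines(dep, paths$dep)
  writeLines(ptb, paths$tree)
  jsonlite::write_json(list(seed = spec$seed, n_documents = spec$n_documents,
                            label_noise = spec$label_noise,
                            templates = vapply(spec$templates, function(t) t$id, "")),
                       paths$manifest, auto_unbox = TRUE)
  documents <- read_parses(paths$dep, paths$tree, read_pubtator(paths$pubtator))
  relations <- if (length(all_gold)) distinct(bind_rows(all_gold)) else
    tibble(doc_id = character(), chem_id = character(), dis_id = character())
  list(paths = paths, documents = documents, relations = relations, dir = dir)
}

#' Worked example: the fentanyl side-effect sentence
#'
#' A single parsed document whose abstract is the classic enumeration
#' sentence ("Various reported side effects of fentanyl administration
#' include ...") with one chemical and four disease mentions, packaged with a
#' plausible hand parse. Useful for demonstrating SDPT/SDF/SPF and the SDP
#' sequences.
#'
#' @return A parsed `cdr_document`.
#' @export
worked_example_sentence1 <- function() {
  title <- "Side effects of fentanyl ."
  abstract <- paste("Various reported side effects of fentanyl administration",
                    "include \" chest wall rigidity \" , \" hypotension \" ,",
                    "\" respiratory depression \" and \" bradycardia \" .")
  text <- paste(title, abstract, sep = " ")
  find_mention <- function(needle, etype, id, n = 1L) {
    at <- gregexpr(needle, text, fixed = TRUE)[[1]]
    vapply(at[seq_len(min(n, length(at)))], function(s)
      paste("2016001", s - 1L, s - 1L + nchar(needle), needle,
            if (etype == "chemical") "Chemical" else "Disease", id, sep = "\t"),
      character(1))
  }
  pub <- c(paste0("2016001|t|", title), paste0("2016001|a|", abstract),
           find_mention("fentanyl", "chemical", "D005283", n = 2L),
           find_mention("chest wall rigidity", "disease", "D009127"),
           find_mention("hypotension", "disease", "D007022"),
           find_mention("respiratory depression", "disease", "D012131"),
           find_mention("bradycardia", "disease", "D001919"),
           paste("2016001", "CID", "D005283", "D009127", sep = "\t"),
           paste("2016001", "CID", "D005283", "D007022", sep = "\t"),
           paste("2016001", "CID", "D005283", "D012131", sep = "\t"),
           paste("2016001", "CID", "D005283", "D001919", sep = "\t"))
  conll_row <- function(i, surf, stem, pos, chunk, head, rel) {
    paste(i, surf, stem, pos, chunk, "_", head, rel, sep = "\t")
  }
  title_dep <- c(conll_row(0, "Side", "side", "NN", "B-NP", 1, "nn"),
                 conll_row(1, "effects", "effect", "NNS", "I-NP", -1, "root"),
                 conll_row(2, "of", "of", "IN", "B-PP", 1, "prep"),
                 conll_row(3, "fentanyl", "fentanyl", "NN", "B-NP", 2, "pobj"),
                 conll_row(4, ".", ".", ".", "O", 1, "punct"))
  s1 <- list(
    c("Various", "various", "JJ", "B-NP", 3, "amod"),
    c("reported", "report", "VBN", "I-NP", 3, "amod"),
    c("side", "side", "NN", "I-NP", 3, "nn"),
    c("effects", "effect", "NNS", "I-NP", 7, "nsubj"),
    c("of", "of", "IN", "B-PP", 3, "prep"),
    c("fentanyl", "fentanyl", "NN", "B-NP", 6, "nn"),
    c("administration", "administration", "NN", "I-NP", 4, "pobj"),
    c("include", "include", "VBP", "B-VP", -1, "root"),
    c("\"", "\"", "``", "O", 11, "punct"),
    c("chest", "chest", "NN", "B-NP", 11, "nn"),
    c("wall", "wall", "NN", "I-NP", 11, "nn"),
    c("rigidity", "rigidity", "NN", "I-NP", 7, "dobj"),
    c("\"", "\"", "''", "O", 11, "punct"),
    c(",", ",", ",", "O", 11, "punct"),
    c("\"", "\"", "``", "O", 15, "punct"),
    c("hypotension", "hypotension", "NN", "B-NP", 11, "conj"),
    c("\"", "\"", "''", "O", 15, "punct"),
    c(",", ",", ",", "O", 11, "punct"),
    c("\"", "\"", "``", "O", 20, "punct"),
    c("respiratory", "respiratory", "JJ", "B-NP", 20, "amod"),
    c("depression", "depression", "NN", "I-NP", 11, "conj"),
    c("\"", "\"", "''", "O", 20, "punct"),
    c("and", "and", "CC", "O", 11, "cc"),
    c("\"", "\"", "``", "O", 24, "punct"),
    c("bradycardia", "bradycardia", "NN", "B-NP", 11, "conj"),
    c("\"", "\"", "''", "O", 24, "punct"),
    c(".", ".", ".", "O", 7, "punct"))
  s1_dep <- vapply(seq_along(s1), function(i) {
    r <- s1[[i]]
    conll_row(i - 1L, r[[1]], r[[2]], r[[3]], r[[4]], r[[5]], r[[6]])
  }, character(1))
  title_tree <- "(NP (NP (NN Side) (NNS effects)) (PP (IN of) (NP (NN fentanyl))) (. .))"
  s1_tree <- paste0(
    "(S (NP (NP (JJ Various) (VBN reported) (NN side) (NNS effects))",
    " (PP (IN of) (NP (NN fentanyl) (NN administration))))",
    " (VP (VBP include) (NP (NP (`` \") (NN chest) (NN wall) (NN rigidity) ('' \"))",
    " (, ,) (NP (`` \") (NN hypotension) ('' \"))",
    " (, ,) (NP (`` \") (JJ respiratory) (NN depression) ('' \"))",
    " (CC and) (NP (`` \") (NN bradycardia) ('' \")))) (. .))")
  td <- tempfile("sentence1_")
  dir.create(td)
  writeLines(c(pub, ""), file.path(td, "doc.pubtator"))
  writeLines(c(title_dep, "", s1_dep, ""), file.path(td, "doc.dep"))
  writeLines(c(title_tree, s1_tree), file.path(td, "doc.ptb"))
  docs <- read_parses(file.path(td, "doc.dep"), file.path(td, "doc.ptb"),
                      read_pubtator(file.path(td, "doc.pubtator")))
  unlink(td, recursive = TRUE)
  docs[[1]]
}
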