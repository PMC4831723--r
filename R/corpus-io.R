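#' @importFrom dplyr %>% arrange bind_rows distinct filter group_by left_join
#'   mutate n pull rename row_number select slice summarise ungroup anti_join
#'   semi_join
#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# ---- document container ------------------------------------------------------

new_document <- function(doc_id, title, abstract, mentions, gold_relations) {
  structure(
    list(
      doc_id = doc_id,
      title = title,
      abstract = abstract,
      # PubTator convention: offsets are 0-based half-open over
      # title + single space + abstract
      text = paste(title, abstract, sep = " "),
      mentions = mentions,
      gold_relations = gold_relations,
      sentences = list()
    ),
    class = "cdr_document"
  )
}

#' @export
print.cdr_document <- function(x, ...) {
  cat(sprintf("<cdr_document %s: %d sentence(s), %d mention(s), %d gold relation(s)>\n",
              x$doc_id, length(x$sentences), nrow(x$mentions), nrow(x$gold_relations)))
  invisible(x)
}

empty_mentions <- function() {
  tibble(doc_id = character(), char_start = integer(), char_end = integer(),
         text = character(), etype = character(), concept_id = character(),
         offset_ok = logical(), sentence_index = integer(),
         tok_start = integer(), tok_end = integer())
}

empty_relations <- function() {
  tibble(chem_id = character(), dis_id = character())
}

# ---- PubTator reader / writer ------------------------------------------------

#' Read a PubTator corpus file
#'
#' Parses the plain-text PubTator format: `pmid|t|title` and `pmid|a|abstract`
#' lines, tab-separated entity mention lines
#' (`pmid start end text type concept`), and relation lines
#' (`pmid CID chemical_id disease_id`). Mention character offsets are 0-based
#' half-open over `title + " " + abstract` and are validated against the text;
#' a mismatching mention is kept with `offset_ok = FALSE` and a warning.
#'
#' @param path Path to a PubTator file.
#' @return A list of `cdr_document` objects (sentences not yet attached; see
#'   [read_parses()]).
#' @export
read_pubtator <- function(path) {
  lines <- readLines(path, warn = FALSE)
  docs <- list()          # doc_id -> list(title, abstract, mentions, relations)
  order_ids <- character()
  get_doc <- function(id) {
    if (is.null(docs[[id]])) {
      docs[[id]] <<- list(title = NA_character_, abstract = NA_character_,
                          mentions = list(), relations = list())
      order_ids <<- c(order_ids, id)
    }
    docs[[id]]
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    m <- regmatches(line, regexec("^([^|\t]+)\\|([ta])\\|(.*)$", line))[[1]]
    if (length(m) == 4L) {
      d <- get_doc(m[2])
      if (m[3] == "t") d$title <- m[4] else d$abstract <- m[4]
      docs[[m[2]]] <- d
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) == 4L && fields[2] == "CID") {
      d <- get_doc(fields[1])
      d$relations[[length(d$relations) + 1L]] <- fields[3:4]
      docs[[fields[1]]] <- d
    } else if (length(fields) >= 6L) {
      d <- get_doc(fields[1])
      d$mentions[[length(d$mentions) + 1L]] <- fields[1:6]
      docs[[fields[1]]] <- d
    } else {
      stop(sprintf("malformed PubTator line %d: %s", i, line))
    }
  }

  lapply(order_ids, function(id) {
    d <- docs[[id]]
    if (is.na(d$title) || is.na(d$abstract)) {
      stop(sprintf("document %s is missing its title or abstract line", id))
    }
    text <- paste(d$title, d$abstract, sep = " ")
    mentions <- if (length(d$mentions)) {
      rows <- lapply(d$mentions, function(f) {
        start <- as.integer(f[2]); end <- as.integer(f[3])
        slice <- substr(text, start + 1L, end)
        ok <- identical(slice, f[4])
        if (!ok) {
          warning(sprintf("document %s: mention offsets [%d,%d) slice to %s, not %s",
                          id, start, end, dQuote(slice), dQuote(f[4])),
                  call. = FALSE)
        }
        tibble(doc_id = id, char_start = start, char_end = end, text = f[4],
               etype = tolower(f[5]), concept_id = f[6], offset_ok = ok,
               sentence_index = NA_integer_, tok_start = NA_integer_,
               tok_end = NA_integer_)
      })
      bind_rows(rows)
    } else empty_mentions()
    bad <- setdiff(unique(mentions$etype), c("chemical", "disease"))
    if (length(bad)) {
      stop(sprintf("document %s: unknown entity type(s): %s",
                   id, paste(bad, collapse = ", ")))
    }
    relations <- if (length(d$relations)) {
      distinct(tibble(chem_id = vapply(d$relations, `[`, "", 1L),
                      dis_id = vapply(d$relations, `[`, "", 2L)))
    } else empty_relations()
    doc <- new_document(id, d$title, d$abstract, mentions, relations)
    check_gold_coverage(doc)
    doc
  })
}

check_gold_coverage <- function(doc) {
  ids <- unique(doc$mentions$concept_id)
  missing <- with(doc$gold_relations, union(setdiff(chem_id, ids), setdiff(dis_id, ids)))
  if (length(missing)) {
    message(sprintf("document %s: gold relation concept(s) with no mention: %s",
                    doc$doc_id, paste(missing, collapse = ", ")))
  }
  invisible(doc)
}

#' Write documents back to PubTator format
#'
#' Inverse of [read_pubtator()]: reproduces the title/abstract, mention and
#' relation lines (mentions before relations within each document).
#'
#' @param documents List of `cdr_document` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pubtator <- function(documents, path) {
  out <- unlist(lapply(documents, function(doc) {
    ment <- doc$mentions
    etype_out <- ifelse(ment$etype == "chemical", "Chemical", "Disease")
    c(paste0(doc$doc_id, "|t|", doc$title),
      paste0(doc$doc_id, "|a|", doc$abstract),
      if (nrow(ment)) paste(ment$doc_id, ment$char_start, ment$char_end,
                            ment$text, etype_out, ment$concept_id, sep = "\t"),
      if (nrow(doc$gold_relations))
        paste(doc$doc_id, "CID", doc$gold_relations$chem_id,
              doc$gold_relations$dis_id, sep = "\t"),
      "")
  }))
  writeLines(out, path)
  invisible(path)
}

# ---- parse attachment --------------------------------------------------------

default_conll_columns <- function() {
  # 0-based positions within a CoNLL-style row; column 0 is the token index
  c(surface = 1L, stem = 2L, pos = 3L, chunk = 4L, head = 6L, rel = 7L)
}

read_conll_blocks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  blocks <- list(); cur <- character()
  for (line in lines) {
    if (nzchar(trimws(line))) cur <- c(cur, line)
    else if (length(cur)) { blocks[[length(blocks) + 1L]] <- cur; cur <- character() }
  }
  if (length(cur)) blocks[[length(blocks) + 1L]] <- cur
  blocks
}

parse_conll_block <- function(block, columns, where) {
  rows <- strsplit(block, "[ \t]+")
  need <- max(columns) + 1L
  tok <- lapply(names(columns), function(nm) {
    vapply(rows, function(r) {
      if (length(r) < need) stop(sprintf("%s: CoNLL row has %d field(s), need %d",
                                         where, length(r), need))
      r[[columns[[nm]] + 1L]]
    }, character(1))
  })
  names(tok) <- names(columns)
  n <- length(rows)
  tokens <- tibble(index = seq_len(n) - 1L, surface = tok$surface,
                   stem = tok$stem, pos = tok$pos, chunk = tok$chunk)
  if (any(!nzchar(tokens$surface))) stop(sprintf("%s: empty token surface", where))
  dep_arcs <- tibble(dependent = tokens$index,
                     head = as.integer(tok$head),
                     relation = tok$rel)
  validate_dep_tree(dep_arcs, where)
  list(tokens = tokens, dep_arcs = dep_arcs)
}

validate_dep_tree <- function(dep_arcs, where) {
  n <- nrow(dep_arcs)
  heads <- dep_arcs$head
  if (sum(heads == -1L) != 1L) {
    stop(sprintf("%s: dependency arcs must have exactly one root (head = -1)", where))
  }
  if (any(heads < -1L | heads >= n)) {
    stop(sprintf("%s: dependency head index out of range", where))
  }
  # acyclicity/connectivity: every token must reach the root in <= n steps
  head_of <- heads; names(head_of) <- as.character(dep_arcs$dependent)
  for (i in seq_len(n)) {
    cur <- i - 1L; steps <- 0L
    while (cur != -1L) {
      cur <- head_of[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > n) stop(sprintf("%s: dependency arcs do not form a tree (cycle)", where))
    }
  }
  invisible(dep_arcs)
}

align_tokens_to_text <- function(tokens, text, cursor, where) {
  # cursor: 0-based offset of the first unconsumed character
  starts <- integer(nrow(tokens)); ends <- integer(nrow(tokens))
  for (i in seq_len(nrow(tokens))) {
    while (cursor < nchar(text) && substr(text, cursor + 1L, cursor + 1L) == " ")
      cursor <- cursor + 1L
    tok <- tokens$surface[[i]]
    got <- substr(text, cursor + 1L, cursor + nchar(tok))
    if (!identical(got, tok)) {
      stop(sprintf("%s: token %s does not match document text at offset %d (found %s)",
                   where, dQuote(tok), cursor, dQuote(got)))
    }
    starts[[i]] <- cursor
    cursor <- cursor + nchar(tok)
    ends[[i]] <- cursor
  }
  list(starts = starts, ends = ends, cursor = cursor)
}

#' Attach dependency and phrase parses to documents
#'
#' Reads blank-line-separated CoNLL-style dependency blocks (`dep_path`) and
#' one Penn-bracketed phrase tree per line (`tree_path`), one block/line per
#' sentence in document order, and attaches `Sentence` objects to each
#' document. Sentence segmentation is taken from the parse files; tokens are
#' aligned left-to-right against each document's text (lines starting with
#' `#` in either file are ignored). After attachment, every entity mention is
#' mapped to its sentence and token span; mentions straddling a sentence
#' boundary are dropped with a warning.
#'
#' @param dep_path Path to the dependency file. Head indices are 0-based with
#'   `-1` marking the root.
#' @param tree_path Path to the bracketed-tree file.
#' @param documents List of `cdr_document` from [read_pubtator()].
#' @param columns Named 0-based column positions in the dependency rows
#'   (defaults: surface 1, stem 2, POS 3, chunk 4, head 6, relation 7).
#' @return The documents with `$sentences` populated and mention token spans
#'   filled in.
#' @export
read_parses <- function(dep_path, tree_path, documents,
                        columns = default_conll_columns()) {
  blocks <- read_conll_blocks(dep_path)
  tree_lines <- readLines(tree_path, warn = FALSE)
  tree_lines <- tree_lines[nzchar(trimws(tree_lines)) &
                             !startsWith(trimws(tree_lines), "#")]
  if (length(blocks) != length(tree_lines)) {
    stop(sprintf("parse files disagree: %d dependency block(s) vs %d tree line(s)",
                 length(blocks), length(tree_lines)))
  }
  b <- 1L
  documents <- lapply(documents, function(doc) {
    cursor <- 0L
    sentences <- list()
    text_len <- nchar(doc$text)
    skip_ws <- function(cur) {
      while (cur < text_len && substr(doc$text, cur + 1L, cur + 1L) == " ")
        cur <- cur + 1L
      cur
    }
    while (skip_ws(cursor) < text_len) {
      if (b > length(blocks)) {
        stop(sprintf("document %s: ran out of parse blocks before its text was covered",
                     doc$doc_id))
      }
      where <- sprintf("document %s, sentence %d (parse block %d)",
                       doc$doc_id, length(sentences), b)
      parsed <- parse_conll_block(blocks[[b]], columns, where)
      tree <- parse_penn(tree_lines[[b]])
      leaves <- tree_leaves(tree)
      if (length(leaves) != nrow(parsed$tokens)) {
        stop(sprintf("%s: %d token(s) in dependency block but %d leaf(s) in phrase tree",
                     where, nrow(parsed$tokens), length(leaves)))
      }
      surf <- vapply(leaves, function(l) l$label, character(1))
      if (!identical(surf, parsed$tokens$surface)) {
        warning(sprintf("%s: phrase-tree leaves differ from dependency tokens", where),
                call. = FALSE)
      }
      ali <- align_tokens_to_text(parsed$tokens, doc$text, cursor, where)
      parsed$tokens$char_start <- ali$starts
      parsed$tokens$char_end <- ali$ends
      cursor <- ali$cursor
      sentences[[length(sentences) + 1L]] <- structure(
        list(tokens = parsed$tokens, dep_arcs = parsed$dep_arcs,
             phrase_tree = tree,
             char_span = c(ali$starts[[1]], ali$ends[[length(ali$ends)]])),
        class = "cdr_sentence")
      b <<- b + 1L
    }
    doc$sentences <- sentences
    attach_mentions(doc)
  })
  if (b <= length(blocks)) {
    stop(sprintf("%d unconsumed parse block(s) after the last document", length(blocks) - b + 1L))
  }
  documents
}

attach_mentions <- function(doc) {
  ment <- doc$mentions
  if (!nrow(ment)) return(doc)
  keep <- logical(nrow(ment))
  for (i in seq_len(nrow(ment))) {
    cs <- ment$char_start[[i]]; ce <- ment$char_end[[i]]
    si <- which(vapply(doc$sentences, function(s)
      cs >= s$char_span[[1]] && cs < s$char_span[[2]], logical(1)))
    if (length(si) != 1L) {
      warning(sprintf("document %s: mention %s at [%d,%d) matches no sentence; dropped",
                      doc$doc_id, dQuote(ment$text[[i]]), cs, ce), call. = FALSE)
      next
    }
    sent <- doc$sentences[[si]]
    if (ce > sent$char_span[[2]]) {
      warning(sprintf("document %s: mention %s straddles a sentence boundary; dropped",
                      doc$doc_id, dQuote(ment$text[[i]])), call. = FALSE)
      next
    }
    tok <- which(sent$tokens$char_start < ce & sent$tokens$char_end > cs)
    if (!length(tok)) {
      warning(sprintf("document %s: mention %s covers no token; dropped",
                      doc$doc_id, dQuote(ment$text[[i]])), call. = FALSE)
      next
    }
    keep[[i]] <- TRUE
    ment$sentence_index[[i]] <- si - 1L
    ment$tok_start[[i]] <- sent$tokens$index[[min(tok)]]
    ment$tok_end[[i]] <- sent$tokens$index[[max(tok)]] + 1L
  }
  doc$mentions <- ment[keep, ]
  doc
}

# ---- candidate generation ----------------------------------------------------

#' Generate labeled intra-sentence candidate instances
#'
#' Every chemical-disease mention pair sharing a sentence becomes one
#' candidate; cross-sentence pairs are ignored. The label is `+1` iff the
#' concept-ID pair is among the document's gold relations (distant-supervision
#' projection of document-level relations onto all co-sentential mention
#' pairs), else `-1`. Mentions with `concept_id == "-1"` (unnormalized)
#' always yield label `-1` when `label_unnormalized_negative` is `TRUE`.
#'
#' @param document A parsed `cdr_document` (sentences attached).
#' @param label_unnormalized_negative Treat unnormalized mentions as negative
#'   regardless of gold relations (default `TRUE`).
#' @return A tibble with one row per candidate: mention spans, concept IDs and
#'   `label` in `{+1, -1}`.
#' @export
generate_candidates <- function(document, label_unnormalized_negative = TRUE) {
  ment <- document$mentions
  chem <- ment[ment$etype == "chemical" & !is.na(ment$sentence_index), ]
  dis <- ment[ment$etype == "disease" & !is.na(ment$sentence_index), ]
  out <- list()
  gold_key <- with(document$gold_relations, paste(chem_id, dis_id, sep = "\r"))
  for (i in seq_len(nrow(chem))) for (j in seq_len(nrow(dis))) {
    if (chem$sentence_index[[i]] != dis$sentence_index[[j]]) next
    pos <- paste(chem$concept_id[[i]], dis$concept_id[[j]], sep = "\r") %in% gold_key
    if (label_unnormalized_negative &&
        (chem$concept_id[[i]] == "-1" || dis$concept_id[[j]] == "-1")) pos <- FALSE
    out[[length(out) + 1L]] <- tibble(
      doc_id = document$doc_id,
      sentence_index = chem$sentence_index[[i]],
      chem_concept = chem$concept_id[[i]], chem_text = chem$text[[i]],
      chem_start = chem$tok_start[[i]], chem_end = chem$tok_end[[i]],
      dis_concept = dis$concept_id[[j]], dis_text = dis$text[[j]],
      dis_start = dis$tok_start[[j]], dis_end = dis$tok_end[[j]],
      label = if (pos) 1L else -1L)
  }
  res <- if (length(out)) bind_rows(out) else tibble(
    doc_id = character(), sentence_index = integer(),
    chem_concept = character(), chem_text = character(),
    chem_start = integer(), chem_end = integer(),
    dis_concept = character(), dis_text = character(),
    dis_start = integer(), dis_end = integer(), label = integer())
  res$candidate_id <- paste(res$doc_id, res$sentence_index,
                            res$chem_start, res$dis_start, sep = ":")
  res
}

#' Candidates for a whole corpus
#'
#' @param documents List of parsed `cdr_document` objects.
#' @param ... Passed to [generate_candidates()].
#' @return One tibble of candidates across all documents.
#' @export
corpus_candidates <- function(documents, ...) {
  bind_rows(lapply(documents, generate_candidates, ...))
}

doc_by_id <- function(documents, id) {
  ids <- vapply(documents, function(d) d$doc_id, character(1))
  documents[[match(id, ids)]]
}
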