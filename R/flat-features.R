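#' Flat lexical features for the feature-based model
#'
#' Namespaced binary feature strings describing a chemical-disease candidate:
#' context windows around both entities, entity heads, relative position,
#' token distance buckets, verb indicators, and the flattened dependency
#' features (FDF) describing the SDPT root. Features are vectorized into
#' sparse binary vectors under a vocabulary fitted on training data.
#'
#' @name flat_features
NULL

tok_at <- function(sentence, idx) {
  if (idx < 0L || idx >= nrow(sentence$tokens)) return(NULL)
  sentence$tokens[sentence$tokens$index == idx, ]
}

window_features <- function(sentence, span, role, prefix, window, attrs) {
  feats <- character()
  offsets <- c(-(window:1), 1:window)
  for (off in offsets) {
    # offsets are relative to the span boundary: -1 = token just left of the
    # span, +1 = token just right; the mention interior is skipped
    idx <- if (off < 0L) span[1] + off else span[2] + off - 1L
    tok <- tok_at(sentence, idx)
    for (a in attrs) {
      val <- if (is.null(tok)) "<pad>" else tok[[a]]
      feats <- c(feats, sprintf("%s:%s:%d:%s=%s", prefix, role, off, a, val))
    }
  }
  feats
}

#' Context features: word/stem/POS/chunk in a window around an entity
#'
#' @param sentence A `cdr_sentence`.
#' @param span 0-based half-open token span of the mention.
#' @param role `"chem"` or `"dis"` (feature namespace).
#' @param window Window half-width in tokens (default 3).
#' @return Character vector of feature strings; out-of-sentence positions
#'   yield `<pad>` features.
#' @export
context_features <- function(sentence, span, role, window = 3L) {
  window_features(sentence, span, role, "ctx", window,
                  c("surface", "stem", "pos", "chunk"))
}

#' Entity features: head word, POS and chunk
#'
#' @inheritParams context_features
#' @return Three feature strings.
#' @export
entity_features <- function(sentence, span, role) {
  h <- entity_head(span[1], span[2], sentence)
  tok <- tok_at(sentence, h)
  c(sprintf("ent:%s:head=%s", role, tok$surface),
    sprintf("ent:%s:pos=%s", role, tok$pos),
    sprintf("ent:%s:chunk=%s", role, tok$chunk))
}

#' Position feature: is the chemical before the disease?
#'
#' @param chem_span,dis_span 0-based half-open token spans.
#' @return `"before"` if the chemical precedes the disease, else `"after"`.
#' @export
position_feature <- function(chem_span, dis_span) {
  if (chem_span[1] < dis_span[1]) "before" else "after"
}

#' Distance feature: bucketed count of words between the entities
#'
#' Buckets the number of tokens strictly between the two spans with half-open
#' boundaries: `[0,3)` LessThree, `[3,6)` MoreThreeLessSix, `[6,9)`
#' MoreSixLessNine, `[9,12)` MoreNineLessTwelve, `[12,Inf)` MoreTwelve.
#'
#' @inheritParams position_feature
#' @return The bucket name.
#' @export
distance_feature <- function(chem_span, dis_span) {
  gap <- max(chem_span[1], dis_span[1]) - min(chem_span[2], dis_span[2])
  gap <- max(gap, 0L)
  if (gap < 3L) "LessThree"
  else if (gap < 6L) "MoreThreeLessSix"
  else if (gap < 9L) "MoreSixLessNine"
  else if (gap < 12L) "MoreNineLessTwelve"
  else "MoreTwelve"
}

#' Verb features: verbs before, between, after the two entities
#'
#' Three indicators for the presence of a token with a verbal POS tag
#' (prefix `VB`) strictly before the first entity, strictly between the two,
#' and strictly after the last.
#'
#' @param sentence A `cdr_sentence`.
#' @inheritParams position_feature
#' @return Named logical vector `c(before=, between=, after=)`.
#' @export
verb_features <- function(sentence, chem_span, dis_span) {
  first_start <- min(chem_span[1], dis_span[1])
  gap_lo <- min(chem_span[2], dis_span[2])
  gap_hi <- max(chem_span[1], dis_span[1])
  last_end <- max(chem_span[2], dis_span[2])
  is_verb <- startsWith(sentence$tokens$pos, "VB")
  idx <- sentence$tokens$index
  c(before = any(is_verb & idx < first_start),
    between = any(is_verb & idx >= gap_lo & idx < gap_hi),
    after = any(is_verb & idx >= last_end))
}

#' Flattened dependency features (FDF) of the SDPT root
#'
#' The SDPT root word's position relative to the two entities
#' ([sdpt_root_position()]) plus word/POS/chunk of the root token and its
#' immediate neighbors (window `[-1, 1]`).
#'
#' @param sentence A `cdr_sentence`.
#' @param sdpt_tree Tree from [sdpt()].
#' @inheritParams position_feature
#' @return Character vector of feature strings.
#' @export
fdf_features <- function(sentence, sdpt_tree, chem_span, dis_span) {
  root_idx <- sdpt_tree$token_index
  feats <- sprintf("fdf:rootpos=%s", sdpt_root_position(sdpt_tree, chem_span, dis_span))
  for (off in -1L:1L) {
    tok <- tok_at(sentence, root_idx + off)
    for (a in c("surface", "pos", "chunk")) {
      val <- if (is.null(tok)) "<pad>" else tok[[a]]
      feats <- c(feats, sprintf("fdf:%d:%s=%s", off, a, val))
    }
  }
  feats
}

#' All flat features of one candidate
#'
#' @param sentence A `cdr_sentence`.
#' @param candidate One-row candidate tibble (see [generate_candidates()]).
#' @param groups Feature groups to include, a subset of
#'   `c("context","entity","position","distance","verb","fdf")` — the
#'   ablation order of the feature-based model.
#' @param window Context window half-width.
#' @param sdpt_tree Optional precomputed SDPT (required for `"fdf"`; if the
#'   candidate has no dependency path, FDF features are skipped).
#' @return Character vector of namespaced feature strings.
#' @export
candidate_features <- function(sentence, candidate,
                               groups = c("context", "entity", "position",
                                          "distance", "verb", "fdf"),
                               window = 3L, sdpt_tree = NULL) {
  cs <- c(candidate$chem_start, candidate$chem_end)
  ds <- c(candidate$dis_start, candidate$dis_end)
  feats <- character()
  if ("context" %in% groups) {
    feats <- c(feats, context_features(sentence, cs, "chem", window),
               context_features(sentence, ds, "dis", window))
  }
  if ("entity" %in% groups) {
    feats <- c(feats, entity_features(sentence, cs, "chem"),
               entity_features(sentence, ds, "dis"))
  }
  if ("position" %in% groups) {
    feats <- c(feats, sprintf("pos=%s", position_feature(cs, ds)))
  }
  if ("distance" %in% groups) {
    feats <- c(feats, sprintf("dist=%s", distance_feature(cs, ds)))
  }
  if ("verb" %in% groups) {
    vf <- verb_features(sentence, cs, ds)
    feats <- c(feats, sprintf("verb:%s=%s", names(vf), vf))
  }
  if ("fdf" %in% groups && !is.null(sdpt_tree)) {
    feats <- c(feats, fdf_features(sentence, sdpt_tree, cs, ds))
  }
  unique(feats)
}

#' Fit a feature vocabulary
#'
#' Maps every feature string seen in training to a stable dimension
#' (lexicographic order, so refitting on the same data gives an identical
#' mapping).
#'
#' @param feature_sets List of character vectors (one per training candidate).
#' @return A `cdr_vocabulary`: named integer vector feature -> column.
#' @export
fit_vocabulary <- function(feature_sets) {
  feats <- sort(unique(unlist(feature_sets)))
  vocab <- seq_along(feats)
  names(vocab) <- feats
  class(vocab) <- "cdr_vocabulary"
  vocab
}

#' Vectorize feature sets under a fitted vocabulary
#'
#' Unseen features are dropped (they map to nothing); values are binary.
#'
#' @param feature_sets List of character vectors.
#' @param vocabulary From [fit_vocabulary()].
#' @return A sparse binary `dgCMatrix` (candidates x features).
#' @export
vectorize_features <- function(feature_sets, vocabulary) {
  ij <- lapply(seq_along(feature_sets), function(i) {
    j <- unname(vocabulary[intersect(unique(feature_sets[[i]]), names(vocabulary))])
    cbind(rep.int(i, length(j)), j)
  })
  ij <- do.call(rbind, ij)
  Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1,
                       dims = c(length(feature_sets), length(vocabulary)))
}
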