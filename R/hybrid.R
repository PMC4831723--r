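#' Hybrid combination and rule-based post-processing
#'
#' Per-candidate scores from the three models are merged by the convex
#' combination
#' `P(R_i) = alpha * sigmoid(F(v_i)) + beta * sigmoid(K(t_i)) + (1 - alpha - beta) * N(s_i)`
#' where `F`/`K` are margin decision values of the feature-based and
#' tree-kernel models and `N` is the neural probability. Mention-level
#' probabilities are aggregated to document-level concept pairs by maximum,
#' with the relation emitted when the probability reaches the 0.5 boundary.
#'
#' @name hybrid
NULL

#' Weight configuration for the hybrid combination
#'
#' @param alpha,beta Weights of the feature-based and tree-kernel models, in
#'   `[0, 1]` with `alpha + beta <= 1`; the neural model receives
#'   `1 - alpha - beta`.
#' @param threshold Decision boundary on the combined probability
#'   (default 0.5).
#' @return A `cdr_weights` list.
#' @export
weight_config <- function(alpha, beta, threshold = 0.5) {
  stopifnot(alpha >= 0, beta >= 0, alpha <= 1, beta <= 1, alpha + beta <= 1 + 1e-12)
  structure(list(alpha = alpha, beta = beta, threshold = threshold),
            class = "cdr_weights")
}

#' Combine per-candidate model scores
#'
#' @param scores Tibble with columns `f_feature`, `f_kernel` (decision
#'   values) and `p_neural` (probability).
#' @param weights A [weight_config()] (or list with `alpha`, `beta`).
#' @return `scores` with a `p_combined` column appended.
#' @export
combine_scores <- function(scores, weights) {
  a <- weights$alpha; b <- weights$beta
  dplyr::mutate(scores, p_combined = a * sigmoid(.data$f_feature) +
                  b * sigmoid(.data$f_kernel) + (1 - a - b) * .data$p_neural)
}

#' Aggregate candidate probabilities to document-level relations
#'
#' For every (document, chemical concept, disease concept) the maximum
#' combined probability over its mention-pair candidates is taken; the triple
#' is emitted iff that maximum reaches the threshold. Unnormalized concepts
#' (`"-1"`) are never emitted.
#'
#' @param scored Tibble of candidates with `doc_id`, `chem_concept`,
#'   `dis_concept` and `p_combined`.
#' @param threshold Boundary probability (default 0.5).
#' @return Relation tibble (`doc_id`, `chem_id`, `dis_id`, `p`).
#' @export
document_relations <- function(scored, threshold = 0.5) {
  scored %>%
    filter(.data$chem_concept != "-1", .data$dis_concept != "-1") %>%
    group_by(doc_id = .data$doc_id, chem_id = .data$chem_concept,
             dis_id = .data$dis_concept) %>%
    summarise(p = max(.data$p_combined), .groups = "drop") %>%
    filter(.data$p >= threshold)
}

# ---- post-processing rules ---------------------------------------------------

causal_trigger_stems <- c("relate", "related", "cause", "caused",
                          "associate", "associated", "induce", "induced")

co_sentential_pairs <- function(document) {
  cand <- generate_candidates(document)
  cand[cand$chem_concept != "-1" & cand$dis_concept != "-1", , drop = FALSE]
}

#' Causal-relation rules
#'
#' Adds, for every co-sentential chemical-disease mention pair whose concept
#' pair is not already predicted: (i) pairs with a causal trigger
#' (*related*, *caused*, *associated*, *induced*; matched on stems,
#' case-insensitively) strictly between a chemical followed by a disease;
#' (ii) pairs with *during* strictly between a disease followed by a
#' chemical; (iii) pairs where the chemical mention immediately precedes the
#' disease mention (at most one intervening hyphen/punctuation token).
#'
#' @param document A parsed `cdr_document`.
#' @param predicted Relation tibble (`doc_id`, `chem_id`, `dis_id`).
#' @return Tibble of relations to add (possibly empty), with a `rule` column.
#' @export
causal_relation_rules <- function(document, predicted) {
  cand <- co_sentential_pairs(document)
  if (!nrow(cand)) return(tibble(doc_id = character(), chem_id = character(),
                                 dis_id = character(), rule = character()))
  pred_key <- paste(predicted$doc_id, predicted$chem_id, predicted$dis_id, sep = "\r")
  out <- list()
  for (i in seq_len(nrow(cand))) {
    key <- paste(cand$doc_id[[i]], cand$chem_concept[[i]], cand$dis_concept[[i]], sep = "\r")
    if (key %in% pred_key) next
    sent <- document$sentences[[cand$sentence_index[[i]] + 1L]]
    toks <- sent$tokens
    chem_first <- cand$chem_start[[i]] < cand$dis_start[[i]]
    gap_lo <- min(cand$chem_end[[i]], cand$dis_end[[i]])
    gap_hi <- max(cand$chem_start[[i]], cand$dis_start[[i]])
    between <- toks[toks$index >= gap_lo & toks$index < gap_hi, ]
    fired <- NA_character_
    if (chem_first && any(tolower(between$stem) %in% causal_trigger_stems)) {
      fired <- "causal_trigger"
    } else if (!chem_first && any(tolower(between$surface) == "during" |
                                  tolower(between$stem) == "during")) {
      fired <- "disease_during_chemical"
    } else if (chem_first && nrow(between) <= 1L &&
               (nrow(between) == 0L || all(grepl("^[-–—/]+$", between$surface)))) {
      fired <- "adjacency"
    }
    if (!is.na(fired)) {
      out[[length(out) + 1L]] <- tibble(doc_id = cand$doc_id[[i]],
                                        chem_id = cand$chem_concept[[i]],
                                        dis_id = cand$dis_concept[[i]],
                                        rule = fired)
    }
  }
  if (length(out)) distinct(bind_rows(out)) else
    tibble(doc_id = character(), chem_id = character(),
           dis_id = character(), rule = character())
}

#' Focused-chemical rules
#'
#' Applied only when a document has no predicted relation: all chemical
#' concepts mentioned in the title are paired with every disease concept in
#' the document; if the title mentions no chemical, the most frequently
#' mentioned chemical concept (ties broken by first occurrence) is paired
#' with every disease concept.
#'
#' @inheritParams causal_relation_rules
#' @return Tibble of relations to add (possibly empty), with a `rule` column.
#' @export
focused_chemical_rules <- function(document, predicted) {
  none <- tibble(doc_id = character(), chem_id = character(),
                 dis_id = character(), rule = character())
  if (any(predicted$doc_id == document$doc_id)) return(none)
  ment <- document$mentions
  ment <- ment[ment$concept_id != "-1", , drop = FALSE]
  if (!nrow(ment)) return(none)
  title_len <- nchar(document$title)
  chems <- ment[ment$etype == "chemical", , drop = FALSE]
  diseases <- unique(ment$concept_id[ment$etype == "disease"])
  if (!nrow(chems) || !length(diseases)) return(none)
  title_chems <- unique(chems$concept_id[chems$char_start < title_len])
  if (length(title_chems)) {
    focused <- title_chems
    rule <- "title_chemical"
  } else {
    counts <- table(chems$concept_id)
    top <- max(counts)
    tied <- names(counts)[counts == top]
    # tie -> first occurring in the document
    first_pos <- vapply(tied, function(id) min(chems$char_start[chems$concept_id == id]),
                        numeric(1))
    focused <- tied[[which.min(first_pos)]]
    rule <- "most_frequent_chemical"
  }
  tidyr::expand_grid(chem_id = focused, dis_id = diseases) %>%
    mutate(doc_id = document$doc_id, rule = rule) %>%
    select("doc_id", "chem_id", "dis_id", "rule")
}

#' Apply both rule families after the hybrid system
#'
#' Causal-relation rules first, then focused-chemical rules on documents
#' still empty. Post-processing only ever adds relations.
#'
#' @param documents List of parsed `cdr_document` objects.
#' @param predicted Relation tibble from [document_relations()].
#' @param causal,focused Toggles for the two rule families.
#' @return List with `relations` (augmented tibble) and `added` (the
#'   rule-introduced relations with their rule names).
#' @export
apply_rules <- function(documents, predicted, causal = TRUE, focused = TRUE) {
  added <- list()
  current <- predicted
  if (causal) {
    for (doc in documents) {
      add <- causal_relation_rules(doc, current)
      if (nrow(add)) {
        added[[length(added) + 1L]] <- add
        current <- bind_rows(current, add[, c("doc_id", "chem_id", "dis_id")])
      }
    }
  }
  if (focused) {
    for (doc in documents) {
      add <- focused_chemical_rules(doc, current)
      if (nrow(add)) {
        added[[length(added) + 1L]] <- add
        current <- bind_rows(current, add[, c("doc_id", "chem_id", "dis_id")])
      }
    }
  }
  added <- if (length(added)) distinct(bind_rows(added)) else
    tibble(doc_id = character(), chem_id = character(),
           dis_id = character(), rule = character())
  list(relations = distinct(current[, c("doc_id", "chem_id", "dis_id")]),
       added = added)
}
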