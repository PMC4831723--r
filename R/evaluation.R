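#' Document-level evaluation
#'
#' Relations are evaluated as sets of (document, chemical concept, disease
#' concept) triples, mirroring the granularity of the official CID
#' evaluation: duplicates collapse, mention offsets are ignored.
#'
#' @name evaluation
NULL

relation_key <- function(rel) {
  paste(rel$doc_id, rel$chem_id, rel$dis_id, sep = "\r")
}

#' Precision, recall and F-score over relation sets
#'
#' `P = |gold ∩ pred| / |pred|`, `R = |gold ∩ pred| / |gold|`,
#' `F = 2PR / (P + R)`; empty denominators yield 0.
#'
#' @param gold,pred Tibbles with columns `doc_id`, `chem_id`, `dis_id`
#'   (duplicates are collapsed).
#' @return One-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
prf <- function(gold, pred) {
  g <- unique(relation_key(gold)); p <- unique(relation_key(pred))
  tp <- length(intersect(g, p))
  prec <- if (length(p)) tp / length(p) else 0
  rec <- if (length(g)) tp / length(g) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  tibble(tp = tp, fp = length(p) - tp, fn = length(g) - tp,
         precision = prec, recall = rec, f1 = f1)
}

#' Read relations in PubTator relation-line format
#'
#' Accepts full PubTator files or bare relation files; only
#' `pmid<TAB>CID<TAB>chem<TAB>dis` lines are used.
#'
#' @param path File path.
#' @return Tibble with `doc_id`, `chem_id`, `dis_id`.
#' @export
read_relation_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) == 4L && f[2] == "CID", logical(1))
  if (!any(keep)) return(tibble(doc_id = character(), chem_id = character(),
                                dis_id = character()))
  distinct(tibble(doc_id = vapply(fields[keep], `[`, "", 1L),
                  chem_id = vapply(fields[keep], `[`, "", 3L),
                  dis_id = vapply(fields[keep], `[`, "", 4L)))
}

#' Write relations in PubTator relation-line format
#' @param relations Tibble with `doc_id`, `chem_id`, `dis_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_relation_file <- function(relations, path) {
  writeLines(paste(relations$doc_id, "CID", relations$chem_id,
                   relations$dis_id, sep = "\t"), path)
  invisible(path)
}

#' Categorize false positives and false negatives
#'
#' Each false positive is assigned to exactly one category by priority:
#' `entity` (a concept of the pair is absent from the gold entity
#' annotations), then `rule` (the relation was introduced by post-processing
#' rules), then `classification`. Each false negative: `entity` (a concept
#' absent from the predicted/available entity annotations), then
#' `cross_sentence` (the concept pair never co-occurs in a sentence, so no
#' candidate could represent it), then `classification`. Percentages are
#' rounded to 2 decimals.
#'
#' @param gold,pred Relation tibbles (`doc_id`, `chem_id`, `dis_id`).
#' @param gold_entities,pred_entities Tibbles of entity annotations with
#'   `doc_id`, `concept_id` (gold-standard vs. system-available entities).
#' @param rule_added Tibble of relations added by post-processing rules (same
#'   columns as `pred`); may be empty.
#' @param candidate_coverage Tibble of concept pairs that had at least one
#'   co-sentential candidate (`doc_id`, `chem_id`, `dis_id`).
#' @return A `cdr_error_report`: list of two tibbles (`fp`, `fn`) with
#'   category counts and percentages, plus totals.
#' @export
categorize_errors <- function(gold, pred, gold_entities, pred_entities,
                              rule_added, candidate_coverage) {
  g <- unique(relation_key(gold)); p <- unique(relation_key(pred))
  fp <- pred[!(relation_key(pred) %in% g), , drop = FALSE]
  fn <- gold[!(relation_key(gold) %in% p), , drop = FALSE]
  ent_key <- function(ents) paste(ents$doc_id, ents$concept_id, sep = "\r")
  has_entities <- function(rel, ents) {
    paste(rel$doc_id, rel$chem_id, sep = "\r") %in% ent_key(ents) &
      paste(rel$doc_id, rel$dis_id, sep = "\r") %in% ent_key(ents)
  }
  fp_cat <- ifelse(!has_entities(fp, gold_entities), "entity",
                   ifelse(relation_key(fp) %in% relation_key(rule_added),
                          "rule", "classification"))
  fn_cat <- ifelse(!has_entities(fn, pred_entities), "entity",
                   ifelse(!(relation_key(fn) %in% relation_key(candidate_coverage)),
                          "cross_sentence", "classification"))
  tab <- function(cats, levels) {
    counts <- unname(vapply(levels, function(l) sum(cats == l), integer(1)))
    tibble(category = levels, count = counts,
           percent = round(100 * counts / max(1L, length(cats)), 2))
  }
  structure(list(fp = tab(fp_cat, c("entity", "classification", "rule")),
                 fn = tab(fn_cat, c("entity", "classification", "cross_sentence")),
                 n_fp = nrow(fp), n_fn = nrow(fn)),
            class = "cdr_error_report")
}

#' @export
print.cdr_error_report <- function(x, ...) {
  cat(sprintf("False positives (%d):\n", x$n_fp))
  print(as.data.frame(x$fp), row.names = FALSE)
  cat(sprintf("False negatives (%d):\n", x$n_fn))
  print(as.data.frame(x$fn), row.names = FALSE)
  invisible(x)
}

#' Error-share arithmetic
#'
#' The percentage share of a category, rounded to 2 decimals (e.g. 345
#' rule-introduced FP of 717 total print as 48.12).
#'
#' @param count Category count.
#' @param total Total error count.
#' @return Percentage rounded to 2 decimals.
#' @export
error_share <- function(count, total) round(100 * count / total, 2)

#' Exact paired sign-flip permutation test over fold scores
#'
#' Two-sided test of the mean difference between two systems' per-fold
#' F-scores by exhaustive enumeration of all `2^k` sign assignments.
#'
#' @param fold_a,fold_b Numeric vectors of per-fold scores (equal length).
#' @return The p-value: the share of sign patterns whose absolute mean is at
#'   least the observed absolute mean.
#' @export
fold_compare <- function(fold_a, fold_b) {
  stopifnot(length(fold_a) == length(fold_b))
  d <- fold_a - fold_b
  k <- length(d)
  obs <- abs(mean(d))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  perm <- abs(as.vector(signs %*% d) / k)
  mean(perm >= obs - 1e-12)
}
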