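#' End-to-end CID extraction pipeline
#'
#' [cdr_train()] fits the three component models on a parsed corpus,
#' [cdr_score()] produces per-candidate decision values and probabilities,
#' [cdr_predict()] combines them (optionally applying post-processing rules)
#' into document-level relations, and [cdr_grid_search()] tunes the
#' combination weights by k-fold cross-validation.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Defaults follow the usual choices for this architecture: SST tree kernel
#' with decay 0.4 and cosine normalization, polynomial kernel of degree 3
#' (coef0 1, C 1, positive-class cost factor = negative/positive ratio), and
#' a peephole LSTM over `SDP-seq+POS+HEAD` input. Embedding width and hidden
#' size default to 200/100; smaller values are appropriate for small
#' synthetic corpora.
#'
#' @param kernel A [kernel_config()].
#' @param feature_groups Flat feature groups (ablation order).
#' @param feature_window Context window half-width (default 3).
#' @param poly_degree,poly_coef0,C,j Feature/kernel margin hyperparameters
#'   (`j = NULL`: class-imbalance ratio).
#' @param poly_normalize Cosine-normalize the polynomial kernel (default
#'   `TRUE`; keeps the degree-3 Gram well conditioned — raw values grow as
#'   `(#active features)^degree`, which stalls the SMO solver).
#' @param method Neural input method string.
#' @param arch `"lstm"` or `"cnn"`.
#' @param d,hidden,n_maps,window Neural dimensions.
#' @param epochs,lr,batch_size,val_frac,patience Neural optimization.
#' @param include_entities Include entity tokens in WORD sequences.
#' @param threshold Combined-probability decision boundary (default 0.5).
#' @param seed Seed used for neural initialization/training.
#' @return A `cdr_config` list.
#' @export
cdr_config <- function(kernel = kernel_config(),
                       feature_groups = c("context", "entity", "position",
                                          "distance", "verb", "fdf"),
                       feature_window = 3L,
                       poly_degree = 3, poly_coef0 = 1, poly_normalize = TRUE,
                       C = 1, j = NULL,
                       method = "SDP-seq+POS+HEAD", arch = "lstm",
                       d = 200L, hidden = 100L, n_maps = 200L, window = 3L,
                       epochs = 30L, lr = 0.01, batch_size = 32L,
                       val_frac = 0.1, patience = 5L,
                       include_entities = TRUE, threshold = 0.5, seed = 42L) {
  structure(as.list(environment()), class = "cdr_config")
}

# per-candidate views: flat features, SDF/SPF trees, neural input sequence.
# Candidates whose heads sit in disconnected dependency components (or whose
# SDP view otherwise fails) get NULL trees and fall back to a WORD sequence.
build_views <- function(documents, config) {
  candidates <- corpus_candidates(documents)
  docs_by_id <- stats::setNames(documents, vapply(documents, function(d) d$doc_id, ""))
  views <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    doc <- docs_by_id[[cand$doc_id]]
    sent <- doc$sentences[[cand$sentence_index + 1L]]
    hc <- entity_head(cand$chem_start, cand$chem_end, sent)
    hd <- entity_head(cand$dis_start, cand$dis_end, sent)
    tree_views <- tryCatch({
      st <- sdpt(sent, hc, hd)
      list(sdpt = st, sdf = sdf(st),
           spf = spf(sent$phrase_tree, sdpt_token_indices(st)))
    }, error = function(e) NULL)
    feats <- candidate_features(sent, cand, groups = config$feature_groups,
                                window = config$feature_window,
                                sdpt_tree = tree_views$sdpt)
    seq_tbl <- tryCatch(
      encode_input(sent, cand, config$method, config$include_entities),
      error = function(e) NULL)
    if (is.null(seq_tbl)) {
      # fragmented parse: fall back to the plain word sequence
      m <- parse_method(config$method)
      fallback <- paste0("WORD", if (m$use_pos) "+POS", if (m$use_head) "+HEAD")
      seq_tbl <- encode_input(sent, cand, fallback, config$include_entities)
    }
    views[[i]] <- list(feats = feats, sdf = tree_views$sdf, spf = tree_views$spf,
                       seq = seq_tbl)
  }
  list(candidates = candidates, views = views)
}

#' Train the hybrid system
#'
#' Fits the feature-based margin model (polynomial kernel over flat
#' features), the tree-kernel margin model (composite SDF+SPF kernel; only
#' candidates with an available dependency path participate) and the neural
#' model on all intra-sentence candidates of the corpus.
#'
#' @param documents List of parsed `cdr_document` objects.
#' @param config A [cdr_config()].
#' @return A `cdr_system`.
#' @export
cdr_train <- function(documents, config = cdr_config()) {
  bv <- build_views(documents, config)
  labels <- bv$candidates$label
  if (length(unique(labels)) < 2L) stop("training corpus has a single class")
  j <- if (is.null(config$j)) sum(labels == -1L) / sum(labels == 1L) else config$j

  vocab <- fit_vocabulary(lapply(bv$views, `[[`, "feats"))
  X <- vectorize_features(lapply(bv$views, `[[`, "feats"), vocab)
  G_feat <- poly_gram(X, degree = config$poly_degree, coef0 = config$poly_coef0)
  feat_diag <- diag(G_feat)
  if (isTRUE(config$poly_normalize)) {
    G_feat <- G_feat / sqrt(tcrossprod(feat_diag))
  }
  feature_model <- train_margin_model(G_feat, labels, C = config$C, j = j)

  has_tree <- vapply(bv$views, function(v) !is.null(v$sdf), logical(1))
  tree_views <- lapply(bv$views[has_tree], function(v) v[c("sdf", "spf")])
  G_tree <- gram_matrix(tree_views, config = config$kernel)
  kernel_model <- train_margin_model(G_tree, labels[has_tree], C = config$C, j = j)

  seqs <- lapply(bv$views, `[[`, "seq")
  vocabs <- build_vocabs(seqs)
  neural <- init_neural(vocabs, method = config$method, d = config$d,
                        hidden = config$hidden, arch = config$arch,
                        n_maps = config$n_maps, window = config$window,
                        seed = config$seed)
  neural <- train_neural(neural, seqs, labels, epochs = config$epochs,
                         lr = config$lr, batch_size = config$batch_size,
                         val_frac = config$val_frac, patience = config$patience,
                         seed = config$seed)

  structure(list(config = config, vocab = vocab, X_train = X,
                 feat_diag = feat_diag,
                 feature_model = feature_model, kernel_model = kernel_model,
                 train_tree_views = tree_views, neural = neural, j = j,
                 n_train = nrow(bv$candidates)),
            class = "cdr_system")
}

#' @export
print.cdr_system <- function(x, ...) {
  cat(sprintf("<cdr_system: %d training candidate(s), %d flat feature(s), %d tree candidate(s), %s neural>\n",
              x$n_train, length(x$vocab), length(x$train_tree_views),
              toupper(x$neural$arch)))
  invisible(x)
}

#' Score candidates of a corpus with a trained system
#'
#' @param system A `cdr_system`.
#' @param documents List of parsed `cdr_document` objects.
#' @return The candidate tibble with `f_feature`, `f_kernel` (margin decision
#'   values; 0 — the hyperplane — for candidates without a tree view) and
#'   `p_neural` columns.
#' @export
cdr_score <- function(system, documents) {
  config <- system$config
  bv <- build_views(documents, config)
  out <- bv$candidates
  if (!nrow(out)) {
    out$f_feature <- numeric(); out$f_kernel <- numeric(); out$p_neural <- numeric()
    return(out)
  }
  X_new <- vectorize_features(lapply(bv$views, `[[`, "feats"), system$vocab)
  G_feat <- poly_gram(X_new, system$X_train, degree = config$poly_degree,
                      coef0 = config$poly_coef0)
  if (isTRUE(config$poly_normalize)) {
    new_diag <- (Matrix::rowSums(X_new^2) + config$poly_coef0)^config$poly_degree
    G_feat <- G_feat / sqrt(tcrossprod(new_diag, system$feat_diag))
  }
  out$f_feature <- decision_value(system$feature_model, G_feat)
  out$f_kernel <- 0
  has_tree <- vapply(bv$views, function(v) !is.null(v$sdf), logical(1))
  if (any(has_tree)) {
    G_tree <- gram_matrix(lapply(bv$views[has_tree], function(v) v[c("sdf", "spf")]),
                          system$train_tree_views, config = config$kernel)
    out$f_kernel[has_tree] <- decision_value(system$kernel_model, G_tree)
  }
  out$p_neural <- predict(system$neural, lapply(bv$views, `[[`, "seq"))
  out
}

#' Gold document-level relations of a corpus
#'
#' @param documents List of `cdr_document` objects.
#' @return Tibble with `doc_id`, `chem_id`, `dis_id`.
#' @export
corpus_gold <- function(documents) {
  rows <- lapply(documents, function(d) {
    if (nrow(d$gold_relations)) mutate(d$gold_relations, doc_id = d$doc_id)
  })
  out <- bind_rows(rows)
  if (!nrow(out)) return(tibble(doc_id = character(), chem_id = character(),
                                dis_id = character()))
  distinct(select(out, "doc_id", "chem_id", "dis_id"))
}

#' Predict document-level relations
#'
#' Scores all candidates, combines the three model outputs with the given
#' weights, aggregates to concept-pair relations at the probability
#' threshold, and optionally applies the two post-processing rule families.
#'
#' @param system A `cdr_system`.
#' @param documents List of parsed `cdr_document` objects.
#' @param weights A [weight_config()] (default: equal thirds).
#' @param rules Apply post-processing rules (default `TRUE`).
#' @param scored Optional precomputed [cdr_score()] tibble.
#' @return A `cdr_prediction` list: `relations` (tibble), `scored`
#'   (candidate scores with `p_combined`), `rule_added` (rule-introduced
#'   relations).
#' @export
cdr_predict <- function(system, documents, weights = weight_config(1/3, 1/3),
                        rules = TRUE, scored = NULL) {
  if (is.null(scored)) scored <- cdr_score(system, documents)
  scored <- combine_scores(scored, weights)
  pred <- document_relations(scored, threshold = weights$threshold %||% system$config$threshold)
  rule_added <- tibble(doc_id = character(), chem_id = character(),
                       dis_id = character(), rule = character())
  relations <- select(pred, "doc_id", "chem_id", "dis_id")
  if (rules) {
    res <- apply_rules(documents, relations)
    relations <- res$relations
    rule_added <- res$added
  }
  structure(list(relations = relations, scored = scored, rule_added = rule_added),
            class = "cdr_prediction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cdr_prediction <- function(x, ...) {
  cat(sprintf("<cdr_prediction: %d relation(s) over %d candidate(s), %d rule-added>\n",
              nrow(x$relations), nrow(x$scored), nrow(x$rule_added)))
  invisible(x)
}

#' @export
tidy.cdr_prediction <- function(x, ...) x$relations

#' Evaluate predictions against a gold corpus
#'
#' @param prediction A `cdr_prediction` or relation tibble.
#' @param gold Gold relation tibble (e.g. [corpus_gold()]).
#' @return One-row [prf()] tibble.
#' @export
cdr_evaluate <- function(prediction, gold) {
  rel <- if (inherits(prediction, "cdr_prediction")) prediction$relations else prediction
  prf(gold, rel)
}

# ---- grid search over combination weights -----------------------------------

#' Simplex grid of combination weights
#'
#' All `(alpha, beta)` pairs with `alpha, beta >= 0`, `alpha + beta <= 1` on
#' a regular grid (computed over integers, so no floating-point drift). The
#' 0.1-step grid has 66 points, including the three corners that reduce the
#' hybrid to each individual model.
#'
#' @param step Grid step (must divide 1; default 0.1).
#' @return Tibble with `alpha`, `beta`.
#' @export
simplex_grid <- function(step = 0.1) {
  n <- round(1 / step)
  grid <- expand.grid(i = 0:n, j = 0:n)
  grid <- grid[grid$i + grid$j <= n, ]
  tibble(alpha = grid$i / n, beta = grid$j / n)
}

eval_weights_on_folds <- function(fold_data, alpha, beta, threshold) {
  fs <- vapply(fold_data, function(fd) {
    sc <- combine_scores(fd$scored, list(alpha = alpha, beta = beta))
    prf(fd$gold, document_relations(sc, threshold))$f1
  }, numeric(1))
  mean(fs)
}

#' Grid-search the combination weights by cross-validation
#'
#' Splits documents into `k` folds, trains the three models on each
#' training portion and scores the held-out documents, then evaluates mean
#' document-level F over folds for every `(alpha, beta)` on the coarse
#' simplex grid, refining with a fine grid around the coarse optimum. Ties
#' are broken toward larger `alpha`, then larger `beta`. Deterministic given
#' the seed.
#'
#' @param documents List of parsed `cdr_document` objects.
#' @param config A [cdr_config()].
#' @param step_coarse,step_fine Grid steps (defaults 0.1, 0.01).
#' @param k Folds (default 5).
#' @param seed Seed for the document-level fold split.
#' @return A `cdr_grid`: best [weight_config()], the evaluated grids, the
#'   per-fold scores at the optimum, and the corner (single-model) means.
#' @export
cdr_grid_search <- function(documents, config = cdr_config(),
                            step_coarse = 0.1, step_fine = 0.01, k = 5L,
                            seed = 1L) {
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(k), length(documents)))
  fold_data <- lapply(seq_len(k), function(f) {
    train_docs <- documents[fold_of != f]
    test_docs <- documents[fold_of == f]
    system <- cdr_train(train_docs, config)
    list(scored = cdr_score(system, test_docs), gold = corpus_gold(test_docs))
  })
  threshold <- config$threshold
  evaluate_grid <- function(grid) {
    grid$mean_f <- vapply(seq_len(nrow(grid)), function(r)
      eval_weights_on_folds(fold_data, grid$alpha[[r]], grid$beta[[r]], threshold),
      numeric(1))
    grid
  }
  coarse <- evaluate_grid(simplex_grid(step_coarse))
  pick <- function(grid) {
    best <- grid[grid$mean_f >= max(grid$mean_f) - 1e-12, ]
    best <- best[order(-best$alpha, -best$beta), ]
    best[1, ]
  }
  cb <- pick(coarse)
  n_fine <- round(1 / step_fine)
  fine_pts <- expand.grid(
    alpha = seq(max(0, cb$alpha - step_coarse), min(1, cb$alpha + step_coarse),
                by = step_fine),
    beta = seq(max(0, cb$beta - step_coarse), min(1, cb$beta + step_coarse),
               by = step_fine))
  fine_pts <- tibble(alpha = round(fine_pts$alpha * n_fine) / n_fine,
                     beta = round(fine_pts$beta * n_fine) / n_fine)
  fine_pts <- fine_pts[fine_pts$alpha + fine_pts$beta <= 1 + 1e-12, ]
  fine <- evaluate_grid(fine_pts)
  fb <- pick(fine)
  best_fold_f <- vapply(fold_data, function(fd) {
    sc <- combine_scores(fd$scored, list(alpha = fb$alpha, beta = fb$beta))
    prf(fd$gold, document_relations(sc, threshold))$f1
  }, numeric(1))
  fold_f_at <- function(alpha, beta) {
    vapply(fold_data, function(fd) {
      sc <- combine_scores(fd$scored, list(alpha = alpha, beta = beta))
      prf(fd$gold, document_relations(sc, threshold))$f1
    }, numeric(1))
  }
  corners <- tibble(
    model = c("feature", "kernel", "neural"),
    alpha = c(1, 0, 0), beta = c(0, 1, 0),
    mean_f = c(coarse$mean_f[coarse$alpha == 1 & coarse$beta == 0],
               coarse$mean_f[coarse$alpha == 0 & coarse$beta == 1],
               coarse$mean_f[coarse$alpha == 0 & coarse$beta == 0]))
  corner_fold_f <- lapply(seq_len(3L), function(i)
    fold_f_at(corners$alpha[[i]], corners$beta[[i]]))
  names(corner_fold_f) <- corners$model
  structure(list(best = weight_config(fb$alpha, fb$beta, threshold),
                 mean_f = fb$mean_f, coarse = coarse, fine = fine,
                 fold_f = best_fold_f, corners = corners,
                 corner_fold_f = corner_fold_f, k = k, seed = seed),
            class = "cdr_grid")
}

#' @export
print.cdr_grid <- function(x, ...) {
  cat(sprintf("<cdr_grid: best alpha=%.2f beta=%.2f (mean F=%.4f over %d folds)>\n",
              x$best$alpha, x$best$beta, x$mean_f, x$k))
  invisible(x)
}

#' @export
tidy.cdr_grid <- function(x, ...) x$coarse

#' @export
glance.cdr_grid <- function(x, ...) {
  tibble(alpha = x$best$alpha, beta = x$best$beta, mean_f = x$mean_f,
         k = x$k, best_single_f = max(x$corners$mean_f))
}

#' Heatmap of the coarse weight grid
#'
#' @param object A `cdr_grid`.
#' @param ... Unused.
#' @return A ggplot object: mean cross-validated F over the `(alpha, beta)`
#'   simplex, with the optimum marked.
#' @export
autoplot.cdr_grid <- function(object, ...) {
  ggplot2::ggplot(object$coarse,
                  ggplot2::aes(x = .data$alpha, y = .data$beta, fill = .data$mean_f)) +
    ggplot2::geom_tile() +
    ggplot2::annotate("point", x = object$best$alpha, y = object$best$beta,
                      shape = 3, size = 3) +
    ggplot2::scale_fill_viridis_c(name = "mean F") +
    ggplot2::labs(x = expression(alpha ~ "(feature model)"),
                  y = expression(beta ~ "(tree-kernel model)"),
                  title = "Cross-validated F over the weight simplex") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Training-loss curve of the neural model
#'
#' @param object A trained `cdr_neural` (with `$log`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cdr_neural <- function(object, ...) {
  if (is.null(object$log)) stop("model has no training log")
  long <- tidyr::pivot_longer(object$log, c("train_loss", "val_loss"),
                              names_to = "series", values_to = "loss")
  ggplot2::ggplot(long[!is.na(long$loss), ],
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean cross-entropy") +
    ggplot2::theme_minimal()
}

# ---- debuggable dumps --------------------------------------------------------

#' Write a per-candidate score dump
#'
#' Tab-separated: candidate id, the two margin decision values, the neural
#' and combined probabilities.
#'
#' @param scored Tibble from [cdr_score()]/[combine_scores()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scored, path) {
  cols <- intersect(c("candidate_id", "f_feature", "f_kernel", "p_neural",
                      "p_combined"), names(scored))
  utils::write.table(scored[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a flat-feature dump
#'
#' One candidate per line: candidate id, then its namespaced feature strings,
#' tab-separated (diffable).
#'
#' @param documents Parsed documents.
#' @param config A [cdr_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_dump <- function(documents, config, path) {
  bv <- build_views(documents, config)
  lines <- vapply(seq_along(bv$views), function(i) {
    paste(c(bv$candidates$candidate_id[[i]], sort(bv$views[[i]]$feats)),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
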