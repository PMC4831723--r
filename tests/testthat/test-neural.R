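toy_neural_setup <- function(method = "SDP-seq+POS+HEAD", arch = "lstm",
                             d = 5L, hidden = 4L, n_docs = 4L) {
  corpus <- generate_corpus(fixture_spec(n_documents = n_docs, seed = 17L))
  cfg <- cdr_config(method = method, arch = arch, d = d, hidden = hidden)
  bv <- cdrhybrid:::build_views(corpus$documents, cfg)
  seqs <- lapply(bv$views, `[[`, "seq")
  list(seqs = seqs, labels = bv$candidates$label,
       vocabs = build_vocabs(seqs), cfg = cfg)
}

test_that("input encodings have the specified lengths and widths", {
  corpus <- shared_fixture_corpus()
  cand <- corpus_candidates(corpus$documents)
  docs <- setNames(corpus$documents,
                   vapply(corpus$documents, function(d) d$doc_id, ""))
  for (i in seq_len(min(nrow(cand), 25L))) {
    sent <- docs[[cand$doc_id[i]]]$sentences[[cand$sentence_index[i] + 1L]]
    w <- encode_input(sent, cand[i, ], "WORD")
    # all tokens from the first mention to the last, inclusive
    lo <- min(cand$chem_start[i], cand$dis_start[i])
    hi <- max(cand$chem_end[i], cand$dis_end[i])
    expect_equal(nrow(w), hi - lo)
    expect_true(all(w$kind == "word"))
    # HEAD never lengthens the sequence
    h <- encode_input(sent, cand[i, ], "HEAD")
    expect_lte(nrow(h), nrow(w))
    # SDP modes share the same element multiset in different orders
    sdep <- encode_input(sent, cand[i, ], "SDP-dep")
    sseq <- encode_input(sent, cand[i, ], "SDP-seq")
    expect_setequal(paste(sdep$kind, sdep$label), paste(sseq$kind, sseq$label))
  }
  # WORD-POS doubles the input width through the POS table
  st <- toy_neural_setup(method = "WORD-POS", d = 6L)
  m <- init_neural(st$vocabs, method = "WORD-POS", d = 6L, hidden = 3L)
  X <- cdrhybrid:::input_matrix(m, m$params, cdrhybrid:::seq_to_ids(st$seqs[[1]], st$vocabs))
  expect_equal(nrow(X), 12L)
  expect_equal(m$D, 2L * m$d)
  # +HEAD on SDP replaces the endpoints with type placeholders
  s1 <- encode_input(docs[[cand$doc_id[1]]]$sentences[[cand$sentence_index[1] + 1L]],
                     cand[1, ], "SDP-seq+HEAD")
  expect_true(all(c("<chemical>", "<disease>") %in% s1$label))
})

test_that("lstm_step follows the five gate equations", {
  H <- 4L; D <- 5L
  zero <- list(Wi = matrix(0, H, D), Wf = matrix(0, H, D), Wc = matrix(0, H, D),
               Wo = matrix(0, H, D), Ui = matrix(0, H, H), Uf = matrix(0, H, H),
               Uc = matrix(0, H, H), Uo = matrix(0, H, H),
               vi = numeric(H), vf = numeric(H), vo = numeric(H),
               bi = numeric(H), bf = numeric(H), bc = numeric(H), bo = numeric(H))
  st <- lstm_step(rnorm(D), numeric(H), numeric(H), zero)
  expect_equal(st$i, rep(0.5, H))
  expect_equal(st$f, rep(0.5, H))
  expect_equal(st$o, rep(0.5, H))
  expect_equal(st$c, numeric(H))
  expect_equal(st$h, numeric(H))
  # saturated forget gate: c_t -> c_prev + i * tanh(candidate)
  sat <- zero; sat$bf <- rep(50, H)
  c_prev <- rnorm(H); x <- rnorm(D)
  st2 <- lstm_step(x, numeric(H), c_prev, sat)
  expect_equal(st2$c, c_prev + st2$i * st2$g, tolerance = 1e-8)
  # random parameters match the straight-line re-implementation
  for (seed in 1:3) {
    p <- random_lstm_params(D, H, seed)
    set.seed(seed + 100)
    x <- rnorm(D); h0 <- rnorm(H); c0 <- rnorm(H)
    got <- lstm_step(x, h0, c0, p)
    want <- oracle_lstm_step(x, h0, c0, p)
    expect_equal(got$h, want$h, tolerance = 1e-12)
    expect_equal(got$c, want$c, tolerance = 1e-12)
  }
  expect_error(lstm_step(rnorm(3), numeric(H), numeric(H), zero), ".")
})

test_that("lstm_encode has the prefix property and sequences map to (0,1)", {
  D <- 5L; H <- 4L
  p <- random_lstm_params(D, H, 9)
  set.seed(5)
  X <- matrix(rnorm(D * 6), D, 6)
  h_full <- lstm_encode(X, p)
  # encoding of the prefix equals the internal state after t steps
  fwd <- cdrhybrid:::lstm_forward_cached(X, p)
  for (t in c(1, 3, 6)) {
    expect_equal(lstm_encode(X[, 1:t, drop = FALSE], p), fwd$cache[[t]]$h)
  }
  expect_equal(h_full, fwd$h_T)
  expect_equal(lstm_encode(X[, 1, drop = FALSE], p),
               lstm_step(X[, 1], numeric(H), numeric(H), p)$h)
  st <- toy_neural_setup()
  m <- init_neural(st$vocabs, d = 5L, hidden = 4L, seed = 3L)
  probs <- predict(m, st$seqs)
  expect_true(all(probs > 0 & probs < 1))
})

test_that("CNN encoder pools the componentwise maximum", {
  D <- 6L; M <- 200L; W <- 3L
  set.seed(8)
  Wc <- matrix(rnorm(M * W * D, sd = 0.3), M, W * D)
  bc <- rnorm(M, sd = 0.1)
  X <- matrix(rnorm(D * 5), D, 5)
  pooled <- cnn_encode(X, Wc, bc, W)
  expect_length(pooled, M)           # one value per feature map
  fwd <- cdrhybrid:::cnn_forward_cached(X, Wc, bc, W)
  expect_true(all(pooled >= fwd$Z - 1e-12))   # max-pool dominance
  expect_equal(pooled, apply(fwd$Z, 1, max))
  # constant-length-1 sequence: pooled equals the single window response
  X1 <- matrix(rnorm(D), D, 1)
  p1 <- cnn_encode(X1, Wc, bc, W)
  expect_equal(p1, as.vector(tanh(Wc %*% c(numeric(D), X1[, 1], numeric(D)) + bc)))
})

test_that("analytic gradients match central finite differences (LSTM and CNN)", {
  st <- toy_neural_setup(d = 5L, hidden = 4L)
  sel <- seq_len(min(4L, length(st$seqs)))
  labels <- st$labels[sel]
  if (length(unique(labels)) < 2) labels[1] <- -labels[1]
  m <- init_neural(st$vocabs, method = st$cfg$method, d = 5L, hidden = 4L, seed = 21L)
  chk <- gradient_check(m, st$seqs[sel], labels)
  expect_true(all(chk$max_rel_err < 1e-4),
              info = paste(capture.output(print(chk)), collapse = "\n"))
  mc <- init_neural(st$vocabs, method = st$cfg$method, d = 5L, hidden = 4L,
                    arch = "cnn", n_maps = 7L, seed = 22L)
  chk2 <- gradient_check(mc, st$seqs[sel], labels)
  expect_true(all(chk2$max_rel_err < 1e-4),
              info = paste(capture.output(print(chk2)), collapse = "\n"))
})

test_that("training is deterministic and memorizes a small toy set", {
  st <- toy_neural_setup(d = 8L, hidden = 6L, n_docs = 5L)
  n <- min(10L, length(st$seqs))
  seqs <- st$seqs[seq_len(n)]; labels <- st$labels[seq_len(n)]
  if (length(unique(labels)) < 2) labels[1] <- -labels[1]
  m0 <- init_neural(st$vocabs, method = st$cfg$method, d = 8L, hidden = 6L, seed = 31L)
  m1 <- train_neural(m0, seqs, labels, epochs = 200L, lr = 0.3, batch_size = 2L,
                     val_frac = 0, seed = 7L)
  expect_lt(tail(m1$log$train_loss, 1), 0.05)
  m2 <- train_neural(m0, seqs, labels, epochs = 200L, lr = 0.3, batch_size = 2L,
                     val_frac = 0, seed = 7L)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params, m2$params)
  expect_error(train_neural(m0, list(), integer()), "empty")
})

test_that("embedding files warm-start the word table", {
  f <- tempfile(fileext = ".vec")
  writeLines(c("induced 0.1 0.2 0.3", "aspirin -1 0 1"), f)
  emb <- read_embeddings(f)
  expect_equal(emb$words, c("induced", "aspirin"))
  expect_equal(dim(emb$vectors), c(2L, 3L))
  st <- toy_neural_setup(d = 3L)
  m <- init_neural(st$vocabs, method = st$cfg$method, d = 3L, hidden = 2L,
                   seed = 1L, embeddings = emb)
  widx <- match("induced", st$vocabs$word)
  expect_equal(unname(m$params$E_word[widx, ]), c(0.1, 0.2, 0.3))
  writeLines(c("a 1 2", "b 1"), f)
  expect_error(read_embeddings(f), "inconsistent")
})
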